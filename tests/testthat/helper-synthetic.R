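# Shared fixtures (built in code) and independent oracles.

alpha_spec <- function(n, seq = strrep("A", n)) build_spec(seq, phi = -65, psi = -40)

pi_spec <- function(n, seq = strrep("A", n)) build_spec(seq, phi = -57.1, psi = -69.7)

# Brute-force proper-rotation oracle for the superposition RMSD: coarse
# quaternion grid over the rotation group followed by a Nelder-Mead polish
# of the quaternion vector part. Entirely independent of the SVD path.
oracle_min_rmsd <- function(mobile, reference, grid_n = 13L) {
  pc <- scale(mobile, scale = FALSE)
  rc <- scale(reference, scale = FALSE)
  quat_rot <- function(q) {
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3L, 3L, byrow = TRUE)
  }
  obj <- function(v) {
    s2 <- sum(v^2)
    if (s2 >= 1) v <- v / sqrt(s2 + 1e-12)
    q <- c(sqrt(max(0, 1 - sum(v^2))), v)
    sqrt(mean(rowSums((pc %*% t(quat_rot(q)) - rc)^2)))
  }
  g <- as.matrix(expand.grid(seq(-0.95, 0.95, length.out = grid_n),
                             seq(-0.95, 0.95, length.out = grid_n),
                             seq(-0.95, 0.95, length.out = grid_n)))
  g <- g[rowSums(g^2) < 1, , drop = FALSE]
  vals <- apply(g, 1L, obj)
  best <- g[which.min(vals), ]
  out <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 10000))
  out$value
}

# random spacer-class matrix for planted-motif sequences
random_classes <- function(n) {
  cbind(sample(c(2L, 4L), n, replace = TRUE),
        sample(c(3L, 4L), n, replace = TRUE))
}

# apply one global rigid motion to every model of an ensemble
transform_ensemble <- function(ens, axis = c(1, 2, -1), angle = 37,
                               shift = c(4, -2, 9)) {
  rot <- zfarray:::rotation_about_axis(axis, angle)
  ens$models <- lapply(ens$models, function(m) {
    xyz <- sweep(as.matrix(m[, c("x", "y", "z")]) %*% t(rot), 2L, shift, "+")
    m$x <- xyz[, 1L]; m$y <- xyz[, 2L]; m$z <- xyz[, 3L]
    m
  })
  ens
}
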