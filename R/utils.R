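# Internal numeric helpers shared across modules.

DEG <- pi / 180

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @keywords internal
wrap_angle <- function(x) {
  w <- ((x %% 360) + 360) %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

# shortest signed angular difference a - b, degrees in (-180, 180]
ang_diff <- function(a, b) wrap_angle(a - b)

# circular mean of angles in degrees, result in (-180, 180]
circular_mean <- function(x) {
  r <- deg2rad(x)
  wrap_angle(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector")
  a / n
}

# torsion angle p1-p2-p3-p4 in degrees, IUPAC sign convention
torsion_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(b2 / vnorm(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

# angle p1-p2-p3 in degrees
angle_points <- function(p1, p2, p3) {
  a <- vunit(p1 - p2)
  b <- vunit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(a * b)))))
}

# place atom D given A-B-C, the C-D bond length, B-C-D bond angle (deg) and
# A-B-C-D torsion (deg); natural-extension reference frame construction
nerf_place <- function(a, b, c3, bond, angle, torsion) {
  th <- deg2rad(angle)
  chi <- deg2rad(torsion)
  d_local <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  bc <- vunit(c3 - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c3 + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical row order for atom names: backbone first, then alphabetical
atom_name_order <- function(names) {
  backbone <- c("N", "CA", "C", "O")
  rank <- match(names, backbone)
  rank[is.na(rank)] <- length(backbone) + rank(names[is.na(rank)])
  names[order(rank)]
}

one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

AA1 <- names(one_to_three)
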