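# Interfinger flexibility: superpose every model of an NMR ensemble on one
# finger and measure the residual ensemble spread of a neighbouring finger
# as a per-model RMSD. A floppy linker lets the neighbour fan out (large
# mean and SD); a restrained linker keeps it put.

ranges_relation <- function(a, b) {
  if (a$chain_id != b$chain_id) return("disjoint")
  if (a$start == b$start && a$end == b$end) return("identical")
  if (a$end < b$start || b$end < a$start) return("disjoint")
  "overlap"
}

#' Ensemble spread of one residue range after fitting on another
#'
#' For every model, superposes the `fit_range` atoms and measures the RMSD
#' of the `measure_range` atoms against a reference. The default reference
#' is the two-pass ensemble mean: models are first superposed (on the fit
#' range) onto model 1, averaged into a mean structure, re-superposed once
#' onto that mean, and the measured range is compared with the final mean
#' coordinates. Alternatives: `"model1"` (reference is model 1) and
#' `"pairwise"` (all model pairs are fitted and measured against each
#' other; the summary is then over pairs).
#'
#' Identical fit and measure ranges are allowed (self-consistency: the
#' fitted core's own spread); partially overlapping ranges are rejected --
#' truncate one range first.
#'
#' @param ens a `StructureEnsemble` with >= 2 models.
#' @param fit_range,measure_range [residue_range()] selections.
#' @param atom_names atoms used for both fit and measure (default CA;
#'   `c("N","CA","C","O")` gives a backbone fit).
#' @param reference `"mean"` (two-pass mean, default), `"model1"`, or
#'   `"pairwise"`.
#' @return a `FlexibilityResult`: list with `fit_range`, `measure_range`,
#'   `atom_set`, `reference`, `per_model_rmsd` (per pair for
#'   `"pairwise"`), `mean`, `sd` (sample SD), `n` (model count).
#' @export
interfinger_flexibility <- function(ens, fit_range, measure_range,
                                    atom_names = "CA",
                                    reference = c("mean", "model1", "pairwise")) {
  stopifnot(inherits(ens, "StructureEnsemble"))
  reference <- match.arg(reference)
  rel <- ranges_relation(fit_range, measure_range)
  if (rel == "overlap")
    stop("fit and measure ranges overlap partially; truncate one of them")
  nm <- n_models(ens)
  if (nm < 2L)
    stop("flexibility is undefined for a single-model ensemble (no spread)")
  fit_sel <- select_atoms(ens, fit_range, atom_names)
  meas_sel <- if (rel == "identical") fit_sel
  else select_atoms(ens, measure_range, atom_names)

  get_mat <- function(sel, m) {
    x <- sel[m, , , drop = FALSE]
    dim(x) <- dim(sel)[2:3]
    x
  }

  if (reference == "pairwise") {
    pairs <- utils::combn(nm, 2L)
    vals <- apply(pairs, 2L, function(ij) {
      sup <- kabsch_superpose(get_mat(fit_sel, ij[1L]), get_mat(fit_sel, ij[2L]))
      rmsd(apply_superposition(sup, get_mat(meas_sel, ij[1L])),
           get_mat(meas_sel, ij[2L]))
    })
    per_model <- vals
  } else {
    ref_fit <- get_mat(fit_sel, 1L)
    fit1 <- array(NA_real_, dim = dim(fit_sel))
    meas1 <- array(NA_real_, dim = dim(meas_sel))
    for (m in seq_len(nm)) {
      sup <- kabsch_superpose(get_mat(fit_sel, m), ref_fit)
      fit1[m, , ] <- apply_superposition(sup, get_mat(fit_sel, m))
      meas1[m, , ] <- apply_superposition(sup, get_mat(meas_sel, m))
    }
    if (reference == "model1") {
      ref_meas <- get_mat(meas_sel, 1L)
      per_model <- vapply(seq_len(nm), function(m)
        rmsd(get_mat(meas1, m), ref_meas), numeric(1))
    } else {
      mean_fit <- apply(fit1, c(2L, 3L), mean)
      fit2 <- array(NA_real_, dim = dim(fit_sel))
      meas2 <- array(NA_real_, dim = dim(meas_sel))
      for (m in seq_len(nm)) {
        sup <- kabsch_superpose(get_mat(fit_sel, m), mean_fit)
        meas2[m, , ] <- apply_superposition(sup, get_mat(meas_sel, m))
      }
      mean_meas <- apply(meas2, c(2L, 3L), mean)
      per_model <- vapply(seq_len(nm), function(m)
        rmsd(get_mat(meas2, m), mean_meas), numeric(1))
    }
  }
  structure(list(
    fit_range = fit_range, measure_range = measure_range,
    atom_set = atom_names, reference = reference,
    per_model_rmsd = per_model,
    mean = mean(per_model),
    sd = stats::sd(per_model),
    n = nm
  ), class = "FlexibilityResult")
}

#' @export
print.FlexibilityResult <- function(x, ...) {
  cat(sprintf(
    "<FlexibilityResult fit %s:%d-%d, measure %s:%d-%d (%s, %s): %.2f +/- %.2f A over %d models>\n",
    x$fit_range$chain_id, x$fit_range$start, x$fit_range$end,
    x$measure_range$chain_id, x$measure_range$start, x$measure_range$end,
    paste(x$atom_set, collapse = ","), x$reference, x$mean, x$sd, x$n))
  invisible(x)
}

#' Rank flexibility results by ensemble spread
#'
#' @param results list of `FlexibilityResult` objects (>= 2).
#' @param labels optional row labels; defaults to "fit a-b / measure c-d".
#' @return data.frame sorted ascending by mean RMSD (stable for ties):
#'   `label`, `fit`, `measure`, `mean`, `sd`, `n`.
#' @export
compare_flexibility <- function(results, labels = NULL) {
  if (!is.list(results) || length(results) < 2L)
    stop("need at least two flexibility results to compare")
  out <- flexibility_table(results, labels)
  out <- out[order(out$mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

flexibility_table <- function(results, labels = NULL) {
  stopifnot(all(vapply(results, inherits, logical(1), "FlexibilityResult")))
  fmt_range <- function(r) sprintf("%s:%d-%d", r$chain_id, r$start, r$end)
  data.frame(
    label = labels %||% vapply(results, function(x)
      sprintf("fit %s / measure %s", fmt_range(x$fit_range),
              fmt_range(x$measure_range)), character(1)),
    fit = vapply(results, function(x) fmt_range(x$fit_range), character(1)),
    measure = vapply(results, function(x) fmt_range(x$measure_range), character(1)),
    mean = vapply(results, function(x) x$mean, numeric(1)),
    sd = vapply(results, function(x) x$sd, numeric(1)),
    n = vapply(results, function(x) x$n, integer(1)),
    stringsAsFactors = FALSE
  )
}
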