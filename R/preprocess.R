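#' Compute dye-oriented log-ratios (M) and mean intensities (A)
#'
#' For each feature, M is the log2 ratio of the experimental over the
#' control channel, oriented using the recorded dye assignment so that
#' positive M always means experimental > control regardless of which dye
#' carried the experimental sample; A is the mean log2 intensity of the two
#' raw channels. One MA record per (feature, replicate, time, condition).
#'
#' @param arrays Two-color table with columns `feature_id`, `cy3`, `cy5`,
#'   `dye_experimental` ("Cy3"/"Cy5"), `replicate`, `time_min`, `condition`.
#' @return Tibble with the identifying columns plus `M` and `A`.
#' @export
compute_ratios <- function(arrays) {
  check_columns(arrays, c("feature_id", "cy3", "cy5", "dye_experimental",
                          "replicate", "time_min", "condition"), "arrays")
  bad <- !is.finite(arrays$cy3) | !is.finite(arrays$cy5) |
    arrays$cy3 <= 0 | arrays$cy5 <= 0
  if (any(bad)) {
    abort(sprintf("non-positive intensity for feature(s): %s",
                  paste(utils::head(unique(arrays$feature_id[bad]), 5),
                        collapse = ", ")))
  }
  if (!all(arrays$dye_experimental %in% c("Cy3", "Cy5"))) {
    abort("`dye_experimental` must be 'Cy3' or 'Cy5'.")
  }
  s <- ifelse(arrays$dye_experimental == "Cy5", 1, -1)
  tibble(
    feature_id = arrays$feature_id,
    condition = arrays$condition,
    time_min = arrays$time_min,
    replicate = arrays$replicate,
    dye_experimental = arrays$dye_experimental,
    M = s * log2(arrays$cy5 / arrays$cy3),
    A = 0.5 * log2(arrays$cy3 * arrays$cy5)
  )
}

# Robust local regression of M on A for one array; returns fitted values in
# input order. lowess() evaluates at sorted unique x, so map back by linear
# interpolation (constant extrapolation at the range ends).
lowess_fit <- function(A, M, span, iter) {
  fit <- lowess(A, M, f = span, iter = iter)
  approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
}

#' Per-array LOWESS normalization of MA data
#'
#' Removes intensity-dependent dye bias by fitting a robust locally weighted
#' regression of M on A separately for each array (each
#' condition/replicate/time combination) and subtracting the fitted trend.
#' Arrays with fewer than 20 features fall back to median-centering with a
#' warning, since a local fit is not meaningful there.
#'
#' @param ma MA tibble from [compute_ratios()].
#' @param span LOWESS span (fraction of points per local fit), in (0, 1].
#' @param iter Robustness iterations.
#' @return The input tibble, row order preserved, with `M` replaced by the
#'   residual from the per-array trend and the trend kept in `fitted`.
#' @export
lowess_normalize <- function(ma, span = 0.3, iter = 3) {
  check_columns(ma, c("feature_id", "condition", "time_min", "replicate",
                      "M", "A"), "ma")
  check_scalar_number(span, "span", lower = 0, upper = 1,
                      strict_lower = TRUE)
  iter <- check_count(iter, "iter", lower = 0L)
  ma <- as_tibble(ma)
  key <- paste(ma$condition, ma$replicate, ma$time_min, sep = "\r")
  fitted <- numeric(nrow(ma))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 20L) {
      warn(sprintf(
        "array %s has %d features (< 20); median-centering instead of LOWESS",
        gsub("\r", "/", k), length(idx)))
      fitted[idx] <- median(ma$M[idx])
    } else {
      fitted[idx] <- lowess_fit(ma$A[idx], ma$M[idx], span, iter)
    }
  }
  ma$fitted <- fitted
  ma$M <- ma$M - fitted
  ma
}

#' Assemble normalized arrays into an expression series
#'
#' Collects per-array MA records into the long gene x time x replicate
#' series consumed by the differential-expression and inference stages.
#' Duplicate (gene, condition, time, replicate) records are an error;
#' missing cells are simply absent (never imputed as zero). Genes missing in
#' more than one replicate at some time point are reported with a warning.
#'
#' @param ma MA tibble (normalized or raw).
#' @param design Optional [array_design()]; when given, replicate ids and
#'   time points are checked against it.
#' @return Expression-series tibble: `gene`, `condition`, `time_min`,
#'   `replicate`, `M`.
#' @export
assemble_series <- function(ma, design = NULL) {
  check_columns(ma, c("feature_id", "condition", "time_min", "replicate",
                      "M"), "ma")
  out <- tibble(gene = ma$feature_id, condition = ma$condition,
                time_min = ma$time_min, replicate = ma$replicate, M = ma$M)
  dup <- duplicated(out[c("gene", "condition", "time_min", "replicate")])
  if (any(dup)) {
    abort(sprintf("duplicate series record(s), e.g. gene %s at t=%s",
                  out$gene[dup][1], out$time_min[dup][1]))
  }
  if (!is.null(design)) {
    stopifnot(inherits(design, "array_design"))
    reps <- design_replicates(design)
    if (!all(out$replicate %in% reps$replicate)) {
      abort("series contains replicate ids not in `design`.")
    }
    if (!all(out$time_min %in% design$time_points_min)) {
      abort("series contains time points not in `design`.")
    }
    n_rep <- nrow(reps)
  } else {
    n_rep <- length(unique(out$replicate))
  }
  counts <- dplyr::count(out, .data$gene, .data$condition, .data$time_min)
  low <- counts$n < n_rep - 1L
  if (any(low)) {
    warn(sprintf(
      "%d gene/time cell(s) are missing in more than one replicate",
      sum(low)))
  }
  dplyr::arrange(out, .data$condition, .data$gene, .data$time_min,
                 .data$replicate)
}

#' Full preprocessing chain from raw arrays to an expression series
#'
#' Ratio computation, per-array LOWESS normalization and series assembly in
#' one call.
#'
#' @inheritParams compute_ratios
#' @inheritParams lowess_normalize
#' @inheritParams assemble_series
#' @return Expression-series tibble.
#' @export
preprocess_arrays <- function(arrays, span = 0.3, iter = 3, design = NULL) {
  arrays |>
    compute_ratios() |>
    lowess_normalize(span = span, iter = iter) |>
    assemble_series(design = design)
}
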