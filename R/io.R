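#' Read / write a two-color array table
#'
#' Tab-delimited long format, one record per (feature, replicate, time,
#' condition), with columns `feature_id`, `cy3`, `cy5`, `dye_experimental`,
#' `replicate`, `time_min`, `condition`.
#'
#' @param path File path.
#' @return `read_array_table()` returns the table as a tibble;
#'   `write_array_table()` returns `path` invisibly.
#' @export
read_array_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), cy3 = readr::col_double(),
    cy5 = readr::col_double(), dye_experimental = readr::col_character(),
    replicate = readr::col_character(), time_min = readr::col_double(),
    condition = readr::col_character()
  ))
}

#' @rdname read_array_table
#' @param arrays Two-color table tibble.
#' @export
write_array_table <- function(arrays, path) {
  check_columns(arrays, c("feature_id", "cy3", "cy5", "dye_experimental",
                          "replicate", "time_min", "condition"), "arrays")
  readr::write_tsv(arrays, path)
  invisible(path)
}

#' Read / write an expression series
#'
#' Tab-delimited long format (`gene`, `condition`, `time_min`, `replicate`,
#' `M`), optionally with a JSON sidecar (same path + `.design.json`)
#' recording the experimental design.
#'
#' @param path TSV path.
#' @param design Optional [array_design()] written to the sidecar.
#' @return `read_series()` returns the series tibble; if a design sidecar is
#'   present it is attached as attribute `design`.
#' @export
read_series <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), condition = readr::col_character(),
    time_min = readr::col_double(), replicate = readr::col_character(),
    M = readr::col_double()
  ))
  sidecar <- paste0(path, ".design.json")
  if (file.exists(sidecar)) {
    d <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "design") <- array_design(d$time_points_min, d$n_bio,
                                        d$n_dye_swap, d$conditions)
  }
  out
}

#' @rdname read_series
#' @param series Expression-series tibble.
#' @export
write_series <- function(series, path, design = NULL) {
  check_columns(series, c("gene", "condition", "time_min", "replicate", "M"),
                "series")
  readr::write_tsv(series, path)
  if (!is.null(design)) {
    stopifnot(inherits(design, "array_design"))
    jsonlite::write_json(unclass(design), paste0(path, ".design.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write a ground-truth bundle
#'
#' A directory holding `network.tsv` (edges with signs and weights),
#' `activities.tsv`, `baselines.tsv` and `meta.json` (noise level and
#' design). Round-trips a `tf_ground_truth` object losslessly.
#'
#' @param dir Directory path (created if needed).
#' @return `read_ground_truth()` returns a `tf_ground_truth`;
#'   `write_ground_truth()` returns `dir` invisibly.
#' @export
read_ground_truth <- function(dir) {
  net <- readr::read_tsv(file.path(dir, "network.tsv"),
                         col_types = readr::cols(
                           tf = readr::col_character(),
                           gene = readr::col_character(),
                           sign = readr::col_integer(),
                           weight = readr::col_double()))
  act <- readr::read_tsv(file.path(dir, "activities.tsv"),
                         col_types = readr::cols(
                           tf = readr::col_character(),
                           time_min = readr::col_double(),
                           activity = readr::col_double()))
  base <- readr::read_tsv(file.path(dir, "baselines.tsv"),
                          col_types = readr::cols(
                            gene = readr::col_character(),
                            baseline = readr::col_double()))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(network = net, activities = act, baselines = base,
         noise_sd = meta$noise_sd,
         design = array_design(meta$design$time_points_min,
                               meta$design$n_bio, meta$design$n_dye_swap,
                               meta$design$conditions)),
    class = "tf_ground_truth"
  )
}

#' @rdname read_ground_truth
#' @param truth A `tf_ground_truth` object.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "tf_ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(truth$network, file.path(dir, "network.tsv"))
  readr::write_tsv(truth$activities, file.path(dir, "activities.tsv"))
  readr::write_tsv(truth$baselines, file.path(dir, "baselines.tsv"))
  jsonlite::write_json(
    list(noise_sd = truth$noise_sd, design = unclass(truth$design)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write fit results as TSV + JSON report
#'
#' Writes `activities.tsv` (tf, time_min, mean, sd), `weights.tsv`
#' (tf, gene, mean, sd) and `fit.json` (iterations, ELBO trace, noise
#' variance, dropped genes, convergence flag) into `dir`.
#'
#' @param fit A `tf_activity_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "tf_activity_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(fit$activities, file.path(dir, "activities.tsv"))
  readr::write_tsv(fit$weights, file.path(dir, "weights.tsv"))
  jsonlite::write_json(
    list(iterations = fit$iterations, elbo = fit$elbo,
         noise_variance = fit$noise_variance, converged = fit$converged,
         dropped_genes = fit$dropped_genes, condition = fit$condition,
         flipped = as.list(fit$flipped)),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
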