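#' Describe a dye-swap time-course array design
#'
#' The default design is a pre-treatment reference sample (0 min) followed by
#' five post-treatment samples, with four replicates per condition: two
#' biological repeats, each hybridized twice with the dye assignment of the
#' experimental and control channels exchanged (dye swap).
#'
#' @param time_points_min Strictly increasing sampling times in minutes; the
#'   first is the pre-treatment reference.
#' @param n_bio Number of biological repeats.
#' @param n_dye_swap Number of technical dye-swap repeats per biological
#'   repeat.
#' @param conditions Character vector of condition labels.
#' @return An object of class `array_design` (a list).
#' @export
array_design <- function(time_points_min = c(0, 10, 20, 40, 60, 120),
                         n_bio = 2, n_dye_swap = 2,
                         conditions = "treated") {
  if (length(time_points_min) < 2L || any(diff(time_points_min) <= 0)) {
    abort("`time_points_min` must be strictly increasing with >= 2 points.")
  }
  n_bio <- check_count(n_bio, "n_bio")
  n_dye_swap <- check_count(n_dye_swap, "n_dye_swap")
  if (!is.character(conditions) || length(conditions) < 1L) {
    abort("`conditions` must be a non-empty character vector.")
  }
  structure(
    list(time_points_min = as.numeric(time_points_min), n_bio = n_bio,
         n_dye_swap = n_dye_swap, conditions = conditions),
    class = "array_design"
  )
}

#' @export
print.array_design <- function(x, ...) {
  cat("<array_design> ", length(x$time_points_min), " time points (",
      paste(x$time_points_min, collapse = ", "), " min); ",
      x$n_bio, " bio x ", x$n_dye_swap, " dye-swap replicates; conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Replicate layout of a design
#'
#' One row per hybridization replicate, recording which dye carried the
#' experimental (treated) sample. Odd dye-swap repeats put the experimental
#' sample on Cy5, even repeats on Cy3.
#'
#' @param design An [array_design()].
#' @return Tibble with columns `replicate`, `bio`, `swap`,
#'   `dye_experimental`.
#' @export
design_replicates <- function(design) {
  stopifnot(inherits(design, "array_design"))
  grid <- tidyr::expand_grid(bio = seq_len(design$n_bio),
                             swap = seq_len(design$n_dye_swap))
  tibble(
    replicate = sprintf("b%d.s%d", grid$bio, grid$swap),
    bio = grid$bio, swap = grid$swap,
    dye_experimental = ifelse(grid$swap %% 2L == 1L, "Cy5", "Cy3")
  )
}

#' Simulate latent TF activity trajectories
#'
#' A fraction `frac_responsive` of TFs (count `round(frac * n_tfs)`) receives
#' a smooth response trajectory; the rest stay identically zero. All
#' trajectories are zero at the first (pre-treatment) time point, the
#' reference against which activity changes are expressed. Two shape families
#' are drawn at random: a saturating rise `1 - exp(-t/tau)` and a transient
#' pulse `(t/tp) * exp(1 - t/tp)` peaking at `tp`, each scaled to a peak
#' magnitude near `amplitude` with a random overall sign.
#'
#' @param network Edge-list tibble (defines the TF set).
#' @param design An [array_design()].
#' @param amplitude Approximate peak |activity change| of responsive TFs.
#' @param frac_responsive Fraction of TFs that respond.
#' @param seed Integer seed.
#' @return Tibble with columns `tf`, `time_min`, `activity`.
#' @export
simulate_activities <- function(network, design, amplitude = 2,
                                frac_responsive = 0.5, seed = 1) {
  check_columns(network, c("tf", "gene"), "network")
  stopifnot(inherits(design, "array_design"))
  check_scalar_number(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  check_scalar_number(frac_responsive, "frac_responsive", 0, 1)

  tf_ids <- sort(unique(network$tf))
  tt <- design$time_points_min
  t0 <- tt[1]
  n_resp <- round(frac_responsive * length(tf_ids))

  withr_seed(seed, {
    responsive <- sample(tf_ids, n_resp)
    prof <- purrr::map(tf_ids, function(f) {
      if (!f %in% responsive) return(rep(0, length(tt)))
      a <- amplitude * runif(1, 0.8, 1.2) * sample(c(-1, 1), 1)
      td <- tt - t0
      if (runif(1) < 0.5) {
        tau <- runif(1, 10, 40)
        a * (1 - exp(-td / tau))
      } else {
        tp <- runif(1, 10, 60)
        a * (td / tp) * exp(1 - td / tp)
      }
    })
  })
  tibble(
    tf = rep(tf_ids, each = length(tt)),
    time_min = rep(tt, length(tf_ids)),
    activity = unlist(prof)
  )
}

#' Assemble a ground-truth object for expression simulation
#'
#' Draws regulatory weights on the network edges (magnitude uniform on
#' `weight_range`, sign taken from the edge annotation where known, random
#' otherwise) and per-gene baseline log2-ratio offsets, and bundles them with
#' the activity trajectories and noise level into a `tf_ground_truth` object.
#'
#' @param network Edge-list tibble (`tf`, `gene`, `sign`).
#' @param activities Tibble from [simulate_activities()].
#' @param design An [array_design()].
#' @param noise_sd Gaussian noise standard deviation on the log2-ratio scale.
#' @param baseline_sd Standard deviation of per-gene baseline offsets.
#' @param weight_range Range of |weight| magnitudes.
#' @param seed Integer seed.
#' @return A `tf_ground_truth` list: `network` (edges + `weight` column),
#'   `activities`, `baselines` (tibble `gene`, `baseline`), `noise_sd`,
#'   `design`.
#' @export
simulate_truth <- function(network, activities, design, noise_sd = 0.2,
                           baseline_sd = 0.2, weight_range = c(0.5, 1.5),
                           seed = 1) {
  check_columns(network, c("tf", "gene", "sign"), "network")
  check_columns(activities, c("tf", "time_min", "activity"), "activities")
  stopifnot(inherits(design, "array_design"))
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(baseline_sd, "baseline_sd", lower = 0)

  gene_ids <- sort(unique(network$gene))
  withr_seed(seed, {
    mag <- runif(nrow(network), weight_range[1], weight_range[2])
    sgn <- ifelse(network$sign != 0, network$sign,
                  sample(c(-1, 1), nrow(network), replace = TRUE))
    net <- dplyr::mutate(network, weight = mag * sgn)
    baselines <- tibble(gene = gene_ids,
                        baseline = rnorm(length(gene_ids), 0, baseline_sd))
  })
  structure(
    list(network = net, activities = activities, baselines = baselines,
         noise_sd = noise_sd, design = design),
    class = "tf_ground_truth"
  )
}

#' Simulate a log2-ratio expression time series from ground truth
#'
#' Each observation is the log-linear combination of the activities of the
#' gene's regulators plus the gene baseline and independent Gaussian noise:
#' `x[g,t,r] = baseline[g] + sum_f weight[g,f] * activity[f,t] + eps`,
#' with `eps ~ N(0, noise_sd^2)` drawn independently per gene, time and
#' replicate, all on the log2 scale.
#'
#' @param truth A `tf_ground_truth` from [simulate_truth()].
#' @param condition Condition label for the generated series.
#' @param seed Integer seed.
#' @return An expression-series tibble with columns `gene`, `condition`,
#'   `time_min`, `replicate`, `M`.
#' @export
simulate_expression <- function(truth, condition = NULL, seed = 1) {
  stopifnot(inherits(truth, "tf_ground_truth"))
  design <- truth$design
  condition <- condition %||% design$conditions[1]
  mats <- network_matrices(truth$network)
  gene_ids <- rownames(mats$connectivity)
  tf_ids <- colnames(mats$connectivity)
  B <- mats$connectivity * 0
  idx <- cbind(match(truth$network$gene, gene_ids),
               match(truth$network$tf, tf_ids))
  B[idx] <- truth$network$weight

  tt <- design$time_points_min
  act <- dplyr::arrange(truth$activities, .data$tf, .data$time_min)
  C <- matrix(act$activity, nrow = length(tf_ids), byrow = TRUE,
              dimnames = list(sort(unique(act$tf)), NULL))
  if (!identical(rownames(C), tf_ids) || ncol(C) != length(tt)) {
    abort("activities do not match the network TF set / design time grid.")
  }
  signal <- B %*% C  # genes x times, noise-free activity contribution
  mu <- truth$baselines$baseline[match(gene_ids, truth$baselines$gene)]

  reps <- design_replicates(design)
  grid <- tidyr::expand_grid(gene = gene_ids, time_min = tt,
                             replicate = reps$replicate)
  noise_free <- mu[match(grid$gene, gene_ids)] +
    signal[cbind(match(grid$gene, gene_ids), match(grid$time_min, tt))]
  withr_seed(seed, {
    eps <- rnorm(nrow(grid), 0, truth$noise_sd)
  })
  tibble(gene = grid$gene, condition = condition,
         time_min = grid$time_min, replicate = grid$replicate,
         M = noise_free + eps)
}

# Intensity-dependent dye bias: inflation of the Cy5/Cy3 log-ratio at low
# mean intensity, decaying smoothly to zero at high intensity.
dye_bias_curve <- function(A, bias_amplitude, a_min = 6, decay = 1.5) {
  bias_amplitude * exp(-(A - a_min) / decay)
}

#' Render an expression series as raw two-color array intensities
#'
#' Inverts the preprocessing chain for simulation: each (gene, replicate,
#' time) observation is assigned a mean log2 intensity `A ~ Uniform(6, 14)`
#' and split into Cy3/Cy5 channel intensities so that the dye-oriented
#' log2-ratio equals the series value plus a dye-attached, intensity-dependent
#' bias `d(A) = bias_amplitude * exp(-(A - 6)/1.5)` (low-intensity inflation
#' of the Cy5/Cy3 ratio, maximal |d| = `bias_amplitude`). Dye-swap replicates
#' have the experimental sample on opposite dyes, so the raw Cy5/Cy3
#' log-ratios of a swap pair are (bias aside) sign-opposed. Channels are
#' floored at 1 before any later log transform.
#'
#' @param expr Expression-series tibble (`gene`, `condition`, `time_min`,
#'   `replicate`, `M`).
#' @param design An [array_design()] (supplies the dye assignment per
#'   replicate).
#' @param bias_amplitude Peak absolute dye bias in log2 units; 0 disables.
#' @param seed Integer seed (drives the A values).
#' @return A two-color table: `feature_id`, `cy3`, `cy5`,
#'   `dye_experimental`, `replicate`, `time_min`, `condition`.
#' @export
render_two_color <- function(expr, design, bias_amplitude = 0, seed = 1) {
  check_columns(expr, c("gene", "condition", "time_min", "replicate", "M"),
                "expr")
  stopifnot(inherits(design, "array_design"))
  if (!all(is.finite(expr$M))) abort("`expr$M` must be finite.")
  check_scalar_number(bias_amplitude, "bias_amplitude", lower = 0)

  reps <- design_replicates(design)
  dye <- reps$dye_experimental[match(expr$replicate, reps$replicate)]
  if (anyNA(dye)) abort("replicate ids in `expr` not found in `design`.")
  withr_seed(seed, {
    A <- runif(nrow(expr), 6, 14)
  })
  s <- ifelse(dye == "Cy5", 1, -1)
  # raw Cy5/Cy3 log-ratio: oriented signal plus dye-attached bias
  m_raw <- s * expr$M + dye_bias_curve(A, bias_amplitude)
  tibble(
    feature_id = expr$gene,
    cy3 = pmax(2^(A - m_raw / 2), 1),
    cy5 = pmax(2^(A + m_raw / 2), 1),
    dye_experimental = dye,
    replicate = expr$replicate,
    time_min = expr$time_min,
    condition = expr$condition
  )
}

#' Exactly remove a known simulated dye bias
#'
#' Bookkeeping inverse of [render_two_color()]: recomputes the oriented
#' log2-ratio from the channels, subtracts the known bias curve at the
#' feature's mean intensity, and returns the expression series. With the
#' correct `bias_amplitude` this recovers the input of [render_two_color()]
#' to machine precision.
#'
#' @param arrays Two-color table from [render_two_color()].
#' @param bias_amplitude The bias amplitude used at rendering time.
#' @return Expression-series tibble (`gene`, `condition`, `time_min`,
#'   `replicate`, `M`).
#' @export
debias_two_color <- function(arrays, bias_amplitude = 0) {
  check_columns(arrays, c("feature_id", "cy3", "cy5", "dye_experimental",
                          "replicate", "time_min", "condition"), "arrays")
  A <- 0.5 * log2(arrays$cy3 * arrays$cy5)
  m_raw <- log2(arrays$cy5 / arrays$cy3) - dye_bias_curve(A, bias_amplitude)
  s <- ifelse(arrays$dye_experimental == "Cy5", 1, -1)
  tibble(gene = arrays$feature_id, condition = arrays$condition,
         time_min = arrays$time_min, replicate = arrays$replicate,
         M = s * m_raw)
}

#' Simulate a complete two-color time-course dataset
#'
#' Convenience orchestrator: network, activities, ground truth, expression
#' and raw arrays in one call. Stage seeds are derived from the run-level
#' `seed` by fixed offsets so each stage is independently reproducible.
#'
#' @inheritParams simulate_network
#' @inheritParams simulate_activities
#' @inheritParams simulate_truth
#' @inheritParams render_two_color
#' @param design An [array_design()].
#' @param condition Condition label.
#' @return List with `truth` (`tf_ground_truth`), `expression` (series
#'   tibble) and `arrays` (two-color table).
#' @export
simulate_dataset <- function(n_tfs = 10, n_genes = 200, mean_regulators = 2,
                             frac_signed = 0.5, amplitude = 2,
                             frac_responsive = 0.5, noise_sd = 0.2,
                             baseline_sd = 0.2, bias_amplitude = 0,
                             design = array_design(), condition = NULL,
                             seed = 1) {
  net <- simulate_network(n_tfs, n_genes, mean_regulators, frac_signed,
                          seed = derive_seed(seed, 1))
  act <- simulate_activities(net, design, amplitude, frac_responsive,
                             seed = derive_seed(seed, 2))
  truth <- simulate_truth(net, act, design, noise_sd = noise_sd,
                          baseline_sd = baseline_sd,
                          seed = derive_seed(seed, 3))
  expr <- simulate_expression(truth, condition = condition,
                              seed = derive_seed(seed, 4))
  arrays <- render_two_color(expr, design, bias_amplitude = bias_amplitude,
                             seed = derive_seed(seed, 5))
  list(truth = truth, expression = expr, arrays = arrays)
}
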