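#' Can a constant time series fit within the error bars?
#'
#' A TF profile carries no inferable response if some constant value lies
#' inside every error bar, i.e. there exists `k` with
#' `|mean[t] - k| <= z * sd[t]` for all `t`. That holds exactly when the
#' intervals `[mean - z*sd, mean + z*sd]` have a common point:
#' `max(mean - z*sd) <= min(mean + z*sd)` -- an exact interval-intersection
#' test, no search required. Such profiles are discarded before
#' cross-condition scoring.
#'
#' @param mean Numeric profile of posterior means (length >= 2).
#' @param sd Matching profile of posterior standard deviations (all > 0).
#' @param z Error-bar multiplier (z = 1: literal 1-sd bars; default z = 2).
#' @return `TRUE` if a constant fits (profile non-responsive), else `FALSE`.
#' @export
is_constant_within_errorbars <- function(mean, sd, z = 2) {
  if (length(mean) != length(sd)) {
    abort("`mean` and `sd` must have the same length.")
  }
  if (length(mean) < 2L) abort("profiles must have >= 2 time points.")
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd <= 0)) {
    abort("`mean` must be finite and `sd` strictly positive.")
  }
  check_scalar_number(z, "z", lower = 0, strict_lower = TRUE)
  max(mean - z * sd) <= min(mean + z * sd)
}

as_activity_profiles <- function(x, name) {
  if (inherits(x, "tf_activity_fit")) x <- x$activities
  check_columns(x, c("tf", "time_min", "mean", "sd"), name)
  as_tibble(x)
}

#' Score TF behaviour across two conditions
#'
#' Implements the cross-condition concordance scoring of inferred TF
#' profiles. Per TF shared between the two fits: (1) the non-responsiveness
#' discard test ([is_constant_within_errorbars()]) is applied in each
#' condition; (2) a TF discarded in both conditions gets status
#' `both_discarded` and no score; (3) a TF discarded in exactly one
#' condition gets the sentinel score 2 (`a_only` / `b_only`: responsive in
#' that condition only), deliberately outside the correlation range; (4) a
#' TF retained in both gets the absolute Pearson correlation of its two mean
#' profiles, in [0, 1] -- the absolute value is taken because each profile's
#' sign is a model gauge, so perfect anti-correlation is as concordant as
#' perfect correlation. When a signed network is supplied, profiles whose
#' weights contradict the annotation are flipped first (bookkeeping only:
#' flips cannot change |r|). The pre-treatment reference time point is
#' dropped from the correlation by default, since it is 0 by convention in
#' every profile and would inflate concordance.
#'
#' @param a,b Two `tf_activity_fit` objects or tidy activity tibbles
#'   (`tf`, `time_min`, `mean`, `sd`) on the same time grid.
#' @param z Error-bar multiplier for the discard test.
#' @param include_t0 Include the first time point in the correlation.
#' @param network Optional signed edge list for the sign-flip correction
#'   (used only when `a` and `b` are full fits carrying weights).
#' @param condition_a,condition_b Labels for the report.
#' @return Tibble `tf`, `status` (`both_retained`, `a_only`, `b_only`,
#'   `both_discarded`), `score` (|r| in [0,1], 2 for one-sided, NA for
#'   `both_discarded`), `flipped_a`, `flipped_b`.
#' @export
compare_conditions <- function(a, b, z = 2, include_t0 = FALSE,
                               network = NULL,
                               condition_a = "A", condition_b = "B") {
  flip_a <- flip_b <- character(0)
  if (!is.null(network)) {
    if (inherits(a, "tf_activity_fit")) {
      rep_a <- sign_ambiguity_report(a, network)
      flip_a <- rep_a$tf[rep_a$status == "flipped"]
      a <- flip_profile(a, flip_a)
    }
    if (inherits(b, "tf_activity_fit")) {
      rep_b <- sign_ambiguity_report(b, network)
      flip_b <- rep_b$tf[rep_b$status == "flipped"]
      b <- flip_profile(b, flip_b)
    }
  }
  pa <- as_activity_profiles(a, "a")
  pb <- as_activity_profiles(b, "b")
  tfs <- sort(intersect(unique(pa$tf), unique(pb$tf)))
  only <- c(setdiff(unique(pa$tf), tfs), setdiff(unique(pb$tf), tfs))
  if (length(only) > 0L) {
    warn(sprintf("%d TF(s) present in only one condition were skipped: %s",
                 length(only), paste(sort(only), collapse = ", ")))
  }
  if (length(tfs) == 0L) abort("no TFs shared between the two conditions.")
  grid_a <- sort(unique(pa$time_min))
  grid_b <- sort(unique(pb$time_min))
  if (!identical(grid_a, grid_b)) {
    abort("the two conditions are on different time grids.")
  }
  use_t <- if (include_t0) grid_a else grid_a[-1]
  if (length(use_t) < 2L) {
    abort("need >= 2 time points for the correlation (after t0 handling).")
  }

  rows <- purrr::map(tfs, function(f) {
    prof_a <- dplyr::arrange(pa[pa$tf == f, ], .data$time_min)
    prof_b <- dplyr::arrange(pb[pb$tf == f, ], .data$time_min)
    disc_a <- is_constant_within_errorbars(prof_a$mean, prof_a$sd, z)
    disc_b <- is_constant_within_errorbars(prof_b$mean, prof_b$sd, z)
    status <- if (disc_a && disc_b) "both_discarded"
      else if (disc_b) "a_only"
      else if (disc_a) "b_only"
      else "both_retained"
    score <- NA_real_
    if (status %in% c("a_only", "b_only")) score <- 2
    if (status == "both_retained") {
      ma <- prof_a$mean[prof_a$time_min %in% use_t]
      mb <- prof_b$mean[prof_b$time_min %in% use_t]
      if (sd(ma) == 0 || sd(mb) == 0) {
        warn(sprintf(
          "TF %s retained with a zero-variance profile; score undefined", f))
      } else {
        score <- abs(cor(ma, mb))
      }
    }
    tibble(tf = f, status = status, score = score)
  })
  out <- dplyr::bind_rows(rows)
  out$flipped_a <- out$tf %in% flip_a
  out$flipped_b <- out$tf %in% flip_b
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  attr(out, "z") <- z
  out
}

#' Rank TFs by cross-condition concordance
#'
#' Partitions comparison scores into `concordant` (score >=
#' `concordant_min`), `discordant` (score <= `discordant_max`),
#' `intermediate` (between the two), `condition_specific` (sentinel score
#' 2) and `unresponsive` (discarded in both conditions), ordered by
#' descending score within each partition with lexicographic TF-id
#' tie-breaking. The sentinel never enters any score summary.
#'
#' @param scores Tibble from [compare_conditions()].
#' @param concordant_min,discordant_max Partition thresholds on |r|.
#' @return The input tibble with a `partition` column, reordered.
#' @export
rank_tfs <- function(scores, concordant_min = 0.8, discordant_max = 0.3) {
  check_columns(scores, c("tf", "status", "score"), "scores")
  check_scalar_number(concordant_min, "concordant_min", 0, 1)
  check_scalar_number(discordant_max, "discordant_max", 0, 1)
  scores |>
    dplyr::mutate(partition = dplyr::case_when(
      .data$status == "both_discarded" ~ "unresponsive",
      .data$status %in% c("a_only", "b_only") ~ "condition_specific",
      is.na(.data$score) ~ "anomalous",
      .data$score >= concordant_min ~ "concordant",
      .data$score <= discordant_max ~ "discordant",
      .default = "intermediate"
    )) |>
    dplyr::mutate(partition = factor(
      .data$partition,
      levels = c("concordant", "intermediate", "discordant",
                 "condition_specific", "unresponsive", "anomalous")
    )) |>
    dplyr::arrange(.data$partition, dplyr::desc(.data$score), .data$tf)
}
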