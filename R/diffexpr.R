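#' One-sample t-test of replicate log-ratios against no change
#'
#' Two-sided one-sample t-test of the replicate log2 ratios at one
#' (gene, time) cell against `null_mean` (0 = no change), with explicit
#' policies for the degenerate cases a 4-replicate design can produce:
#' fewer than 2 non-missing values is "untestable" (p = NA); replicates all
#' exactly equal to the null mean give p = 1 (no evidence of change);
#' replicates all equal but different from the null mean have zero sample
#' variance and get the sentinel p = 0 with a flag (change without
#' measurable noise).
#'
#' @param values Numeric replicate log2 ratios (NAs dropped).
#' @param null_mean Null hypothesis mean.
#' @return One-row tibble: `n`, `mean`, `t`, `p`, `zero_variance`,
#'   `testable`.
#' @export
t_test_ratios <- function(values, null_mean = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) {
    return(tibble(n = n, mean = if (n) mean(values) else NA_real_,
                  t = NA_real_, p = NA_real_, zero_variance = FALSE,
                  testable = FALSE))
  }
  m <- mean(values)
  if (sd(values) == 0) {
    p <- if (m == null_mean) 1 else 0
    return(tibble(n = n, mean = m, t = if (m == null_mean) 0 else Inf,
                  p = p, zero_variance = TRUE, testable = TRUE))
  }
  ht <- t.test(values, mu = null_mean)
  tibble(n = n, mean = m, t = unname(ht$statistic), p = ht$p.value,
         zero_variance = FALSE, testable = TRUE)
}

#' Call differentially expressed genes per time point
#'
#' For each (gene, condition, time) cell: averages the replicate log2
#' ratios, converts to a signed fold change, tests the replicates against 0
#' with [t_test_ratios()], and flags the cell significant iff the mean
#' |log2 ratio| reaches `log2(fold_cutoff)` AND p < `alpha`. No
#' multiple-testing correction gates the call; a Benjamini-Hochberg adjusted
#' p-value is reported alongside for transparency, and the number of tests
#' performed is attached as attribute `n_tests`.
#'
#' @param series Expression-series tibble (`gene`, `condition`, `time_min`,
#'   `replicate`, `M`).
#' @param fold_cutoff Fold-change gate (on the natural fold scale; default 2,
#'   i.e. |mean log2 ratio| >= 1).
#' @param alpha Significance level for the t-test (strict inequality).
#' @return Tibble with one row per (gene, condition, time): `gene`,
#'   `condition`, `time_min`, `n`, `mean_log2`, `fold_change` (signed:
#'   negative values are fold down), `t`, `p`, `p_bh`, `significant`,
#'   `direction` ("up"/"down"/"none").
#' @export
call_de <- function(series, fold_cutoff = 2, alpha = 0.05) {
  check_columns(series, c("gene", "condition", "time_min", "replicate", "M"),
                "series")
  check_scalar_number(fold_cutoff, "fold_cutoff", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE)

  calls <- series |>
    dplyr::group_by(.data$gene, .data$condition, .data$time_min) |>
    dplyr::summarise(t_test_ratios(.data$M), .groups = "drop")
  fc <- 2^abs(calls$mean)
  calls <- calls |>
    dplyr::rename(mean_log2 = "mean") |>
    dplyr::mutate(
      fold_change = ifelse(.data$mean_log2 >= 0, fc, -fc),
      p_bh = p.adjust(.data$p, method = "BH"),
      significant = .data$testable & !is.na(.data$p) &
        abs(.data$mean_log2) >= log2(fold_cutoff) & .data$p < alpha,
      direction = dplyr::case_when(
        .data$significant & .data$mean_log2 > 0 ~ "up",
        .data$significant & .data$mean_log2 < 0 ~ "down",
        .default = "none"
      )
    ) |>
    dplyr::select("gene", "condition", "time_min", "n", "mean_log2",
                  "fold_change", "t", "p", "p_bh", "zero_variance",
                  "significant", "direction")
  attr(calls, "n_tests") <- sum(!is.na(calls$p))
  calls
}

#' Summarize fold changes across conditions and times
#'
#' Builds the wide per-gene summary table: one row per gene, one column per
#' (condition, time) combination holding the signed mean fold change, with a
#' trailing `*` marking cells whose t-test p-value exceeds `alpha` (the
#' fold change is shown but not statistically supported). Genes absent from
#' the annotation are filled in as "unannotated" with a warning.
#'
#' @param calls DE-call tibble from [call_de()] (one or more conditions
#'   bound together).
#' @param annotation Optional tibble `gene`, `product`, `category`,
#'   `regulators`.
#' @param alpha Flagging threshold for the asterisk.
#' @param digits Rounding for the displayed fold changes.
#' @return Wide tibble: `gene`, annotation columns, then one character
#'   column per `<condition>_t<time>` cell.
#' @export
summarize_fold_changes <- function(calls, annotation = NULL, alpha = 0.05,
                                   digits = 2) {
  check_columns(calls, c("gene", "condition", "time_min", "fold_change",
                         "p"), "calls")
  if (nrow(calls) == 0L) {
    return(tibble(gene = character()))
  }
  cells <- calls |>
    dplyr::mutate(
      cell = paste0(formatC(round(.data$fold_change, digits),
                            format = "fg"),
                    ifelse(!is.na(.data$p) & .data$p > alpha, "*", "")),
      column = paste0(.data$condition, "_t", .data$time_min)
    ) |>
    dplyr::select("gene", "column", "cell") |>
    tidyr::pivot_wider(names_from = "column", values_from = "cell")
  if (!is.null(annotation)) {
    check_columns(annotation, c("gene", "product", "category", "regulators"),
                  "annotation")
    missing <- setdiff(cells$gene, annotation$gene)
    if (length(missing) > 0L) {
      warn(sprintf("%d gene(s) without annotation, filled as 'unannotated'",
                   length(missing)))
    }
    cells <- cells |>
      dplyr::left_join(annotation[c("gene", "product", "category",
                                    "regulators")], by = "gene") |>
      dplyr::mutate(dplyr::across(c("product", "category", "regulators"),
                                  ~ dplyr::coalesce(.x, "unannotated"))) |>
      dplyr::relocate("product", "category", "regulators",
                      .after = "gene")
  }
  cells
}
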