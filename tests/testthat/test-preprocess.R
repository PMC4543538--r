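design <- array_design()

one_row_array <- function(cy3, cy5, dye = "Cy5") {
  tibble::tibble(feature_id = "g1", cy3 = cy3, cy5 = cy5,
                 dye_experimental = dye, replicate = "b1.s1",
                 time_min = 10, condition = "treated")
}

test_that("M is oriented by the dye assignment and A uses both channels", {
  # experimental on Cy5, twice the control: M = 1
  ma <- compute_ratios(one_row_array(cy3 = 100, cy5 = 200))
  expect_equal(ma$M, 1)
  expect_equal(ma$A, 0.5 * log2(100 * 200))
  # same fold change with the dyes swapped: identical M
  ma_sw <- compute_ratios(one_row_array(cy3 = 200, cy5 = 100, dye = "Cy3"))
  expect_equal(ma_sw$M, 1)
  # equal channels: no change
  expect_equal(compute_ratios(one_row_array(100, 100))$M, 0)
})

test_that("non-positive intensities fail loudly, naming the feature", {
  bad <- one_row_array(cy3 = 0, cy5 = 50)
  expect_error(compute_ratios(bad), "g1")
})

test_that("a constant M offset is fully absorbed by normalization", {
  arr <- tibble::tibble(
    feature_id = sprintf("g%02d", 1:50),
    cy3 = 2^seq(6, 13, length.out = 50),
    cy5 = 2 * 2^seq(6, 13, length.out = 50),   # M = +1 everywhere
    dye_experimental = "Cy5", replicate = "b1.s1", time_min = 10,
    condition = "treated"
  )
  norm <- lowess_normalize(compute_ratios(arr))
  expect_lt(max(abs(norm$M)), 1e-6)
  expect_equal(norm$feature_id, arr$feature_id)  # order preserved
})

test_that("tiny arrays fall back to median-centering with a warning", {
  arr <- tibble::tibble(
    feature_id = sprintf("g%d", 1:5), cy3 = c(100, 100, 100, 100, 100),
    cy5 = c(100, 200, 400, 400, 800), dye_experimental = "Cy5",
    replicate = "b1.s1", time_min = 10, condition = "treated"
  )
  expect_warning(norm <- lowess_normalize(compute_ratios(arr)),
                 "median-centering")
  expect_equal(norm$M, c(0, 1, 2, 2, 3) - 2)
})

test_that("LOWESS removes an injected intensity-dependent dye bias", {
  sim <- simulate_dataset(n_tfs = 10, n_genes = 4000, frac_responsive = 0,
                          noise_sd = 0.2, bias_amplitude = 1, seed = 7)
  norm <- lowess_normalize(compute_ratios(sim$arrays))
  joined <- dplyr::inner_join(
    norm, sim$expression,
    by = c(feature_id = "gene", "condition", "time_min", "replicate"))
  err <- joined |>
    dplyr::group_by(.data$replicate, .data$time_min) |>
    dplyr::mutate(decile = dplyr::ntile(.data$A, 10)) |>
    dplyr::group_by(.data$replicate, .data$time_min, .data$decile) |>
    dplyr::summarise(err = abs(mean(.data$M.x) - mean(.data$M.y)),
                     .groups = "drop")
  expect_lt(max(err$err), 0.1)
})

test_that("normalizing twice barely moves an already-normalized array", {
  sim <- simulate_dataset(n_tfs = 5, n_genes = 1000, frac_responsive = 0,
                          noise_sd = 0.01, baseline_sd = 0,
                          bias_amplitude = 1, seed = 13)
  ma <- compute_ratios(sim$arrays)
  n1 <- lowess_normalize(ma)
  n2 <- lowess_normalize(dplyr::select(n1, -"fitted"))
  key <- paste(ma$replicate, ma$time_min)
  decile <- stats::ave(ma$A, key, FUN = function(a) dplyr::ntile(a, 10))
  cell <- paste(key, decile)
  first <- abs(tapply(n1$M - ma$M, cell, mean))
  second <- abs(tapply(n2$M - n1$M, cell, mean))
  # lowess is not an exact projection, so the second pass can still shave
  # off a sliver of span-limited misfit -- but only a small fraction of
  # what the first pass removed
  expect_lt(max(second), 0.05 * max(first))

  # the median-centering fallback, by contrast, is exactly idempotent
  small <- ma[ma$replicate == "b1.s1" & ma$time_min == 10, ][1:10, ]
  suppressWarnings({
    m1 <- lowess_normalize(small)
    m2 <- lowess_normalize(dplyr::select(m1, -"fitted"))
  })
  expect_equal(m2$M, m1$M)
})

test_that("the preprocessing chain is invariant to a global dye swap", {
  sim <- simulate_dataset(n_tfs = 4, n_genes = 200, noise_sd = 0.2,
                          bias_amplitude = 0.5, seed = 5)
  swapped <- dplyr::mutate(sim$arrays, cy3 = .data$cy5, cy5 = sim$arrays$cy3,
                           dye_experimental = ifelse(
                             .data$dye_experimental == "Cy5", "Cy3", "Cy5"))
  s1 <- preprocess_arrays(sim$arrays, design = design)
  s2 <- preprocess_arrays(swapped, design = design)
  expect_equal(s1, s2)
})

test_that("zero-bias rendering and ratio computation are mutually inverse", {
  sim <- simulate_dataset(n_tfs = 4, n_genes = 50, noise_sd = 0.3, seed = 3)
  ma <- compute_ratios(sim$arrays)
  joined <- dplyr::inner_join(
    ma, sim$expression,
    by = c(feature_id = "gene", "condition", "time_min", "replicate"))
  expect_equal(joined$M.x, joined$M.y, tolerance = 1e-9)
})

test_that("series assembly enforces uniqueness and completeness", {
  sim <- simulate_dataset(n_tfs = 3, n_genes = 30, seed = 8)
  series <- preprocess_arrays(sim$arrays, design = design)
  expect_equal(nrow(series), 30 * 6 * 4)
  counts <- dplyr::count(series, gene, time_min)
  expect_true(all(counts$n == 4L))

  ma <- compute_ratios(sim$arrays)
  expect_error(assemble_series(dplyr::bind_rows(ma, ma[1, ])), "duplicate")

  one <- assemble_series(ma[ma$replicate == "b1.s1" & ma$time_min == 10, ])
  expect_equal(dim(one), c(30L, 5L))

  # missing cells stay absent and heavy missingness is flagged
  expect_warning(assemble_series(ma[-(1:50), ], design = design),
                 "missing in more than one replicate")
})
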