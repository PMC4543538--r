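design <- array_design()

test_that("the default design matches the dye-swap time-course layout", {
  expect_equal(design$time_points_min, c(0, 10, 20, 40, 60, 120))
  reps <- design_replicates(design)
  expect_equal(nrow(reps), 4L)                      # 2 bio x 2 dye-swap
  expect_setequal(reps$dye_experimental, c("Cy5", "Cy3"))
  expect_error(array_design(time_points_min = c(0, 10, 10)), "increasing")
})

test_that("activity trajectories respect the responsive-fraction rule", {
  net <- simulate_network(10, 50, 2, 0.5, seed = 1)
  act0 <- simulate_activities(net, design, frac_responsive = 0, seed = 2)
  expect_true(all(act0$activity == 0))

  act <- simulate_activities(net, design, amplitude = 2,
                             frac_responsive = 0.5, seed = 3)
  expect_true(all(act$activity[act$time_min == 0] == 0))
  peak <- tapply(abs(act$activity), act$tf, max)
  expect_equal(sum(peak > 0), 5L)                   # round(0.5 * 10)
  # responsive peaks sit near the requested amplitude
  expect_true(all(peak[peak > 0] > 2 * 0.8 * exp(1 - 120 / 10) &
                    peak[peak > 0] < 2 * 1.2))
})

test_that("noise-free expression reproduces the log-linear combination", {
  genes <- sprintf("g%02d", 1:6)
  net <- single_tf_network(genes)
  act <- simulate_activities(net, design, frac_responsive = 1, seed = 5)
  truth <- make_truth(net, act, design, weights = 1)
  expr <- simulate_expression(truth, seed = 1)
  joined <- dplyr::left_join(expr, act, by = "time_min")
  expect_equal(joined$M, joined$activity)           # x[g,t,r] = c[1,t]

  # flat activities: x equals the baseline at every time and replicate
  truth2 <- make_truth(net, dplyr::mutate(act, activity = 0), design,
                       weights = 1, baselines = 0.7)
  expr2 <- simulate_expression(truth2, seed = 1)
  expect_true(all(expr2$M == 0.7))
})

test_that("expression noise follows the stated Gaussian law", {
  sim <- simulate_dataset(n_tfs = 10, n_genes = 200, noise_sd = 0.1,
                          seed = 11)
  noise_free <- make_truth(sim$truth$network[c("tf", "gene", "sign")],
                           sim$truth$activities, design,
                           weights = sim$truth$network$weight,
                           baselines = sim$truth$baselines$baseline)
  expr0 <- simulate_expression(noise_free, seed = 99)
  eps <- sim$expression$M - expr0$M
  expect_gt(var(eps), 0.008)
  expect_lt(var(eps), 0.012)
})

test_that("two-color rendering is invertible and dye-swap symmetric", {
  sim <- simulate_dataset(n_tfs = 5, n_genes = 60, noise_sd = 0.2,
                          bias_amplitude = 0, seed = 4)
  arrays <- sim$arrays
  # zero bias: oriented channel ratio equals the series exactly
  back <- debias_two_color(arrays, bias_amplitude = 0)
  expect_equal(back$M, sim$expression$M, tolerance = 1e-12)

  # swap pair of the same biological sample: raw log-ratios sign-opposed
  raw <- log2(arrays$cy5 / arrays$cy3)
  key <- paste(arrays$feature_id, arrays$time_min, sub("s[12]$", "", arrays$replicate))
  s1 <- grepl("s1$", arrays$replicate)
  m1 <- raw[s1][order(key[s1])]
  m2 <- raw[!s1][order(key[!s1])]
  # technical swap pairs share the biological signal but not the noise draw;
  # rebuild from a noise-free series for the exact symmetry
  truth0 <- sim$truth; truth0$noise_sd <- 0
  expr0 <- simulate_expression(truth0, seed = 1)
  arr0 <- render_two_color(expr0, design, bias_amplitude = 0, seed = 2)
  raw0 <- log2(arr0$cy5 / arr0$cy3)
  key0 <- paste(arr0$feature_id, arr0$time_min, sub("s[12]$", "", arr0$replicate))
  s01 <- grepl("s1$", arr0$replicate)
  expect_equal(raw0[s01][order(key0[s01])], -raw0[!s01][order(key0[!s01])])

  # known bias removed exactly by the bookkeeping inverse
  arr1 <- render_two_color(sim$expression, design, bias_amplitude = 1,
                           seed = 2)
  back1 <- debias_two_color(arr1, bias_amplitude = 1)
  expect_equal(back1$M, sim$expression$M, tolerance = 1e-9)
  # and the injected bias is large where intensity is low
  A <- 0.5 * log2(arr1$cy3 * arr1$cy5)
  low <- A <= quantile(A, 0.1)
  bias_seen <- abs(log2(arr1$cy5 / arr1$cy3) - log2(arrays$cy5 / arrays$cy3))
  expect_gte(mean(bias_seen[low]), 0.5)
})

test_that("the generator is deterministic end to end", {
  a <- simulate_dataset(n_tfs = 4, n_genes = 30, seed = 9)
  b <- simulate_dataset(n_tfs = 4, n_genes = 30, seed = 9)
  expect_identical(a$arrays, b$arrays)
  expect_identical(a$truth$baselines, b$truth$baselines)
})

test_that("generated tables carry one record per design cell", {
  sim <- simulate_dataset(n_tfs = 3, n_genes = 25, seed = 2)
  counts <- dplyr::count(sim$arrays, feature_id, condition)
  expect_true(all(counts$n == 6 * 4))
  cell <- dplyr::count(sim$arrays, feature_id, replicate, time_min,
                       condition)
  expect_true(all(cell$n == 1L))
})

test_that("ground truth round-trips losslessly through the writers", {
  sim <- simulate_dataset(n_tfs = 4, n_genes = 30, seed = 6)
  dir <- withr::local_tempdir()
  write_ground_truth(sim$truth, dir)
  back <- read_ground_truth(dir)
  expect_equal(back$network, sim$truth$network)
  expect_equal(back$activities, sim$truth$activities)
  expect_equal(back$baselines, sim$truth$baselines)
  expect_equal(back$noise_sd, sim$truth$noise_sd)
  expect_equal(back$design$time_points_min, design$time_points_min)
})
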