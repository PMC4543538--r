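design <- array_design()

# small single-condition dataset with known truth
recovery_sim <- function(n_tfs = 10, n_genes = 200, noise_sd = 0.2,
                         frac_responsive = 0.5, seed = 1) {
  simulate_dataset(n_tfs = n_tfs, n_genes = n_genes, noise_sd = noise_sd,
                   frac_responsive = frac_responsive, amplitude = 2,
                   seed = seed)
}

abs_cor_with_truth <- function(fit, truth) {
  act <- dplyr::arrange(fit$activities, .data$tf, .data$time_min)
  tru <- dplyr::arrange(truth$activities, .data$tf, .data$time_min)
  sapply(split(seq_len(nrow(act)), act$tf), function(i) {
    ct <- tru$activity[i]
    if (sd(ct) == 0) return(NA_real_)
    abs(cor(act$mean[i], ct))
  })
}

test_that("a noise-free single-TF system is recovered exactly up to gauge", {
  genes <- sprintf("g%02d", 1:20)
  net <- single_tf_network(genes)
  act <- simulate_activities(net, design, amplitude = 2,
                             frac_responsive = 1, seed = 2)
  truth <- make_truth(net, act, design, weights = seq(0.5, 1.5,
                                                      length.out = 20))
  series <- simulate_expression(truth, seed = 1)
  fit <- infer_tf_activities(series, net, seed = 0)
  r <- abs(cor(fit$activities$mean, act$activity))
  expect_gt(r, 0.999)
})

test_that("the ELBO trace is non-decreasing and convergence is reported", {
  sim <- recovery_sim(n_tfs = 5, n_genes = 80, seed = 3)
  fit <- infer_tf_activities(sim$expression,
                             sim$truth$network[c("tf", "gene", "sign")],
                             seed = 1)
  expect_true(fit$converged)
  d <- diff(fit$elbo)
  expect_true(all(d >= -1e-8 * pmax(abs(fit$elbo[-length(fit$elbo)]), 1)))
  expect_true(all(fit$activities$sd > 0))
  g <- glance(fit)
  expect_equal(g$n_tfs, 5L)
  expect_true(g$converged)
})

test_that("weights are confined to the wiring diagram", {
  sim <- recovery_sim(n_tfs = 4, n_genes = 40, seed = 5)
  net <- sim$truth$network[c("tf", "gene", "sign")]
  fit <- infer_tf_activities(sim$expression, net, seed = 1)
  expect_equal(nrow(fit$weights), nrow(net))
  expect_equal(paste(fit$weights$tf, fit$weights$gene),
               paste(net$tf, net$gene)[order(net$tf, net$gene)])
})

test_that("negating a TF profile and its weights is a model symmetry", {
  sim <- recovery_sim(n_tfs = 4, n_genes = 50, seed = 6)
  fit <- infer_tf_activities(sim$expression,
                             sim$truth$network[c("tf", "gene", "sign")],
                             seed = 1)
  flipped <- flip_profile(fit, "TF02")
  expect_equal(predict(flipped)$fitted, predict(fit)$fitted,
               tolerance = 1e-8)
  # involution
  expect_equal(flip_profile(flipped, "TF02")$activities, fit$activities)
  expect_error(flip_profile(fit, "nope"), "unknown TF")
})

test_that("sign reports classify agreement by majority vote", {
  fit <- structure(list(
    activities = make_profile(c(0, 1, 2, 3, 4, 5), 0.1),
    weights = tibble::tibble(
      tf = c("TF01", "TF01", "TF02", "TF02", "TF03"),
      gene = c("g1", "g2", "g1", "g3", "g4"),
      mean = c(1.2, -0.4, -0.8, -0.5, 0.7), sd = 0.1),
    flipped = c(TF01 = FALSE, TF02 = FALSE, TF03 = FALSE)),
    class = "tf_activity_fit")
  net <- tibble::tibble(tf = c("TF01", "TF01", "TF02", "TF02", "TF03"),
                        gene = c("g1", "g2", "g1", "g3", "g4"),
                        sign = c(1L, 1L, 1L, 1L, 0L))
  rep <- sign_ambiguity_report(fit, net)
  expect_equal(rep$status[rep$tf == "TF01"], "undetermined")  # 1-1 tie
  expect_equal(rep$status[rep$tf == "TF02"], "flipped")
  expect_equal(rep$status[rep$tf == "TF03"], "undetermined")  # no signs
  # flipping a 'flipped' TF makes it consistent
  rep2 <- sign_ambiguity_report(flip_profile(fit, "TF02"), net)
  expect_equal(rep2$status[rep2$tf == "TF02"], "consistent")
})

test_that("the activity update equals brute-force Bayesian regression", {
  genes <- sprintf("g%d", 1:5)
  net <- tibble::tibble(
    tf = c("TF1", "TF2", "TF1", "TF2", "TF1", "TF2", "TF1"),
    gene = c("g1", "g1", "g2", "g2", "g3", "g3", "g4"),
    sign = 0L)
  net <- dplyr::bind_rows(net, tibble::tibble(tf = "TF2", gene = "g5",
                                              sign = 0L))
  w <- tibble::tibble(tf = net$tf, gene = net$gene,
                      weight = c(1.0, -0.6, 0.8, 0.4, -1.1, 0.9, 0.7, 1.3))
  set.seed(7)
  grid <- tidyr::expand_grid(gene = genes, time_min = c(0, 10, 20),
                             replicate = c("r1", "r2"))
  series <- tibble::tibble(gene = grid$gene, condition = "x",
                           time_min = grid$time_min,
                           replicate = grid$replicate,
                           M = rnorm(nrow(grid)))
  s2 <- 0.04
  tau_c <- 1
  fit <- infer_tf_activities(series, net, max_iter = 1, tol = 1e-12,
                             prior_var_activities = tau_c,
                             noise_init = s2, update_noise = FALSE,
                             update_weights = FALSE, weights_init = w,
                             center = "none", gauge_fix = FALSE,
                             seed = 0) |> suppressWarnings()
  # oracle: per time point, ridge posterior with design rows b_g per obs
  tf_ids <- sort(unique(net$tf))
  B <- matrix(0, 5, 2, dimnames = list(sort(genes), tf_ids))
  B[cbind(match(w$gene, sort(genes)), match(w$tf, tf_ids))] <- w$weight
  for (t in unique(series$time_min)) {
    st <- series[series$time_min == t, ]
    Xd <- B[st$gene, , drop = FALSE]
    prec <- diag(2) / tau_c + crossprod(Xd) / s2
    mpost <- solve(prec, crossprod(Xd, st$M) / s2)
    vpost <- solve(prec)
    got <- fit$activities[fit$activities$time_min == t, ]
    expect_equal(got$mean, as.numeric(mpost), tolerance = 1e-8)
    expect_equal(got$sd, unname(sqrt(diag(vpost))), tolerance = 1e-8)
  }
})

test_that("recovery degrades gracefully with increasing noise", {
  med <- sapply(c(0.05, 0.2, 0.5), function(sigma) {
    r <- sapply(1:5, function(s) {
      sim <- recovery_sim(n_tfs = 5, n_genes = 60, noise_sd = sigma,
                          frac_responsive = 1, seed = 100 + s)
      fit <- infer_tf_activities(sim$expression,
                                 sim$truth$network[c("tf", "gene", "sign")],
                                 max_iter = 150, tol = 1e-7, seed = 1) |>
        suppressWarnings()
      median(abs_cor_with_truth(fit, sim$truth), na.rm = TRUE)
    })
    median(r)
  })
  expect_true(all(diff(med) <= 1e-6))
})

test_that("genes outside the network are dropped, never silently", {
  sim <- recovery_sim(n_tfs = 3, n_genes = 30, seed = 8)
  net <- sim$truth$network[c("tf", "gene", "sign")]
  extra <- dplyr::mutate(sim$expression[sim$expression$gene == "g0001", ],
                         gene = "not_in_network")
  expect_message(
    fit <- infer_tf_activities(dplyr::bind_rows(sim$expression, extra),
                               net, seed = 1),
    "dropping 1 gene")
  expect_equal(fit$dropped_genes, "not_in_network")
  expect_error(
    infer_tf_activities(dplyr::mutate(sim$expression, gene = "zzz"), net),
    "no genes shared")
})
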