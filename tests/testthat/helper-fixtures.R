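# shared fixture builders (all generated in code, no files)

# a tidy activity-profile tibble for one TF, as consumed by compare_conditions
make_profile <- function(mean, sd, tf = "TF01",
                         time_min = c(0, 10, 20, 40, 60, 120)) {
  tibble::tibble(tf = tf, time_min = time_min, mean = mean,
                 sd = rep_len(sd, length(mean)))
}

# a single-TF network covering `genes`, every edge signed +1
single_tf_network <- function(genes, tf = "TF01") {
  tibble::tibble(tf = tf, gene = genes, sign = 1L)
}

# ground truth with fully controlled weights/baselines/noise
make_truth <- function(network, activities, design, weights, baselines = 0,
                       noise_sd = 0) {
  truth <- simulate_truth(network, activities, design, noise_sd = 1,
                          seed = 1)
  truth$network$weight <- rep_len(weights, nrow(truth$network))
  truth$baselines$baseline <- rep_len(baselines, nrow(truth$baselines))
  truth$noise_sd <- noise_sd
  truth
}

# brute-force grid search version of the constant-fits discard test
grid_constant_fits <- function(mean, sd, z = 2, step = 1e-3) {
  ks <- seq(min(mean) - 3 * max(sd), max(mean) + 3 * max(sd), by = step)
  any(vapply(ks, function(k) all(abs(mean - k) <= z * sd), logical(1)))
}
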