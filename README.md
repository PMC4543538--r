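# tfpulse

Time-resolved transcription-factor (TF) activity analysis for two-color
microarray time courses, written for bacterial stress-response experiments:
a treated culture is sampled at a pre-treatment reference and a handful of
post-treatment time points, each sample is hybridized against an untreated
control with dye-swap technical replication, and the question is which
regulators drove the observed transcriptional response — and whether they
behaved the same way under two different treatments.

The package covers the full computational chain on tidy tibbles:

1. **Preprocessing** (`compute_ratios()`, `lowess_normalize()`,
   `assemble_series()` / `preprocess_arrays()`): dye-swap-aware log2 ratios
   M = log2(experimental/control), mean intensities
   A = ½·log2(Cy3·Cy5), and per-array LOWESS normalization of M on A to
   remove intensity-dependent dye bias. Labelling QC calculators
   (`cdna_yield()`, `specific_activity()`, `qc_assess()`) implement the
   standard suitability gates (yield > 825 ng, specific activity >
   8 pmol/µg).
2. **Differential expression** (`call_de()`, `summarize_fold_changes()`):
   per-(gene, time) one-sample t-tests of the replicate log ratios against
   0, gated by both a 2-fold cut-off (|mean log2 ratio| ≥ 1) and p < 0.05.
3. **TF activity inference** (`infer_tf_activities()`): the log-linear
   factor model

   x<sub>gt</sub> = Σ<sub>f</sub> X<sub>gf</sub> b<sub>gf</sub> c<sub>ft</sub> + ε,  ε ~ N(0, s²)

   where X is a fixed binary TF→gene wiring diagram (e.g. from regulonDB),
   b are regulatory weights and c the latent TF activity changes over time.
   Fitted by mean-field variational Bayes with per-TF ARD priors on the
   weights, so TFs without coherent support in the data are pruned and
   report wide, honest error bars. Results come back as tidy tibbles via
   `tidy()` / `glance()`, with `autoplot()` for profile ribbons.
4. **Cross-condition comparison** (`is_constant_within_errorbars()`,
   `compare_conditions()`, `rank_tfs()`): profiles in which a constant time
   series fits inside the error bars are discarded as non-responsive; a TF
   retained in exactly one condition gets the sentinel score **2**; TFs
   retained in both are scored by the **absolute Pearson correlation** of
   their mean profiles (|r| ∈ [0, 1]), absolute because each profile's sign
   is a model gauge (`flip_profile()`, `sign_ambiguity_report()`).
5. **Synthetic data** (`simulate_dataset()` and friends): a generator that
   emulates the experimental design — 6 time points (0/10/20/40/60/120 min),
   2 biological × 2 dye-swap replicates per condition, sparse signed
   networks, smooth activity trajectories, log-linear expression with
   Gaussian noise, and an injectable intensity-dependent dye bias — so the
   whole pipeline is testable without any external data.

## Worked example

```r
library(tfpulse)
design <- array_design()     # 0/10/20/40/60/120 min, 2 bio x 2 dye-swap

net   <- simulate_network(n_tfs = 8, n_genes = 150, mean_regulators = 2,
                          frac_signed = 0.5, seed = 1)
actA  <- simulate_activities(net, design, amplitude = 2,
                             frac_responsive = 0.5, seed = 2)
truthA <- simulate_truth(net, actA, design, noise_sd = 0.2, seed = 3)
exprA  <- simulate_expression(truthA, condition = "CORM3", seed = 4)
arraysA <- render_two_color(exprA, design, bias_amplitude = 1, seed = 5)

seriesA <- preprocess_arrays(arraysA, design = design)  # ratios -> LOWESS -> series
fitA <- infer_tf_activities(seriesA, net, seed = 1)
fitA
#> <tf_activity_fit> 8 TFs x 6 time points, 150 genes
#>   ELBO -1051.7387 after 16 sweep(s); converged; noise sd 0.2876
```

A second condition (different seed for the activities, same network) is
fitted the same way and the two runs compared:

```r
scores <- compare_conditions(fitA, fitB, z = 2, network = net,
                             condition_a = "CORM3", condition_b = "iCORM3")
rank_tfs(scores)
#> # A tibble: 8 × 6
#>   tf    status          score flipped_a flipped_b partition
#>   <chr> <chr>           <dbl> <lgl>     <lgl>     <fct>
#> 1 TF06  both_retained   0.997 FALSE     FALSE     concordant
#> 2 TF05  both_retained   0.933 FALSE     FALSE     concordant
#> 3 TF01  a_only          2     FALSE     FALSE     condition_specific
#> 4 TF03  b_only          2     TRUE      FALSE     condition_specific
#> 5 TF07  a_only          2     FALSE     FALSE     condition_specific
#> 6 TF08  b_only          2     FALSE     FALSE     condition_specific
#> 7 TF02  both_discarded NA     TRUE      TRUE      unresponsive
#> 8 TF04  both_discarded NA     TRUE      TRUE      unresponsive
```

Reading the table: TF05/TF06 responded in both conditions with highly
correlated profiles (|r| ≈ 0.93–1.0, concordant); TF01/TF03/TF07/TF08
responded in only one condition and carry the sentinel score 2; TF02/TF04
showed no inferable response in either condition (a constant series fits
within their error bars) and receive no score. `flipped_*` records where
the sign-ambiguous profile was inverted to match the signed network
annotation — flips never change |r|.

The per-time DE calls for the same data come from `call_de(seriesA)`; for
example gene g0003 is called up at 20 min with mean log2 ratio 2.07
(4.2-fold, p = 5.4e-4), while sub-2-fold changes are never called however
small their p-value.

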