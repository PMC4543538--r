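#' Infer TF activity profiles from an expression series and a network
#'
#' Fits the log-linear factor model
#' `x[g,t] = sum_f X[g,f] * b[g,f] * c[f,t] + eps`, `eps ~ N(0, s^2)`,
#' where `X` is the fixed binary wiring diagram, `b` the regulatory weights
#' and `c` the latent time-resolved TF activity changes. Inference is
#' mean-field variational Bayes over the bilinear pair: a Gaussian posterior
#' over each gene's weight vector and over each time point's activity
#' vector, updated in closed form in alternation, with EM-style point
#' updates of the noise variance and -- the automatic relevance
#' determination (ARD) step -- of a per-TF weight-prior variance. ARD is
#' what makes the downstream non-responsiveness filter meaningful: a TF
#' whose targets carry no coherent signal has its weight column shrunk
#' towards zero by the learned prior, so its activity posterior reverts to
#' the activity prior (near-zero mean, wide error bars) instead of fitting
#' noise with deceptively tight bars, the familiar overconfidence of
#' bilinear factor models. For the same reason, reported activity error
#' bars are computed from the plug-in precision at the weight means
#' (weight-posterior variance excluded): in the mean-field update that
#' variance acts as additional apparent signal power, so it would narrow
#' the bars most exactly where the weights are least determined. The
#' evidence lower bound (ELBO) is recorded each
#' sweep and is non-decreasing; the fit stops when its relative change
#' drops below `tol`. Because ARD leaves a quasi-flat scale direction
#' (weight-prior variance against weight scale) along which the ELBO creeps
#' long after every reported quantity has stabilized, the fit also stops --
#' and is reported converged -- when the gauge-fixed activity profiles move
#' by less than `tol_activity` in one sweep.
#'
#' Replicates enter by default as repeated observations of the same
#' (gene, time) mean, which sharpens the posterior; set
#' `replicates = "average"` to collapse them first. Gene baselines are
#' absorbed by centering each gene's series, by default on its grand mean
#' over all times and replicates (`center = "mean"`): the centering error is
#' then a small constant shared by every time point, which the
#' shift-invariant downstream analyses (non-responsiveness filtering,
#' profile correlation) ignore. `center = "reference"` instead centers on
#' the replicate mean at the first (pre-treatment) time point, anchoring
#' profiles at zero there; note that with few replicates this injects the
#' reference-time noise as a shared offset into all later time points,
#' which can mimic a step response. The bilinear model leaves a per-TF
#' scale degeneracy (b/alpha, c*alpha); reported weights are rescaled after
#' fitting so each TF column has unit mean squared weight, with the inverse
#' scale applied to the activities. A per-TF sign degeneracy remains and is
#' handled downstream ([sign_ambiguity_report()], [flip_profile()]).
#'
#' @param series Expression-series tibble (`gene`, `condition`, `time_min`,
#'   `replicate`, `M`) for a single condition.
#' @param network Edge-list tibble (`tf`, `gene`, `sign`).
#' @param max_iter Maximum number of update sweeps.
#' @param tol Convergence tolerance on the relative ELBO change.
#' @param tol_activity Convergence tolerance on the largest one-sweep change
#'   of any gauge-fixed activity mean.
#' @param prior_var_activities,prior_var_weights Variances of the zero-mean
#'   Gaussian priors on activities (per TF-time) and weights (per edge);
#'   the latter is the initial value of the per-TF ARD variances when
#'   `ard = TRUE`.
#' @param ard Learn a per-TF weight-prior variance by empirical Bayes
#'   (default); set `FALSE` to keep `prior_var_weights` fixed.
#' @param noise_init Initial noise variance; default half the variance of
#'   the centered data.
#' @param update_noise,update_weights Set to `FALSE` to hold the noise
#'   variance or the weights fixed (the latter as point masses at their
#'   initialization), mainly for diagnostics.
#' @param weights_init Optional tibble (`tf`, `gene`, `weight`) of initial
#'   weight means; default: signed edges start at their annotated sign,
#'   unsigned edges at small random values under `seed`.
#' @param replicates `"observations"` (default) or `"average"`.
#' @param center `"mean"` (default), `"reference"` or `"none"`; how gene
#'   baselines are removed before fitting.
#' @param gauge_fix Rescale to unit mean squared weight per TF column.
#' @param seed Seed for the random part of the weight initialization.
#' @return A `tf_activity_fit` object: tibbles `activities`
#'   (`tf`, `time_min`, `mean`, `sd`) and `weights` (`tf`, `gene`, `mean`,
#'   `sd`), `noise_variance`, `ard_variance` (per-TF learned weight-prior
#'   variance; values at the pruning floor mark TFs with no inferable
#'   signal), `elbo` (trace), `iterations`, `converged`, `dropped_genes`,
#'   `flipped` (per-TF flag for downstream sign correction), `condition`.
#' @export
infer_tf_activities <- function(series, network, max_iter = 500,
                                tol = 1e-7, tol_activity = 1e-6,
                                prior_var_activities = 1,
                                prior_var_weights = 1, noise_init = NULL,
                                update_noise = TRUE, update_weights = TRUE,
                                weights_init = NULL,
                                replicates = c("observations", "average"),
                                center = c("mean", "reference", "none"),
                                ard = TRUE, gauge_fix = TRUE, seed = 0) {
  check_columns(series, c("gene", "condition", "time_min", "replicate", "M"),
                "series")
  check_columns(network, c("tf", "gene", "sign"), "network")
  replicates <- match.arg(replicates)
  center <- match.arg(center)
  max_iter <- check_count(max_iter, "max_iter")
  check_scalar_number(tol, "tol", lower = 0, strict_lower = TRUE)
  check_scalar_number(tol_activity, "tol_activity", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(prior_var_activities, "prior_var_activities",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(prior_var_weights, "prior_var_weights",
                      lower = 0, strict_lower = TRUE)
  condition <- unique(series$condition)
  if (length(condition) > 1L) {
    abort("`series` holds several conditions; fit one condition at a time.")
  }

  # --- data/network intersection ---------------------------------------
  net_genes <- unique(network$gene)
  dropped <- setdiff(unique(series$gene), net_genes)
  if (length(dropped) > 0L) {
    message(sprintf("dropping %d gene(s) absent from the network",
                    length(dropped)))
    series <- series[series$gene %in% net_genes, , drop = FALSE]
  }
  if (nrow(series) == 0L) {
    abort("no genes shared between `series` and `network`.")
  }
  gene_ids <- sort(unique(series$gene))
  network <- network[network$gene %in% gene_ids, , drop = FALSE]
  tf_ids <- sort(unique(network$tf))
  tt <- sort(unique(series$time_min))
  G <- length(gene_ids); F_ <- length(tf_ids); T_ <- length(tt)

  # --- centering and sufficient statistics ------------------------------
  if (center != "none") {
    ref <- series |>
      (\(s) if (center == "reference") {
        dplyr::filter(s, .data$time_min == tt[1])
      } else s)() |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(ref = mean(.data$M), .groups = "drop")
    series <- dplyr::left_join(series, ref, by = "gene")
    series$M <- series$M - dplyr::coalesce(series$ref, 0)
    series$ref <- NULL
  }
  if (replicates == "average") {
    series <- series |>
      dplyr::group_by(.data$gene, .data$time_min) |>
      dplyr::summarise(M = mean(.data$M), .groups = "drop")
  }
  gi <- match(series$gene, gene_ids)
  ti <- match(series$time_min, tt)
  n_gt <- matrix(0, G, T_); s1 <- matrix(0, G, T_); s2 <- matrix(0, G, T_)
  for (i in seq_along(gi)) {
    n_gt[gi[i], ti[i]] <- n_gt[gi[i], ti[i]] + 1
    s1[gi[i], ti[i]] <- s1[gi[i], ti[i]] + series$M[i]
    s2[gi[i], ti[i]] <- s2[gi[i], ti[i]] + series$M[i]^2
  }
  n_obs <- sum(n_gt)

  # per-gene regulator index sets
  supp <- split(match(network$tf, tf_ids), match(network$gene, gene_ids))
  supp <- supp[as.character(seq_len(G))]
  edge_sign <- split(network$sign, match(network$gene, gene_ids))
  edge_sign <- edge_sign[as.character(seq_len(G))]

  # --- initialization ---------------------------------------------------
  tau_c <- prior_var_activities
  # Per-TF weight-prior variance (ARD), constrained below by a pruning
  # floor: a TF whose mean squared weight falls under 1e-4 (prior sd 1% of
  # the unit weight scale) is effectively pruned, and the floor stops the
  # slow algebraic decay of fully collapsed columns.
  tau_b <- rep(prior_var_weights, F_)
  tau_floor <- 1e-4
  beta <- vector("list", G)   # weight posterior means, per gene
  sig_b <- vector("list", G)  # weight posterior covariances
  if (!is.null(weights_init)) {
    check_columns(weights_init, c("tf", "gene", "weight"), "weights_init")
    wkey <- paste(weights_init$tf, weights_init$gene)
    wmap <- setNames(weights_init$weight, wkey)
  }
  withr_seed(seed, {
    for (g in seq_len(G)) {
      k <- length(supp[[g]])
      if (!is.null(weights_init)) {
        b0 <- unname(wmap[paste(tf_ids[supp[[g]]], gene_ids[g])])
        if (anyNA(b0)) abort("`weights_init` does not cover all edges.")
      } else {
        b0 <- ifelse(edge_sign[[g]] != 0, as.numeric(edge_sign[[g]]),
                     rnorm(k, 0, 0.1))
      }
      beta[[g]] <- b0
      sig_b[[g]] <- if (update_weights) diag(0.01, k) else matrix(0, k, k)
    }
  })
  xbar <- series$M
  s2_noise <- noise_init %||% max(var(xbar) / 2, 1e-6)
  check_scalar_number(s2_noise, "noise_init", lower = 0, strict_lower = TRUE)

  m_c <- matrix(0, F_, T_)          # activity posterior means
  V_c <- replicate(T_, diag(tau_c, F_), simplify = FALSE)

  elbo_trace <- numeric(0)
  converged <- FALSE
  act_prev <- NULL   # gauge-fixed activity means of the previous sweep
  logdet <- function(S) {
    if (length(S) == 0L || nrow(S) == 0L) return(0)
    2 * sum(log(diag(chol(S))))
  }

  for (it in seq_len(max_iter)) {
    # --- activity update: Gaussian posterior per time point -------------
    # B_g = E[b_g b_g'] on the gene's support
    Bg <- purrr::map(seq_len(G), ~ tcrossprod(beta[[.x]]) + sig_b[[.x]])
    for (t in seq_len(T_)) {
      lam <- diag(1 / tau_c, F_)
      rhs <- numeric(F_)
      for (g in seq_len(G)) {
        if (n_gt[g, t] == 0) next
        s_g <- supp[[g]]
        lam[s_g, s_g] <- lam[s_g, s_g] + n_gt[g, t] / s2_noise * Bg[[g]]
        rhs[s_g] <- rhs[s_g] + s1[g, t] / s2_noise * beta[[g]]
      }
      V_c[[t]] <- chol2inv(chol(lam))
      m_c[, t] <- V_c[[t]] %*% rhs
    }
    Ct <- purrr::map(seq_len(T_), ~ tcrossprod(m_c[, .x]) + V_c[[.x]])

    # --- weight update: Gaussian posterior per gene ---------------------
    # With ARD, the weight posterior and the per-TF prior variances are
    # iterated to their joint fixed point within the sweep (inner
    # coordinate ascent, so the ELBO is still non-decreasing); otherwise a
    # weakly supported TF would linger on the slow ARD decay path instead
    # of being pruned or kept cleanly.
    if (update_weights) {
      for (inner in seq_len(if (ard) 25L else 1L)) {
        for (g in seq_len(G)) {
          s_g <- supp[[g]]
          k <- length(s_g)
          lam <- diag(1 / tau_b[s_g], nrow = k)
          rhs <- numeric(k)
          for (t in seq_len(T_)) {
            if (n_gt[g, t] == 0) next
            lam <- lam + n_gt[g, t] / s2_noise *
              Ct[[t]][s_g, s_g, drop = FALSE]
            rhs <- rhs + s1[g, t] / s2_noise * m_c[s_g, t]
          }
          sig_b[[g]] <- chol2inv(chol(lam))
          beta[[g]] <- drop(sig_b[[g]] %*% rhs)
        }
        if (!ard) break
        # ARD update: per-TF weight-prior variance (empirical Bayes)
        msum <- numeric(F_); mcount <- numeric(F_)
        for (g in seq_len(G)) {
          s_g <- supp[[g]]
          msum[s_g] <- msum[s_g] + beta[[g]]^2 + diag(sig_b[[g]])
          mcount[s_g] <- mcount[s_g] + 1
        }
        tau_new <- pmax(ifelse(mcount > 0, msum / pmax(mcount, 1), tau_b),
                        tau_floor)
        drift <- max(abs(log(tau_new / tau_b)))
        tau_b <- tau_new
        if (drift < 1e-3) break
      }
      Bg <- purrr::map(seq_len(G), ~ tcrossprod(beta[[.x]]) + sig_b[[.x]])
    }

    # --- expected residual sum of squares and noise update --------------
    sse <- 0
    for (g in seq_len(G)) {
      s_g <- supp[[g]]
      for (t in seq_len(T_)) {
        if (n_gt[g, t] == 0) next
        mu <- sum(beta[[g]] * m_c[s_g, t])
        quad <- sum(Ct[[t]][s_g, s_g] * Bg[[g]])
        sse <- sse + s2[g, t] - 2 * s1[g, t] * mu + n_gt[g, t] * quad
      }
    }
    sse <- max(sse, 1e-12)
    if (update_noise) s2_noise <- sse / n_obs

    # --- evidence lower bound -------------------------------------------
    elbo <- -n_obs / 2 * log(2 * pi * s2_noise) - sse / (2 * s2_noise)
    for (g in seq_len(G)) {
      k <- length(supp[[g]])
      tb <- tau_b[supp[[g]]]
      elbo <- elbo -
        0.5 * sum(log(2 * pi * tb) +
                    (beta[[g]]^2 + diag(sig_b[[g]])) / tb)
      if (update_weights) {
        elbo <- elbo + 0.5 * (logdet(sig_b[[g]]) + k * (1 + log(2 * pi)))
      }
    }
    for (t in seq_len(T_)) {
      elbo <- elbo -
        0.5 * (F_ * log(2 * pi * tau_c) +
                 sum(m_c[, t]^2 + diag(V_c[[t]])) / tau_c) +
        0.5 * (logdet(V_c[[t]]) + F_ * (1 + log(2 * pi)))
    }
    elbo_trace <- c(elbo_trace, elbo)
    # gauge-fixed profiles: per-TF scale = root mean squared weight
    msq_f <- numeric(F_)
    cnt_f <- numeric(F_)
    for (g in seq_len(G)) {
      s_g <- supp[[g]]
      msq_f[s_g] <- msq_f[s_g] + beta[[g]]^2 + diag(sig_b[[g]])
      cnt_f[s_g] <- cnt_f[s_g] + 1
    }
    act_now <- m_c * sqrt(pmax(msq_f / pmax(cnt_f, 1), 1e-12))
    if (it > 1L) {
      rel <- abs(elbo - elbo_trace[it - 1L]) /
        (abs(elbo_trace[it - 1L]) + 1e-12)
      if (rel < tol || max(abs(act_now - act_prev)) < tol_activity) {
        converged <- TRUE
        act_prev <- act_now
        break
      }
    }
    act_prev <- act_now
  }
  if (!converged) {
    warn(sprintf("fit did not converge in %d sweeps (tol %g)",
                 max_iter, tol))
  }

  # --- reported activity covariance: plug-in weight calibration ---------
  # The mean-field activity precision includes the weight posterior
  # variance as extra apparent signal power, which narrows the error bars
  # most for the least-determined weight columns. Reported bars therefore
  # use the plug-in precision at the weight means (the Bayesian
  # linear-regression covariance given b = E[b]); the activity means keep
  # their fully shrunken variational values.
  Bp <- purrr::map(beta, tcrossprod)
  for (t in seq_len(T_)) {
    lam <- diag(1 / tau_c, F_)
    for (g in seq_len(G)) {
      if (n_gt[g, t] == 0) next
      s_g <- supp[[g]]
      lam[s_g, s_g] <- lam[s_g, s_g] + n_gt[g, t] / s2_noise * Bp[[g]]
    }
    V_c[[t]] <- chol2inv(chol(lam))
  }

  # --- gauge fixing: unit mean squared weight per TF column -------------
  # TF columns pruned by ARD (negligible weight mass) are left unscaled so
  # they report near-zero means with prior-level error bars.
  alpha <- rep(1, F_)
  if (gauge_fix) {
    for (f in seq_len(F_)) {
      msq <- c()
      for (g in seq_len(G)) {
        j <- which(supp[[g]] == f)
        if (length(j)) msq <- c(msq, beta[[g]][j]^2 + sig_b[[g]][j, j])
      }
      if (length(msq) && mean(msq) > 1e-6) alpha[f] <- sqrt(mean(msq))
    }
  }

  act <- tibble(
    tf = rep(tf_ids, T_),
    time_min = rep(tt, each = F_),
    mean = as.vector(m_c * alpha),
    sd = unlist(purrr::map(seq_len(T_),
                           ~ sqrt(pmax(diag(V_c[[.x]]), 1e-300)) * alpha))
  ) |> dplyr::arrange(.data$tf, .data$time_min)
  wts <- tibble(
    tf = tf_ids[unlist(supp)],
    gene = rep(gene_ids, lengths(supp)),
    mean = unlist(beta) / alpha[unlist(supp)],
    sd = unlist(purrr::map(seq_len(G),
                           ~ sqrt(pmax(diag(sig_b[[.x]]), 0)))) /
      alpha[unlist(supp)]
  ) |> dplyr::arrange(.data$tf, .data$gene)

  structure(
    list(activities = act, weights = wts, noise_variance = s2_noise,
         ard_variance = setNames(tau_b, tf_ids),
         elbo = elbo_trace, iterations = length(elbo_trace),
         converged = converged, dropped_genes = dropped,
         flipped = setNames(rep(FALSE, F_), tf_ids),
         condition = condition %||% NA_character_,
         time_points_min = tt),
    class = "tf_activity_fit"
  )
}

#' @export
print.tf_activity_fit <- function(x, ...) {
  cat("<tf_activity_fit> ", length(unique(x$activities$tf)), " TFs x ",
      length(x$time_points_min), " time points, ",
      length(unique(x$weights$gene)), " genes\n",
      "  ELBO ", format(utils::tail(x$elbo, 1), digits = 8), " after ",
      x$iterations, " sweep(s); ",
      if (x$converged) "converged" else "NOT converged",
      "; noise sd ", format(sqrt(x$noise_variance), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @rdname infer_tf_activities
#' @param x A `tf_activity_fit`.
#' @param ... Unused.
#' @export
tidy.tf_activity_fit <- function(x, ...) {
  dplyr::mutate(x$activities,
                flipped = unname(x$flipped[.data$tf]))
}

#' @rdname infer_tf_activities
#' @export
glance.tf_activity_fit <- function(x, ...) {
  tibble(
    n_tfs = length(unique(x$activities$tf)),
    n_genes = length(unique(x$weights$gene)),
    n_dropped = length(x$dropped_genes),
    iterations = x$iterations,
    elbo = utils::tail(x$elbo, 1),
    noise_variance = x$noise_variance,
    converged = x$converged
  )
}

#' Model-implied expression means from a fit
#'
#' @param object A `tf_activity_fit`.
#' @param ... Unused.
#' @return Tibble `gene`, `time_min`, `fitted` (posterior-mean prediction of
#'   the centered log2 ratio).
#' @export
predict.tf_activity_fit <- function(object, ...) {
  object$weights |>
    dplyr::inner_join(object$activities, by = "tf", suffix = c("_b", "_c"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$gene, .data$time_min) |>
    dplyr::summarise(fitted = sum(.data$mean_b * .data$mean_c),
                     .groups = "drop")
}

#' Compare inferred weight signs with network annotation
#'
#' The bilinear model cannot identify the sign of a TF profile from the data
#' alone: jointly negating a TF's activities and weights leaves the fit
#' unchanged. This report compares, for each TF, the signs of its inferred
#' weights against the signed interaction annotations (where present) by
#' majority vote: `consistent` if most signed edges agree, `flipped` if most
#' disagree (the profile should be negated via [flip_profile()]),
#' `undetermined` if there are no signed edges or the vote ties.
#'
#' @param fit A `tf_activity_fit`.
#' @param network Edge-list tibble with the `sign` column.
#' @return Tibble `tf`, `n_signed`, `n_agree`, `status`.
#' @export
sign_ambiguity_report <- function(fit, network) {
  stopifnot(inherits(fit, "tf_activity_fit"))
  check_columns(network, c("tf", "gene", "sign"), "network")
  fit$weights |>
    dplyr::left_join(network, by = c("tf", "gene")) |>
    dplyr::mutate(sign = dplyr::coalesce(.data$sign, 0L)) |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(
      n_signed = sum(.data$sign != 0L),
      n_agree = sum(.data$sign != 0L & sign(.data$mean) == .data$sign),
      .groups = "drop"
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_signed == 0L ~ "undetermined",
      .data$n_agree * 2L > .data$n_signed ~ "consistent",
      .data$n_agree * 2L < .data$n_signed ~ "flipped",
      .default = "undetermined"
    ))
}

#' Flip the sign of inferred TF profiles
#'
#' Negates the activity profile and the weight column of the given TFs --
#' the gauge transformation the model is invariant under -- and records the
#' flip. Flipping twice restores the original fit.
#'
#' @param fit A `tf_activity_fit`.
#' @param tfs Character vector of TF ids to flip.
#' @return The modified `tf_activity_fit`.
#' @export
flip_profile <- function(fit, tfs) {
  stopifnot(inherits(fit, "tf_activity_fit"))
  unknown <- setdiff(tfs, names(fit$flipped))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown TF(s): %s", paste(unknown, collapse = ", ")))
  }
  sel_a <- fit$activities$tf %in% tfs
  fit$activities$mean[sel_a] <- -fit$activities$mean[sel_a]
  sel_w <- fit$weights$tf %in% tfs
  fit$weights$mean[sel_w] <- -fit$weights$mean[sel_w]
  fit$flipped[tfs] <- !fit$flipped[tfs]
  fit
}
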