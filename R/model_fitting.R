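# Maximum-likelihood fitting of the spreading-activation RT models, model
# comparison via cross-model recovery, parameter recovery, and trial-type RMSD
# diagnostics.

#' Gaussian linear negative log-likelihood
#'
#' Fits `observed_z = b0 + b1 * predicted_z + e` by ordinary least squares
#' with Gaussian errors, profiling the residual variance at its ML value
#' `RSS / n` (floored at 1e-6 to keep the likelihood bounded on perfect fits),
#' and returns `n/2 * (log(2 * pi * sigma2) + 1)` in nats. A degenerate
#' (constant) predictor falls back to the intercept-only model.
#'
#' @param predicted_z model-predicted standardized RTs.
#' @param observed_z observed standardized RTs.
#' @return negative log-likelihood (scalar, nats) with attribute `coef`.
#' @export
gaussian_linear_nll <- function(predicted_z, observed_z) {
  n <- length(observed_z)
  if (length(predicted_z) != n) stop("length mismatch")
  if (n < 3L) stop("need at least 3 trials")
  sx <- stats::sd(predicted_z)
  if (!is.finite(sx) || sx < 1e-10) {
    b1 <- 0
    b0 <- mean(observed_z)
  } else {
    b1 <- stats::cov(predicted_z, observed_z) / stats::var(predicted_z)
    b0 <- mean(observed_z) - b1 * mean(predicted_z)
  }
  rss <- sum((observed_z - b0 - b1 * predicted_z)^2)
  s2 <- max(rss / n, 1e-6)
  nll <- n / 2 * (log(2 * pi * s2) + 1)
  attr(nll, "coef") <- c(intercept = b0, slope = b1, sigma2 = s2)
  nll
}

# objective over alpha given a precomputed prediction structure; degenerate
# (constant) raw predictions are maximally penalized
model_nll_fn <- function(pre, observed_z) {
  function(par) {
    # optim's finite-difference gradient can step marginally outside the box
    par <- pmin(pmax(par, 0), 1)
    raw <- predict_raw_from_precompute(pre, par)
    z <- zscore(raw)
    if (is_degenerate(z)) return(1e8)
    as.numeric(gaussian_linear_nll(z, observed_z))
  }
}

fit_precomputed <- function(pre, observed_z, n_restarts, seed, model_kind) {
  fn <- model_nll_fn(pre, observed_z)
  starts <- with_seed(seed, matrix(stats::runif(3L * n_restarts), n_restarts, 3L))
  fits <- lapply(seq_len(n_restarts), function(i) {
    stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                 lower = rep(0, 3), upper = rep(1, 3),
                 control = list(maxit = 200))
  })
  nlls <- vapply(fits, `[[`, 0, "value")
  best <- fits[[which.min(nlls)]]
  par <- pmin(pmax(best$par, 0), 1)  # guard against numerical bound overshoot
  structure(list(
    model_kind = model_kind,
    params = activation_params(par[1], par[2], par[3]),
    nll = min(nlls),
    n_trials = length(observed_z),
    restart_nlls = nlls,
    converged = best$convergence == 0
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: nll = %.3f over %d trials (%d restarts)\n",
              x$model_kind, x$nll, x$n_trials, length(x$restart_nlls)))
  cat(sprintf("  alpha = (%.3f, %.3f, %.3f)\n",
              x$params[1], x$params[2], x$params[3]))
  invisible(x)
}

#' Fit an activation model to reaction times
#'
#' Finds the rate parameters `(alpha1, alpha2, alpha3)` in `[0, 1]^3` that
#' minimize the Gaussian linear negative log-likelihood of the observed
#' z-scored RTs given the model-predicted z-scored RTs, using bounded
#' L-BFGS-B restarted from `n_restarts` uniform random starting points to
#' avoid local minima. Only correct generalization trials with an RT enter the
#' fit; RTs are z-scored internally across those trials.
#'
#' @param model_kind one of `"CAR"`, `"IAR"`, `"LS"`, `"HLS"`.
#' @param trial_data a `trial_sequence` with behavioral `rt` / `correct`
#'   fields (RTs in seconds or already standardized; standardization is
#'   internal either way).
#' @param n_restarts number of random restarts.
#' @param seed integer seed for the restart starting points.
#' @param design `task_design`; defaults to the one attached to `trial_data`.
#' @return a `fit_result` with fitted `params`, best `nll`, per-restart NLLs,
#'   and trial count.
#' @export
fit_model <- function(model_kind, trial_data, n_restarts = 30L, seed = 1L,
                      design = design_of(trial_data)) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  trials <- modelable_trials(trial_data)
  trials <- trials[!is.na(trials$rt), , drop = FALSE]
  if (!is.null(trials$choice))
    trials <- trials[is.na(trials$choice) | trials$choice != "missed", ,
                     drop = FALSE]
  if (nrow(trials) < 10L) stop("fewer than 10 usable trials")
  observed_z <- as.numeric(zscore(trials$rt))
  pre <- precompute_prediction(model_kind, design, trials)
  fit_precomputed(pre, observed_z, n_restarts, seed, model_kind)
}

#' Simulate standardized RTs from a model
#'
#' Adds i.i.d. Gaussian noise of standard deviation `noise_sd` (z units) to
#' the model-predicted z-scored RTs and re-standardizes.
#'
#' @inheritParams predict_sequence
#' @param noise_sd noise standard deviation in z units.
#' @param seed integer seed.
#' @return simulated z-scored RT vector.
#' @export
simulate_rts <- function(model_kind, params, sequence, noise_sd = 0.5,
                         seed = 1L, design = design_of(sequence)) {
  z <- predict_sequence(model_kind, params, sequence, design = design)
  if (noise_sd == 0) return(as.numeric(z))
  noisy <- with_seed(seed, z + stats::rnorm(length(z), 0, noise_sd))
  as.numeric(zscore(noisy))
}

#' Cross-model recovery matrix
#'
#' For each generator model, simulates RT data from that model on freshly
#' generated randomized-generalization sequences, fits all four models to each
#' simulated dataset, and records the negative log-likelihoods. With
#' distinguishable models, each generator attains the lowest mean NLL in its
#' own row (diagonal dominance).
#'
#' @param params_per_model named list (CAR, IAR, LS, HLS) of generating
#'   parameter vectors.
#' @param noise_sd simulation noise in z units.
#' @param n_replicates replicates per generator.
#' @param n_runs randomized generalization runs per replicate (180 trials
#'   each).
#' @param n_restarts optimizer restarts per fit.
#' @param seed integer seed.
#' @return object of class `recovery_matrix`: list with `mean_nll` (generator
#'   x fitted model), the full `nll` array, and settings.
#' @export
cross_model_recovery <- function(params_per_model, noise_sd = 0.5,
                                 n_replicates = 20L, n_runs = 3L,
                                 n_restarts = 10L, seed = 1L) {
  stopifnot(all(MODEL_KINDS %in% names(params_per_model)))
  seeds <- matrix(child_seeds(seed, 3L * n_replicates), ncol = 3L)
  nll <- array(NA_real_, dim = c(4L, 4L, n_replicates),
               dimnames = list(generator = MODEL_KINDS, fitted = MODEL_KINDS,
                               replicate = NULL))
  for (r in seq_len(n_replicates)) {
    design <- build_design(seeds[r, 1L])
    runs <- generate_randomized_generalization_runs(design, seeds[r, 2L],
                                                    n_runs = n_runs)
    seq_r <- do.call(rbind, runs)
    seq_r <- new_trial_sequence(as.data.frame(seq_r), design)
    pres <- lapply(stats::setNames(MODEL_KINDS, MODEL_KINDS), function(m)
      precompute_prediction(m, design, seq_r))
    for (g in MODEL_KINDS) {
      obs <- simulate_rts(g, params_per_model[[g]], seq_r, noise_sd,
                          seed = seeds[r, 3L] + match(g, MODEL_KINDS),
                          design = design)
      for (m in MODEL_KINDS) {
        fit <- fit_precomputed(pres[[m]], obs, n_restarts,
                               seed = seeds[r, 3L] + 10L + match(m, MODEL_KINDS),
                               model_kind = m)
        nll[g, m, r] <- fit$nll
      }
    }
  }
  structure(list(mean_nll = apply(nll, c(1, 2), mean), nll = nll,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 n_trials = 180L * n_runs),
            class = "recovery_matrix")
}

#' @export
print.recovery_matrix <- function(x, ...) {
  cat("Cross-model recovery: mean NLL (rows = generator, cols = fitted)\n")
  print(round(x$mean_nll, 2))
  diag_dom <- all(apply(x$mean_nll, 1, which.min) == seq_len(4))
  cat(if (diag_dom) "Diagonal dominance holds.\n" else
        "Diagonal dominance violated.\n")
  invisible(x)
}

#' Parameter recovery for one model
#'
#' Repeatedly simulates RT data at known generating parameters on fresh
#' randomized-generalization sequences and refits the same model, reporting
#' the recovered parameters per replicate.
#'
#' @param model_kind generating (and fitted) model.
#' @param true_params generating `activation_params`.
#' @param noise_sd simulation noise in z units.
#' @inheritParams cross_model_recovery
#' @return list with `recovered` (replicates x 3 matrix), `true_params`,
#'   `median_abs_error` per parameter, and `ordering_preserved` fraction of
#'   replicates with `alpha1 > alpha2 > alpha3`.
#' @export
parameter_recovery <- function(model_kind = "HLS",
                               true_params = activation_params(0.9, 0.5, 0.1),
                               noise_sd = 0.3, n_replicates = 20L,
                               n_runs = 3L, n_restarts = 10L, seed = 1L) {
  seeds <- matrix(child_seeds(seed, 3L * n_replicates), ncol = 3L)
  rec <- matrix(NA_real_, n_replicates, 3L,
                dimnames = list(NULL, c("alpha1", "alpha2", "alpha3")))
  for (r in seq_len(n_replicates)) {
    design <- build_design(seeds[r, 1L])
    runs <- generate_randomized_generalization_runs(design, seeds[r, 2L],
                                                    n_runs = n_runs)
    seq_r <- new_trial_sequence(as.data.frame(do.call(rbind, runs)), design)
    obs <- simulate_rts(model_kind, true_params, seq_r, noise_sd,
                        seed = seeds[r, 3L], design = design)
    pre <- precompute_prediction(model_kind, design, seq_r)
    fit <- fit_precomputed(pre, obs, n_restarts, seed = seeds[r, 3L] + 1L,
                           model_kind = model_kind)
    rec[r, ] <- unclass(fit$params)
  }
  tp <- as_params(true_params)
  list(recovered = rec, true_params = tp,
       median_abs_error = apply(abs(sweep(rec, 2, tp)), 2, stats::median),
       ordering_preserved = mean(rec[, 1] > rec[, 2] & rec[, 2] > rec[, 3]))
}

#' Trial-type labels for mini-blocked generalization trials
#'
#' Labels every trial as either the first trial of the n-th context (n = 1, 2)
#' of the m-th latent state (m = 1, 2, 3) in presentation order
#' (`"first_ls<m>_ctx<n>"`), a switch of category mini-block within a context
#' (`"category_switch"`), or an ordinary within-mini-block trial
#' (`"within_miniblock"`).
#'
#' @param sequence a mini-blocked generalization `trial_sequence` (rows in
#'   presentation order).
#' @return character vector of labels, one per row.
#' @export
label_trial_types <- function(sequence) {
  n <- nrow(sequence)
  first_ctx <- !duplicated(sequence$context)
  new_mb <- c(TRUE, sequence$context[-1] != sequence$context[-n] |
                sequence$category[-1] != sequence$category[-n])
  ls_ord <- match(sequence$latent_state, unique(sequence$latent_state))
  # context order within its latent state, by first appearance
  ctx_first <- sequence[first_ctx, c("context", "latent_state")]
  ctx_first$ord <- stats::ave(seq_len(nrow(ctx_first)), ctx_first$latent_state,
                              FUN = seq_along)
  ctx_ord <- ctx_first$ord[match(sequence$context, ctx_first$context)]
  labels <- rep("within_miniblock", n)
  labels[new_mb] <- "category_switch"
  labels[first_ctx] <- sprintf("first_ls%d_ctx%d", ls_ord[first_ctx],
                               ctx_ord[first_ctx])
  labels
}

#' RMSD between observed and predicted RTs per trial type
#'
#' @param observed_z observed standardized RTs.
#' @param predicted_z model-predicted standardized RTs.
#' @param labels trial-type labels (see [label_trial_types()]).
#' @return named numeric vector of root-mean-squared deviations, one per
#'   label present; empty classes are omitted.
#' @export
rmsd_by_trial_type <- function(observed_z, predicted_z, labels) {
  stopifnot(length(observed_z) == length(predicted_z),
            length(labels) == length(observed_z))
  out <- tapply((observed_z - predicted_z)^2, labels,
                function(e) sqrt(mean(e)))
  c(out)
}
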