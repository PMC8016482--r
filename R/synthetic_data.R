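# Synthetic behavioral cohorts and multivoxel pattern datasets with the
# statistical structure the analyses assume, so the full pipeline runs without
# any external data.

#' Configuration of a simulated agent
#'
#' An agent responds to training trials with a saturating within-mini-block
#' accuracy curve (chance at the first trial of a condition, approaching
#' `1 - lapse_rate`) and to generalization trials correctly with probability
#' `1 - lapse_rate`. Generalization RTs are produced by the agent's generative
#' spreading-activation model: the model's z-scored predicted RT is mapped to
#' seconds by `scale * z + offset`, plus Gaussian noise of SD
#' `scale * rt_noise_sd`, floored at 0.2 s. Training RTs decay exponentially
#' within a mini-block at the training learning rate. The default affine map
#' (scale 0.5, offset 1.2 s) places post-first-trial generalization RTs near
#' 1.1-1.2 s with a much slower first trial.
#'
#' @param generative_model one of `"CAR"`, `"IAR"`, `"LS"`, `"HLS"`.
#' @param params `activation_params` of the generative model.
#' @param rt_noise_sd RT noise SD in z units.
#' @param rt_scale,rt_offset affine map from z-scored model RT to seconds.
#' @param lapse_rate probability of a random (incorrect) choice.
#' @param training_learning_rate exponential accuracy-growth rate per
#'   within-mini-block trial during training.
#' @param seed integer seed.
#' @return list of class `agent_config`.
#' @export
agent_config <- function(generative_model = "HLS",
                         params = activation_params(0.9, 0.5, 0.1),
                         rt_noise_sd = 0.3, rt_scale = 0.5, rt_offset = 1.2,
                         lapse_rate = 0.02, training_learning_rate = 1,
                         seed = 1L) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 1, rt_scale > 0)
  structure(list(generative_model = match.arg(generative_model, MODEL_KINDS),
                 params = params, rt_noise_sd = rt_noise_sd,
                 rt_scale = rt_scale, rt_offset = rt_offset,
                 lapse_rate = lapse_rate,
                 training_learning_rate = training_learning_rate,
                 seed = seed),
            class = "agent_config")
}

optimal_choice <- function(value) ifelse(value > 0, "sell", "pass")

#' Simulate one subject's behavior over the whole experiment
#'
#' Generates all phases (initial training + reminder, new-category training,
#' blocked generalization, six randomized generalization runs) and fills in
#' choices, correctness, outcomes, and RTs according to the agent
#' configuration. The agent's memory network starts fresh at generalization
#' onset and carries over across all generalization trials (blocked, then
#' randomized runs in order).
#'
#' @param design a `task_design`.
#' @param agent an `agent_config`.
#' @return a `trial_sequence` covering all phases, with behavior populated
#'   (feedback-phase trials have `outcome`; generalization trials do not).
#' @export
simulate_subject_behavior <- function(design, agent) {
  s <- child_seeds(agent$seed, 6L)
  init <- generate_initial_training(design, s[1])
  newt <- generate_new_category_training(design, s[2])
  blocked <- generate_blocked_generalization(design, s[3])
  runs <- generate_randomized_generalization_runs(design, s[4], n_runs = 6L)
  gen <- new_trial_sequence(as.data.frame(do.call(rbind, c(list(blocked), runs))),
                            design)

  # model-predicted z-scored RTs, one fresh network per generalization segment
  # (the blocked phase, then each scanner run): activation is monotone and
  # saturates at its asymptote, so a single network carried across all 1260
  # trials would leave the later runs with constant predictions; re-engaging
  # the task after each run break restarts retrieval dynamics
  z <- unlist(lapply(c(list(blocked), runs), function(seg)
    as.numeric(predict_sequence(agent$generative_model, agent$params, seg,
                                design = design))))

  with_seed(s[5], {
    # training phases: saturating accuracy, exponentially speeding RTs
    train <- as.data.frame(rbind(init, newt))
    p <- train$trial_in_miniblock
    p_correct <- 0.5 + (1 - agent$lapse_rate - 0.5) *
      (1 - exp(-agent$training_learning_rate * (p - 1)))
    train$correct <- stats::runif(nrow(train)) < p_correct
    opt <- optimal_choice(train$value)
    train$choice <- ifelse(train$correct, opt,
                           ifelse(opt == "sell", "pass", "sell"))
    train$rt <- pmax(0.2, agent$rt_offset +
                       2 * agent$rt_scale * exp(-agent$training_learning_rate * (p - 1)) +
                       agent$rt_scale * stats::rnorm(nrow(train), 0, agent$rt_noise_sd))
    train$outcome <- vapply(seq_len(nrow(train)), function(i)
      sample_outcome(design, train[i, ], train$choice[i])$gold_change, 0)

    # generalization: lapse process for accuracy, model-driven RTs, no feedback
    gdf <- as.data.frame(gen)
    gdf$correct <- stats::runif(nrow(gdf)) >= agent$lapse_rate
    opt <- optimal_choice(gdf$value)
    gdf$choice <- ifelse(gdf$correct, opt, ifelse(opt == "sell", "pass", "sell"))
    gdf$rt <- pmax(0.2, agent$rt_scale * z + agent$rt_offset +
                     agent$rt_scale * stats::rnorm(nrow(gdf), 0, agent$rt_noise_sd))
    gdf$outcome <- NA_real_

    out <- new_trial_sequence(rbind(train, gdf), design)
    attr(out, "agent") <- agent
    out
  })
}

#' Simulate a cohort of subjects
#'
#' Each subject gets an independently re-randomized design (context-to-state
#' and category-value assignments re-drawn, as across participants) and an
#' independent behavioral simulation seed.
#'
#' @param agent an `agent_config` shared by all subjects (per-subject seeds
#'   are derived internally).
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return list of `trial_sequence`s, one per subject.
#' @export
simulate_cohort <- function(agent, n_subjects = 16L, seed = 1L) {
  stopifnot(n_subjects >= 1L)
  seeds <- matrix(child_seeds(seed, 2L * n_subjects), ncol = 2L)
  lapply(seq_len(n_subjects), function(i) {
    design <- build_design(seeds[i, 1L])
    agent_i <- agent
    agent_i$seed <- seeds[i, 2L]
    simulate_subject_behavior(design, agent_i)
  })
}

#' Specification of a synthetic multivoxel pattern dataset
#'
#' @param n_channels number of channels (voxels); must be at least the total
#'   number of factor levels (14) to allow orthonormal factor codes.
#' @param effect_amplitudes named amplitudes (signal units) for the factors
#'   `ls`, `context`, `category`, `value`.
#' @param noise_sd noise standard deviation per channel.
#' @param noise_channel_corr common between-channel noise correlation (must
#'   keep the compound-symmetry covariance positive definite).
#' @param n_runs number of runs.
#' @param n_resid residual samples per run for noise-covariance estimation.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return list of class `pattern_spec`.
#' @export
pattern_spec <- function(n_channels = 40L,
                         effect_amplitudes = c(ls = 0, context = 0,
                                               category = 0, value = 0),
                         noise_sd = 1, noise_channel_corr = 0.2,
                         n_runs = 6L, n_resid = 60L, n_subjects = 1L,
                         seed = 1L) {
  amps <- c(ls = 0, context = 0, category = 0, value = 0)
  amps[names(effect_amplitudes)] <- effect_amplitudes
  stopifnot(all(amps >= 0), noise_sd > 0,
            noise_channel_corr > -1 / (n_channels - 1), noise_channel_corr < 1)
  structure(list(n_channels = n_channels, effect_amplitudes = amps,
                 noise_sd = noise_sd, noise_channel_corr = noise_channel_corr,
                 n_runs = n_runs, n_resid = n_resid, n_subjects = n_subjects,
                 seed = seed),
            class = "pattern_spec")
}

#' Generate synthetic multivoxel pattern datasets
#'
#' Each condition's true pattern is a sum over factors of
#' `amplitude_f * code_f(level)`, with one orthonormal code vector per factor
#' level (orthonormalized across all factors, so planted effects do not leak
#' into each other). Per-run condition estimates add correlated Gaussian noise
#' (compound-symmetry channel covariance), and a residual array from the same
#' noise distribution is provided for covariance estimation.
#'
#' @param design a `task_design` (provides the 18 generalization conditions).
#' @param spec a `pattern_spec`.
#' @return list of per-subject pattern datasets; each is a list with
#'   `estimates` (runs x 18 x channels), `residuals` (runs x n_resid x
#'   channels), `conditions`, and the true `mu` (18 x channels).
#' @export
generate_pattern_dataset <- function(design, spec) {
  conds <- generalization_conditions(design)
  labels <- condition_labels(conds)
  fac_levels <- list(ls = conds$latent_state, context = conds$context,
                     category = conds$category,
                     value = ifelse(conds$value > 0, "pos", "neg"))
  all_levels <- unlist(lapply(names(fac_levels), function(f)
    paste(f, unique(fac_levels[[f]]), sep = ".")))
  L <- length(all_levels)
  V <- spec$n_channels
  if (V < L) stop("n_channels too small to orthogonalize ", L, " factor levels")

  rho <- spec$noise_channel_corr
  Sigma <- spec$noise_sd^2 * ((1 - rho) * diag(V) + rho)
  ch <- chol(Sigma)
  rnoise <- function(n) matrix(stats::rnorm(n * V), n, V) %*% ch

  seeds <- child_seeds(spec$seed, spec$n_subjects)
  lapply(seq_len(spec$n_subjects), function(sj) {
    with_seed(seeds[sj], {
      Q <- qr.Q(qr(matrix(stats::rnorm(V * L), V, L)))
      colnames(Q) <- all_levels
      mu <- matrix(0, nrow(conds), V)
      for (f in names(fac_levels)) {
        codes <- Q[, paste(f, fac_levels[[f]], sep = "."), drop = FALSE]
        mu <- mu + spec$effect_amplitudes[[f]] * t(codes)
      }
      estimates <- array(0, dim = c(spec$n_runs, nrow(conds), V))
      residuals <- array(0, dim = c(spec$n_runs, spec$n_resid, V))
      for (r in seq_len(spec$n_runs)) {
        estimates[r, , ] <- mu + rnoise(nrow(conds))
        residuals[r, , ] <- rnoise(spec$n_resid)
      }
      list(estimates = estimates, residuals = residuals,
           conditions = labels, mu = mu)
    })
  })
}

#' Visual-similarity coordinates for the context scenes
#'
#' Emulates the drag-and-drop similarity judgment task: each of the nine
#' context scenes gets a 2-D coordinate drawn uniformly on the unit square,
#' independently of its latent-state assignment (participants were instructed
#' to judge visual content only), so the resulting visual RDM is uncorrelated
#' with the latent-state RDM in expectation.
#'
#' @param design a `task_design`.
#' @param seed integer seed.
#' @return data frame with `context`, `x`, `y`.
#' @export
generate_visual_similarity_coords <- function(design, seed = 1L) {
  with_seed(seed, data.frame(context = design$contexts$context,
                             x = stats::runif(9), y = stats::runif(9),
                             stringsAsFactors = FALSE))
}
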