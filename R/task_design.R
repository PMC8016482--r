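# Task design and trial-sequence generation for the three-phase latent-state
# generalization ("category betting") task.
#
# Nine scene contexts cluster into three latent states (LS A, B, C; three
# contexts per state) by sharing identical category-value associations. Phase 1
# trains three old categories in all nine contexts; phase 2 trains three new
# categories in one context per LS; the generalization phase probes the six
# held-out contexts with the new categories, without feedback.

OLD_CATEGORIES <- c("hands", "foods", "leaves")
NEW_CATEGORIES <- c("faces", "animals", "objects")
LATENT_STATES  <- c("A", "B", "C")

#' Build a randomized task design
#'
#' Draws a complete specification of the experiment: the assignment of nine
#' contexts to three latent states (three per state), the preferred old
#' category of each latent state in initial training, the value signs of the
#' three new categories per latent state (two positive, one negative), and
#' which context group serves as the trained contexts for new-category
#' training. All assignments are functions of `seed` only.
#'
#' @param seed integer seed controlling every random assignment.
#' @return an object of class `task_design`: a list with contexts, latent
#'   states, category labels, reward probabilities (0.9 / 0.1), per-phase
#'   payoffs (+50/-25 initial; +50/-100 new-category; doubled to +100/-200 in
#'   generalization), a latent-state-by-category value-sign map, and the
#'   trained / held-out context split.
#' @export
build_design <- function(seed = 1L) {
  with_seed(seed, {
    # contexts: 9 scene identifiers randomly assigned 3 per latent state,
    # with an introduction order (1..3) within each state ("roadwork" groups)
    ls_assign <- sample(rep(LATENT_STATES, each = 3L))
    contexts <- data.frame(
      context = paste0("ctx", 1:9),
      latent_state = ls_assign,
      stringsAsFactors = FALSE
    )
    contexts$intro_order <- stats::ave(seq_len(9), contexts$latent_state,
                                       FUN = seq_along)

    # each latent state strongly prefers one old category (a permutation, so
    # every state prefers a different category)
    old_pref <- sample(OLD_CATEGORIES)
    names(old_pref) <- LATENT_STATES

    # new-category phase: per latent state, one of the three new categories is
    # negative, the other two positive (independent draws per state)
    new_neg <- vapply(LATENT_STATES, function(l) sample(NEW_CATEGORIES, 1L), "")

    value_map <- matrix(-1L, nrow = 3L, ncol = 6L,
                        dimnames = list(LATENT_STATES,
                                        c(OLD_CATEGORIES, NEW_CATEGORIES)))
    for (l in LATENT_STATES) {
      value_map[l, old_pref[[l]]] <- 1L
      value_map[l, NEW_CATEGORIES] <- 1L
      value_map[l, new_neg[[l]]] <- -1L
    }

    # trained context group for new-category training: one of the three
    # introduction-order groups, i.e. one context per latent state
    trained_group <- sample(1:3, 1L)
    trained <- contexts$context[contexts$intro_order == trained_group]
    names(trained) <- contexts$latent_state[contexts$intro_order == trained_group]
    trained <- trained[LATENT_STATES]

    structure(list(
      seed = seed,
      latent_states = LATENT_STATES,
      contexts = contexts,
      old_categories = OLD_CATEGORIES,
      new_categories = NEW_CATEGORIES,
      reward_prob_high = 0.9,
      reward_prob_low = 0.1,
      payoffs_by_phase = list(
        initial = c(gain = 50, loss = 25),
        new_training = c(gain = 50, loss = 100),
        generalization = c(gain = 100, loss = 200)
      ),
      old_category_preference = old_pref,
      value_map = value_map,
      trained_group = trained_group,
      trained_contexts = trained,
      heldout_contexts = setdiff(contexts$context, trained)
    ), class = "task_design")
  })
}

#' @export
print.task_design <- function(x, ...) {
  cat("Task design (seed ", x$seed, ")\n", sep = "")
  cat("  contexts by latent state:\n")
  for (l in x$latent_states) {
    cat("   ", l, ":", paste(context_of_ls(x, l), collapse = " "),
        " (prefers", x$old_category_preference[[l]], "initially)\n")
  }
  cat("  trained contexts:", paste(x$trained_contexts, collapse = " "), "\n")
  invisible(x)
}

context_ls <- function(design, context) {
  design$contexts$latent_state[match(context, design$contexts$context)]
}

context_of_ls <- function(design, ls) {
  design$contexts$context[design$contexts$latent_state == ls]
}

condition_value <- function(design, context, category) {
  design$value_map[cbind(context_ls(design, context), category)]
}

# the single phase-2-trained context of a held-out (or any) context's LS
linked_trained_context <- function(design, context) {
  unname(design$trained_contexts[context_ls(design, context)])
}

# the other held-out context sharing this context's latent state
sibling_heldout_context <- function(design, context) {
  sibs <- setdiff(intersect(context_of_ls(design, context_ls(design, context)),
                            design$heldout_contexts), context)
  if (length(sibs)) sibs else NA_character_
}

#' The 18 generalization conditions
#'
#' @param design a `task_design`.
#' @return data frame of held-out context x new category conditions in the
#'   canonical order (contexts grouped by latent state, then category), with
#'   value signs.
#' @export
generalization_conditions <- function(design) {
  ctx <- design$contexts[design$contexts$context %in% design$heldout_contexts, ]
  ctx <- ctx[order(ctx$latent_state, ctx$intro_order), ]
  out <- expand.grid(category = design$new_categories, context = ctx$context,
                     stringsAsFactors = FALSE)[, 2:1]
  out$latent_state <- context_ls(design, out$context)
  out$value <- condition_value(design, out$context, out$category)
  out
}

# lognormal ITIs whose post-clipping mean equals `mean_s`; the log-scale sd is
# a free shape parameter and the draw is clipped to [lo, hi]
r_iti_lognormal <- function(n, mean_s = 1, sdlog = 0.5, lo = 0.5, hi = 4) {
  clipped_mean <- function(mu) {
    lo * stats::plnorm(lo, mu, sdlog) +
      hi * stats::plnorm(hi, mu, sdlog, lower.tail = FALSE) +
      exp(mu + sdlog^2 / 2) *
        (stats::pnorm((log(hi) - mu - sdlog^2) / sdlog) -
         stats::pnorm((log(lo) - mu - sdlog^2) / sdlog))
  }
  mu <- stats::uniroot(function(m) clipped_mean(m) - mean_s,
                       c(log(lo) - 2, log(hi)))$root
  pmin(pmax(stats::rlnorm(n, mu, sdlog), lo), hi)
}

new_trial_sequence <- function(df, design) {
  base <- data.frame(phase = NA_character_, session = NA_integer_,
                     run = NA_integer_, block = NA_integer_,
                     miniblock = NA_integer_, trial_in_miniblock = NA_integer_,
                     context = NA_character_, latent_state = NA_character_,
                     category = NA_character_, value = NA_integer_,
                     iti = NA_real_, choice = NA_character_,
                     outcome = NA_real_, correct = NA,
                     rt = NA_real_, stringsAsFactors = FALSE)[0, ]
  for (nm in names(base)) if (is.null(df[[nm]])) df[[nm]] <- base[[nm]][NA][seq_len(nrow(df))]
  df <- df[, names(base)]
  rownames(df) <- NULL
  structure(df, design = design, class = c("trial_sequence", "data.frame"))
}

#' Task design attached to a trial sequence
#'
#' @param x a `trial_sequence`.
#' @return the `task_design` the sequence was generated from.
#' @export
design_of <- function(x) attr(x, "design")

# expand a table of mini-blocks (context, category, n per mini-block) into
# trial rows, numbering mini-blocks sequentially
expand_miniblocks <- function(design, mb, n_per, phase, session, run, block) {
  n_mb <- nrow(mb)
  df <- data.frame(
    phase = phase, session = session, run = run, block = block,
    miniblock = rep(seq_len(n_mb), each = n_per),
    trial_in_miniblock = rep(seq_len(n_per), n_mb),
    context = rep(mb$context, each = n_per),
    category = rep(mb$category, each = n_per),
    stringsAsFactors = FALSE
  )
  df$latent_state <- context_ls(design, df$context)
  df$value <- condition_value(design, df$context, df$category)
  df
}

# one training block: mini-blocks nested by context (all categories of a
# context contiguous), context order and within-context category order random
nested_block_miniblocks <- function(contexts, categories) {
  ctx_order <- sample(contexts)
  do.call(rbind, lapply(ctx_order, function(cx) {
    data.frame(context = cx, category = sample(categories),
               stringsAsFactors = FALSE)
  }))
}

#' Generate the initial training phase
#'
#' Six blocks of 54 trials (nine conditions x 6-trial mini-blocks, nested by
#' context). Blocks 1-2 present the first-introduced context of each latent
#' state, blocks 3-4 the second, blocks 5-6 the third. A final reminder block
#' presents all nine contexts x three old categories in 8-trial mini-blocks
#' (216 trials). Inter-trial intervals are lognormal with mean 1 s clipped to
#' [0.5, 4] s.
#'
#' @param design a `task_design`.
#' @param seed integer seed.
#' @param session session number for the trial records.
#' @return a `trial_sequence` data frame (540 trials).
#' @export
generate_initial_training <- function(design, seed = 1L, session = 2L) {
  with_seed(seed, {
    blocks <- lapply(1:6, function(b) {
      grp <- ceiling(b / 2)
      ctxs <- design$contexts$context[design$contexts$intro_order == grp]
      mb <- nested_block_miniblocks(ctxs, design$old_categories)
      expand_miniblocks(design, mb, 6L, "initial", session, NA_integer_, b)
    })
    mb <- nested_block_miniblocks(design$contexts$context, design$old_categories)
    reminder <- expand_miniblocks(design, mb, 8L, "reminder", session,
                                  NA_integer_, 7L)
    out <- rbind(do.call(rbind, blocks), reminder)
    out$iti <- r_iti_lognormal(nrow(out))
    new_trial_sequence(out, design)
  })
}

#' Generate the new-category training phase
#'
#' One block of 90 trials: a 10-trial mini-block for each combination of the
#' three trained contexts and three new categories, mini-block order
#' randomized (not nested).
#'
#' @inheritParams generate_initial_training
#' @return a `trial_sequence` (90 trials).
#' @export
generate_new_category_training <- function(design, seed = 1L, session = 2L) {
  with_seed(seed, {
    mb <- expand.grid(context = unname(design$trained_contexts),
                      category = design$new_categories,
                      stringsAsFactors = FALSE)
    mb <- mb[sample(nrow(mb)), ]
    out <- expand_miniblocks(design, mb, 10L, "new_training", session,
                             NA_integer_, 1L)
    out$iti <- r_iti_lognormal(nrow(out))
    new_trial_sequence(out, design)
  })
}

#' Generate the blocked (mini-block) generalization phase
#'
#' 180 feedback-free trials: a 10-trial mini-block for each of the 18
#' conditions (six held-out contexts x three new categories), mini-blocks
#' nested by context with context order and within-context category order
#' randomized.
#'
#' @inheritParams generate_initial_training
#' @return a `trial_sequence` (180 trials).
#' @export
generate_blocked_generalization <- function(design, seed = 1L, session = 2L) {
  with_seed(seed, {
    mb <- nested_block_miniblocks(design$heldout_contexts, design$new_categories)
    out <- expand_miniblocks(design, mb, 10L, "generalization_blocked",
                             session, NA_integer_, 1L)
    out$iti <- r_iti_lognormal(nrow(out))
    new_trial_sequence(out, design)
  })
}

#' Generate pseudo-randomized generalization runs
#'
#' Each run presents 10 trials of each of the 18 conditions in a pseudo-random
#' order such that the empirical rate of consecutive trials sharing a latent
#' state or a context stays within `tolerance` of chance (6/18 and 3/18
#' respectively), emulating an efficiency-optimized scanner sequence by
#' rejection sampling. ITIs are uniform on [1, 9] s. With the default six runs
#' (three per scanning session) this yields the full 1080-trial randomized
#' generalization test.
#'
#' @inheritParams generate_initial_training
#' @param n_runs number of 180-trial runs.
#' @param tolerance maximum absolute deviation of the empirical same-LS /
#'   same-context transition fractions from chance.
#' @param max_attempts rejection-sampling cap per run; exceeding it signals an
#'   over-tight tolerance and raises an error.
#' @return list of `trial_sequence` objects, one per run.
#' @export
generate_randomized_generalization_runs <- function(design, seed = 1L,
                                                    n_runs = 6L,
                                                    tolerance = 0.05,
                                                    max_attempts = 1000L) {
  stopifnot(n_runs >= 1L)
  conds <- generalization_conditions(design)
  seeds <- child_seeds(seed, n_runs)
  lapply(seq_len(n_runs), function(r) {
    with_seed(seeds[r], {
      idx <- rep(seq_len(nrow(conds)), each = 10L)
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        ord <- sample(idx)
        tr <- conds[ord, ]
        rates <- transition_rates(tr)
        if (abs(rates$ls_rate - 6 / 18) <= tolerance &&
            abs(rates$context_rate - 3 / 18) <= tolerance) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not satisfy transition-rate tolerance ", tolerance,
                    " after ", max_attempts, " attempts")
      tr$phase <- "generalization_randomized"
      tr$session <- if (r <= 3L) 2L else 3L
      tr$run <- r
      tr$block <- 1L
      tr$miniblock <- NA_integer_
      tr$trial_in_miniblock <- NA_integer_
      tr$iti <- stats::runif(nrow(tr), 1, 9)
      new_trial_sequence(tr, design)
    })
  })
}

#' Sample a trial outcome
#'
#' Draws the probabilistic gold outcome of a feedback trial: a reward with
#' probability 0.9 for positive-value conditions (0.1 for negative-value
#' ones). Selling yields the drawn gain/loss; passing changes no gold but the
#' counterfactual outcome is still shown as feedback.
#'
#' @param design a `task_design`.
#' @param trial a single trial record (list or one-row data frame with
#'   `phase`, `context`, `category`).
#' @param choice `"sell"` or `"pass"`.
#' @param seed optional seed.
#' @return list with `gold_change` and the displayed `feedback` amount.
#' @export
sample_outcome <- function(design, trial, choice = c("sell", "pass"),
                           seed = NULL) {
  choice <- match.arg(choice)
  phase <- as.character(trial$phase)
  if (grepl("^generalization", phase))
    stop("generalization trials provide no feedback")
  pay <- switch(phase,
    initial = ,
    reminder = design$payoffs_by_phase$initial,
    new_training = design$payoffs_by_phase$new_training,
    stop("unknown phase: ", phase))
  v <- condition_value(design, as.character(trial$context),
                       as.character(trial$category))
  p_reward <- if (v > 0) design$reward_prob_high else design$reward_prob_low
  rewarded <- with_seed(seed, stats::runif(1) < p_reward)
  outcome <- if (rewarded) pay[["gain"]] else -pay[["loss"]]
  list(gold_change = if (choice == "sell") outcome else 0,
       feedback = outcome)
}

#' Empirical feature-transition rates of a trial sequence
#'
#' Fraction of consecutive trial pairs sharing the latent state and sharing
#' the context. Pairs spanning a run boundary are excluded when a `run` column
#' is present.
#'
#' @param sequence data frame with `latent_state` and `context` columns (and
#'   optionally `run`).
#' @return list with `ls_rate` and `context_rate`.
#' @export
transition_rates <- function(sequence) {
  stopifnot(nrow(sequence) >= 2L)
  n <- nrow(sequence)
  keep <- rep(TRUE, n - 1L)
  if (!is.null(sequence$run) && !all(is.na(sequence$run))) {
    keep <- sequence$run[-n] == sequence$run[-1L]
    keep[is.na(keep)] <- TRUE
  }
  same_ls <- (sequence$latent_state[-n] == sequence$latent_state[-1L])[keep]
  same_cx <- (sequence$context[-n] == sequence$context[-1L])[keep]
  list(ls_rate = mean(same_ls), context_rate = mean(same_cx))
}

#' Chance transition rates over the generalization conditions
#'
#' Analytic probability that two independently, uniformly drawn generalization
#' conditions share a latent state or a context (6/18 and 3/18 for the
#' standard design, i.e. 33% and 16.7%).
#'
#' @param design a `task_design`.
#' @return list with `ls_rate` and `context_rate`.
#' @export
chance_transition_rates <- function(design) {
  conds <- generalization_conditions(design)
  n <- nrow(conds)
  ls_rate <- mean(vapply(seq_len(n), function(i)
    sum(conds$latent_state == conds$latent_state[i]) / n, 0))
  cx_rate <- mean(vapply(seq_len(n), function(i)
    sum(conds$context == conds$context[i]) / n, 0))
  list(ls_rate = ls_rate, context_rate = cx_rate)
}
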