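# Behavioral analyses: power-law learning/RT curve rate fits, latent-state
# switch costs in the randomized generalization runs, and latent-state
# repetition effects in the mini-blocked generalization phase.

#' Fit a power curve y = a * t^x
#'
#' Least-squares fit of a two-parameter power function of the within-mini-block
#' trial number t (the rate exponent x captures how quickly accuracy or RT
#' changes over repeated trials of a condition). The fit is run `n_starts`
#' times from standard-normal random starting points for (a, x) and the lowest
#' sum of squared errors wins, guarding against local minima.
#'
#' @param y response values at trial positions `1:length(y)` (or `t`).
#' @param n_starts number of random restarts.
#' @param seed integer seed for the starting points.
#' @param t trial numbers (positive), defaults to `seq_along(y)`.
#' @return object of class `power_curve_fit`: list with `a`, `x`, `sse`.
#' @export
fit_power_curve <- function(y, n_starts = 10L, seed = 1L, t = seq_along(y)) {
  if (any(!is.finite(y)) || any(t <= 0)) stop("non-finite y or non-positive t")
  sse <- function(par) {
    pred <- par[1] * t^par[2]
    if (any(!is.finite(pred))) return(1e12)
    sum((y - pred)^2)
  }
  starts <- with_seed(seed, matrix(stats::rnorm(2L * n_starts), n_starts, 2L))
  fits <- lapply(seq_len(n_starts), function(i)
    stats::optim(starts[i, ], sse, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  structure(list(a = best$par[1], x = best$par[2], sse = best$value),
            class = "power_curve_fit")
}

#' @export
print.power_curve_fit <- function(x, ...) {
  cat(sprintf("power curve y = a * t^x: a = %.4f, x = %.4f (sse %.4g)\n",
              x$a, x$x, x$sse))
  invisible(x)
}

# consecutive mini-block id within a sequence (robust to repeated per-block
# numbering)
miniblock_id <- function(sequence) {
  n <- nrow(sequence)
  new_mb <- c(TRUE, sequence$context[-1] != sequence$context[-n] |
                sequence$category[-1] != sequence$category[-n] |
                sequence$block[-1] != sequence$block[-n])
  cumsum(new_mb)
}

#' Within-mini-block learning-curve rate for one phase
#'
#' Averages the behavioral measure (accuracy, or RT in seconds) across
#' mini-blocks at each within-mini-block trial position `1:window`, then fits
#' a power curve to the mean curve and returns its rate exponent. For accuracy
#' curves, the analysis can be limited to the first `max_miniblocks`
#' mini-blocks; for RT speeding curves it can be limited to the first
#' mini-block of each of the first `first_contexts` contexts in presentation
#' order.
#'
#' @param sequence a `trial_sequence` with behavior for a single subject.
#' @param phase phase name to analyze (`"initial"`, `"new_training"`,
#'   `"generalization_blocked"`, ...).
#' @param window number of within-mini-block trial positions used.
#' @param measure `"accuracy"` or `"rt"`.
#' @param max_miniblocks optional cap on the number of mini-blocks used.
#' @param first_contexts optional: use only the first mini-block of each of
#'   the first `first_contexts` contexts.
#' @param n_starts,seed passed to [fit_power_curve()].
#' @return list with `rate` (the exponent x), the full `fit`, and the mean
#'   `curve` by position.
#' @export
learning_curve_rates <- function(sequence, phase, window = 6L,
                                 measure = c("accuracy", "rt"),
                                 max_miniblocks = NULL, first_contexts = NULL,
                                 n_starts = 10L, seed = 1L) {
  measure <- match.arg(measure)
  tr <- sequence[sequence$phase == phase, , drop = FALSE]
  if (!nrow(tr)) stop("no trials in phase ", phase)
  tr$mb <- miniblock_id(tr)
  if (!is.null(first_contexts)) {
    first_mb_of_ctx <- tapply(tr$mb, tr$context, min)
    ctx_order <- unique(tr$context)[seq_len(first_contexts)]
    tr <- tr[tr$mb %in% first_mb_of_ctx[ctx_order], , drop = FALSE]
  }
  if (!is.null(max_miniblocks))
    tr <- tr[tr$mb %in% sort(unique(tr$mb))[seq_len(max_miniblocks)], ,
             drop = FALSE]
  tr <- tr[tr$trial_in_miniblock <= window, , drop = FALSE]
  if (!nrow(tr)) stop("no usable mini-blocks")
  val <- if (measure == "accuracy") as.numeric(tr$correct) else tr$rt
  curve <- tapply(val, tr$trial_in_miniblock, mean, na.rm = TRUE)
  fit <- fit_power_curve(as.numeric(curve), n_starts = n_starts, seed = seed,
                         t = as.numeric(names(curve)))
  list(rate = fit$x, fit = fit, curve = curve)
}

# accept a cohort as a list of trial_sequences or a data frame with `subject`
as_cohort_df <- function(trials) {
  if (is.data.frame(trials)) {
    if (is.null(trials$subject)) trials$subject <- 1L
    return(trials)
  }
  do.call(rbind, lapply(seq_along(trials), function(i) {
    df <- as.data.frame(trials[[i]])
    df$subject <- i
    df
  }))
}

#' Latent-state switch costs in randomized generalization runs
#'
#' Log-transforms RTs of correct trials, z-scores them within session per
#' subject, labels each trial (except run-initial trials, which have no
#' previous trial) by whether the latent state and the context switched or
#' stayed relative to the previous trial, and contrasts latent-state switch
#' versus stay among context-switch trials only, so the latent-state cost is
#' not confounded with a context change.
#'
#' @param trials randomized generalization trials with behavior: a list of
#'   `trial_sequence`s (one per subject) or a data frame with a `subject`
#'   column.
#' @return list with per-subject `cell_means` (three cells), per-subject
#'   `switch_cost` (LS switch minus LS stay among context switches),
#'   `t_switch_cost` (paired t-test across subjects, when n >= 3),
#'   `stay_benefit` (context-and-LS stay minus LS-stay context-switch) and
#'   its test.
#' @export
switch_cost_analysis <- function(trials) {
  df <- as_cohort_df(trials)
  df <- df[grepl("^generalization_randomized", df$phase), , drop = FALSE]
  if (!nrow(df)) stop("no randomized generalization trials")
  df <- df[!is.na(df$rt) & df$rt > 0, , drop = FALSE]
  if (!is.null(df$correct)) df <- df[is.na(df$correct) | df$correct, ,
                                     drop = FALSE]
  df$logrt <- log(df$rt)
  key <- interaction(df$subject, df$session, drop = TRUE)
  df$zrt <- stats::ave(df$logrt, key, FUN = function(x) as.numeric(zscore(x)))

  per_subject <- lapply(split(df, df$subject), function(s) {
    s <- s[order(s$session, s$run), , drop = FALSE]
    n <- nrow(s)
    same_run <- c(FALSE, s$run[-1] == s$run[-n] & s$session[-1] == s$session[-n])
    ls_stay <- c(NA, s$latent_state[-1] == s$latent_state[-n])
    cx_stay <- c(NA, s$context[-1] == s$context[-n])
    cell <- rep(NA_character_, n)
    cell[same_run & !ls_stay & !cx_stay] <- "ls_switch_context_switch"
    cell[same_run & ls_stay & !cx_stay]  <- "ls_stay_context_switch"
    cell[same_run & ls_stay & cx_stay]   <- "ls_stay_context_stay"
    tapply(s$zrt[!is.na(cell)], cell[!is.na(cell)], mean)[
      c("ls_switch_context_switch", "ls_stay_context_switch",
        "ls_stay_context_stay")]
  })
  cells <- do.call(rbind, per_subject)
  colnames(cells) <- c("ls_switch_context_switch", "ls_stay_context_switch",
                       "ls_stay_context_stay")
  switch_cost <- cells[, 1] - cells[, 2]
  stay_benefit <- cells[, 2] - cells[, 3]
  n_sub <- nrow(cells)
  t_sw <- if (n_sub >= 3 && stats::sd(switch_cost) > 0)
    stats::t.test(switch_cost) else NULL
  t_stay <- if (n_sub >= 3 && stats::sd(stay_benefit) > 0)
    stats::t.test(stay_benefit) else NULL
  list(cell_means = cells, switch_cost = switch_cost,
       t_switch_cost = t_sw, stay_benefit = stay_benefit,
       t_stay_benefit = t_stay)
}

#' Latent-state repetition curves in the blocked generalization phase
#'
#' Organizes mini-blocked generalization RTs by the presentation order of
#' latent states (1-3) and of contexts within each latent state (first versus
#' second), averages RTs over mini-blocks at each within-mini-block position,
#' and fits a power curve per cell. Encountering a latent state's second
#' context is expected to be faster on the first trial, and its speeding curve
#' shallower, than the first context.
#'
#' @param trials blocked generalization trials with behavior: list of
#'   `trial_sequence`s or data frame with `subject`.
#' @param window within-mini-block positions used for the curves.
#' @param n_starts,seed passed to [fit_power_curve()].
#' @return list with `curves` (subject x ls_order x context_order x position
#'   mean RTs, long format), `rates` (fitted exponent per subject and cell),
#'   `first_trial` (per-subject first-trial RT for context 1 and 2, averaged
#'   over latent states), and `rate_by_context` (per-subject mean rate for
#'   context 1 and 2).
#' @export
ls_repetition_curves <- function(trials, window = 10L, n_starts = 10L,
                                 seed = 1L) {
  df <- as_cohort_df(trials)
  df <- df[grepl("^generalization_blocked", df$phase), , drop = FALSE]
  if (!nrow(df)) stop("no blocked generalization trials")

  per_subject <- lapply(split(df, df$subject), function(s) {
    s <- s[order(miniblock_id(s), s$trial_in_miniblock), , drop = FALSE]
    ls_ord <- match(s$latent_state, unique(s$latent_state))
    first_ctx <- !duplicated(s$context)
    ctx_first <- s[first_ctx, c("context", "latent_state")]
    ctx_first$ord <- stats::ave(seq_len(nrow(ctx_first)),
                                ctx_first$latent_state, FUN = seq_along)
    ctx_ord <- ctx_first$ord[match(s$context, ctx_first$context)]
    s$ls_order <- ls_ord
    s$context_order <- ctx_ord
    s <- s[s$trial_in_miniblock <= window, , drop = FALSE]
    agg <- stats::aggregate(rt ~ ls_order + context_order + trial_in_miniblock,
                            data = s, FUN = mean, na.rm = TRUE)
    agg
  })

  curves <- do.call(rbind, lapply(names(per_subject), function(sb) {
    cbind(subject = as.integer(sb), per_subject[[sb]])
  }))
  rates <- do.call(rbind, lapply(names(per_subject), function(sb) {
    agg <- per_subject[[sb]]
    cells <- unique(agg[, c("ls_order", "context_order")])
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sub <- agg[agg$ls_order == cells$ls_order[i] &
                   agg$context_order == cells$context_order[i], ]
      sub <- sub[order(sub$trial_in_miniblock), ]
      fit <- fit_power_curve(sub$rt, n_starts = n_starts, seed = seed,
                             t = sub$trial_in_miniblock)
      data.frame(subject = as.integer(sb), ls_order = cells$ls_order[i],
                 context_order = cells$context_order[i],
                 a = fit$a, rate = fit$x)
    }))
  }))
  first_trial <- stats::aggregate(
    rt ~ subject + context_order,
    data = curves[curves$trial_in_miniblock == 1L, ], FUN = mean)
  rate_by_context <- stats::aggregate(rate ~ subject + context_order,
                                      data = rates, FUN = mean)
  list(curves = curves, rates = rates, first_trial = first_trial,
       rate_by_context = rate_by_context)
}
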