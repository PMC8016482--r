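test_that("design structure: contexts partition into latent states and value maps", {
  d <- fixture_design
  expect_equal(nrow(d$contexts), 9L)
  expect_equal(unname(table(d$contexts$latent_state)), rep(3L, 3L),
               ignore_attr = TRUE)
  # trained + held-out contexts partition the nine
  expect_setequal(c(d$trained_contexts, d$heldout_contexts),
                  d$contexts$context)
  expect_length(d$trained_contexts, 3L)
  # initial phase: exactly one high-value old category per latent state
  old <- d$value_map[, d$old_categories]
  expect_equal(unname(rowSums(old > 0)), rep(1L, 3L))
  # new-category phase: exactly two high-value new categories per state
  new <- d$value_map[, d$new_categories]
  expect_equal(unname(rowSums(new > 0)), rep(2L, 3L))
})

test_that("designs are deterministic in the seed and cover all preference permutations", {
  expect_identical(build_design(3L), build_design(3L))
  expect_false(identical(build_design(3L)$contexts, build_design(4L)$contexts))
  perms <- vapply(1:100, function(s)
    paste(build_design(s)$old_category_preference, collapse = "-"), "")
  expect_equal(length(unique(perms)), 6L)  # all 3! assignments occur
})

test_that("initial training layout: 54-trial blocks, 216-trial reminder, nested mini-blocks", {
  seq1 <- generate_initial_training(fixture_design, 11L)
  expect_equal(unname(table(seq1$block[seq1$phase == "initial"])),
               rep(54L, 6L), ignore_attr = TRUE)
  expect_equal(sum(seq1$phase == "reminder"), 216L)
  # mini-blocks are contiguous constant-(context, category) runs of length 6 / 8
  for (b in 1:7) {
    blk <- seq1[seq1$block == b, ]
    key <- paste(blk$context, blk$category)
    runs <- rle(key)
    expect_true(all(runs$lengths == if (b == 7) 8L else 6L))
    expect_equal(length(runs$values), length(unique(key)))
  }
  # blocks 1-2 use the first-introduced context of each latent state
  intro1 <- fixture_design$contexts$context[fixture_design$contexts$intro_order == 1]
  expect_setequal(unique(seq1$context[seq1$block %in% 1:2]), intro1)
  # categories nested by context: each context appears as one contiguous stretch
  blk <- seq1[seq1$block == 1, ]
  expect_equal(length(rle(blk$context)$values), 3L)
})

test_that("new-category training: 90 trials, trained contexts only, 10 per condition", {
  seq2 <- generate_new_category_training(fixture_design, 12L)
  expect_equal(nrow(seq2), 90L)
  expect_setequal(unique(seq2$context), unname(fixture_design$trained_contexts))
  counts <- table(seq2$context, seq2$category)
  expect_true(all(counts == 10L))
  expect_true(all(rle(paste(seq2$context, seq2$category))$lengths == 10L))
})

test_that("blocked generalization: 180 trials over 18 held-out conditions", {
  seq3 <- generate_blocked_generalization(fixture_design, 13L)
  expect_equal(nrow(seq3), 180L)
  conds <- unique(seq3[, c("context", "category")])
  expect_equal(nrow(conds), 18L)
  expect_setequal(unique(seq3$context), fixture_design$heldout_contexts)
  # each held-out context appears in exactly 3 mini-blocks
  mb <- taskstates:::miniblock_id(seq3)
  expect_equal(unname(tapply(mb, seq3$context, function(m) length(unique(m)))),
               rep(3L, 6L), ignore_attr = TRUE)
})

test_that("randomized generalization runs: counts, ITIs, transition rates near chance", {
  runs <- generate_randomized_generalization_runs(fixture_design, 14L)
  expect_length(runs, 6L)
  expect_equal(sum(vapply(runs, nrow, 0L)), 1080L)
  for (r in runs) {
    expect_true(all(table(r$context, r$category) == 10L))
    expect_true(all(r$iti >= 1 & r$iti <= 9))
    rates <- transition_rates(r)
    # binomial 3 SE at n = 179 pairs around 6/18 and 3/18
    expect_lt(abs(rates$ls_rate - 6 / 18), 3 * sqrt(1 / 3 * 2 / 3 / 179))
    expect_lt(abs(rates$context_rate - 3 / 18), 3 * sqrt(1 / 6 * 5 / 6 / 179))
  }
  expect_equal(runs[[1]]$session[1], 2L)
  expect_equal(runs[[6]]$session[1], 3L)
  # over-tight tolerance is reported rather than looping forever
  expect_error(generate_randomized_generalization_runs(
    fixture_design, 1L, n_runs = 1L, tolerance = 1e-5, max_attempts = 5L),
    "tolerance")
})

test_that("training ITIs are lognormal with mean 1 s clipped to [0.5, 4]", {
  seq1 <- generate_initial_training(fixture_design, 15L)
  expect_true(all(seq1$iti >= 0.5 & seq1$iti <= 4))
  expect_lt(abs(mean(seq1$iti) - 1), 0.1)
})

test_that("sequences are byte-identical under the same seed", {
  expect_identical(generate_initial_training(fixture_design, 5L),
                   generate_initial_training(fixture_design, 5L))
  expect_false(identical(generate_blocked_generalization(fixture_design, 5L)$context,
                         generate_blocked_generalization(fixture_design, 6L)$context))
})

test_that("transition_rates: degenerate cases and the analytic chance level", {
  one <- data.frame(latent_state = rep("A", 10), context = rep("ctx1", 10))
  expect_equal(transition_rates(one), list(ls_rate = 1, context_rate = 1))
  alt <- data.frame(latent_state = rep(c("A", "B"), 10),
                    context = rep(c("ctx1", "ctx2"), 10))
  expect_equal(transition_rates(alt), list(ls_rate = 0, context_rate = 0))
  # unconstrained uniform draws converge on the analytic 6/18 chance rate
  conds <- generalization_conditions(fixture_design)
  set.seed(1)
  big <- conds[sample.int(18L, 1e5, replace = TRUE), ]
  r <- transition_rates(big)
  expect_lt(abs(r$ls_rate - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 1e5))
  ch <- chance_transition_rates(fixture_design)
  expect_equal(ch$ls_rate, 6 / 18)
  expect_equal(ch$context_rate, 3 / 18)
})

test_that("sample_outcome follows the stated reward probabilities and payoffs", {
  d <- fixture_design
  conds <- generalization_conditions(d)
  # a high-value and a low-value condition probed in a feedback phase
  hi <- conds[conds$value > 0, ][1, ]; hi$phase <- "new_training"
  lo <- conds[conds$value < 0, ][1, ]; lo$phase <- "new_training"
  set.seed(2)
  draws_hi <- replicate(2e4, sample_outcome(d, hi, "sell")$gold_change)
  expect_setequal(unique(draws_hi), c(50, -100))
  expect_lt(abs(mean(draws_hi > 0) - 0.9), 3 * sqrt(0.9 * 0.1 / 2e4))
  draws_lo <- replicate(2e4, sample_outcome(d, lo, "sell")$gold_change)
  expect_lt(abs(mean(draws_lo > 0) - 0.1), 3 * sqrt(0.9 * 0.1 / 2e4))
  # passing never changes gold but still reports the counterfactual
  p <- sample_outcome(d, hi, "pass", seed = 3)
  expect_equal(p$gold_change, 0)
  expect_true(p$feedback %in% c(50, -100))
  # initial-phase payoffs are +50 / -25
  hi2 <- hi; hi2$phase <- "initial"; hi2$category <- d$old_categories[1]
  set.seed(4)
  draws <- replicate(200, sample_outcome(d, hi2, "sell")$gold_change)
  expect_true(all(draws %in% c(50, -25)))
  gen <- hi; gen$phase <- "generalization_blocked"
  expect_error(sample_outcome(d, gen, "sell"), "no feedback")
})
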