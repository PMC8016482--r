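test_that("rw_update closed forms and bounds", {
  expect_equal(rw_update(0, 0.5), 0.5)
  expect_equal(rw_update(1, 0.9), 1)
  expect_equal(rw_update(0.5, 0.5), 0.75)
  expect_error(rw_update(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(rw_update(0.5, 1.5), "\\[0, 1\\]")
})

test_that("node inventories match the model architectures", {
  d <- fixture_design
  car <- build_network("CAR", d)
  expect_equal(nrow(car$nodes), 27L + 9L + 18L)
  iar <- build_network("IAR", d)
  expect_equal(sum(iar$nodes$type == "ctx"), 9L)
  # category-value nodes are instantiated as experienced: every (category,
  # sign) pair present in the value map, and nothing else
  experienced <- unique(data.frame(
    category = rep(colnames(d$value_map), each = 3),
    value = as.integer(d$value_map)))
  expect_equal(sum(iar$nodes$type == "catval"), nrow(experienced))
  ls <- build_network("LS", d)
  expect_equal(sum(ls$nodes$type == "ls"), 3L)
  expect_equal(sum(ls$nodes$type == "lscat"), 18L)
  hls <- build_network("HLS", d)
  # every context node has exactly one parent latent state
  ctx_nodes <- hls$nodes[hls$nodes$type == "ctx", ]
  expect_equal(ctx_nodes$latent_state,
               taskstates:::context_ls(d, ctx_nodes$context))
  expect_error(build_network("XXX", d))
})

test_that("per-trial rates match the rate walkthroughs", {
  d <- fixture_design
  ctx <- d$heldout_contexts[1]
  tr <- make_trial(d, ctx, "objects")
  p <- fixture_params  # (0.5, 0.2, 0.1)
  r_hls <- classify_and_rate(build_network("HLS", d), tr, p)
  expect_equal(r_hls[[paste0("ctx|", ctx)]], 0.25)           # alpha1^2
  expect_equal(r_hls[[paste0("ctxcat|", ctx, "|objects")]], 0.125)  # alpha1^3
  v <- taskstates:::condition_value(d, ctx, "objects")
  r_iar <- classify_and_rate(build_network("IAR", d), tr, p)
  expect_equal(r_iar[[paste0("catval|objects|", if (v > 0) "+" else "-")]],
               0.5^4)                                        # alpha1^4
  r_ls <- classify_and_rate(build_network("LS", d), tr, p)
  other_ls <- setdiff(d$latent_states, taskstates:::context_ls(d, ctx))[1]
  expect_equal(r_ls[[paste0("lscat|", other_ls, "|faces")]], 0.01)  # alpha3^2
  # old categories cannot be probed during generalization
  expect_error(classify_and_rate(build_network("HLS", d),
                                 make_trial(d, ctx, "hands"), p),
               "not representable")
})

# RT series computed by hand from the rate walkthroughs at alpha = (0.5, 0.2, 0.1)
test_that("step_trial reproduces hand-derived RT series", {
  d <- fixture_design
  ctx <- d$heldout_contexts[1]
  sib <- taskstates:::sibling_heldout_context(d, ctx)
  tr <- make_trial(d, ctx, "objects")
  p <- fixture_params
  hand <- list(CAR = c(1, 0.99, 0.9801),
               IAR = c(2, 1.4375, 1.12890625),
               LS  = c(2, 1.25, 0.8125),
               HLS = c(2, 1.625, 1.328125))
  for (mk in names(hand)) {
    net <- build_network(mk, d)
    rts <- numeric(3)
    for (i in 1:3) {
      st <- step_trial(net, tr, p)
      rts[i] <- st$rt
      net <- st$network
    }
    expect_equal(rts, hand[[mk]], info = mk)
  }
  # second trial probes the sibling held-out context of the same latent state
  hand_sib <- c(CAR = 0.998, IAR = 1.8875, LS = 1.25, HLS = 1.88)
  tr2 <- make_trial(d, sib, "objects")
  for (mk in names(hand_sib)) {
    net <- step_trial(build_network(mk, d), tr, p)$network
    expect_equal(step_trial(net, tr2, p)$rt, hand_sib[[mk]], info = mk)
  }
})

test_that("product-form and step engines agree for all models", {
  for (mk in c("CAR", "IAR", "LS", "HLS")) {
    for (p in list(fixture_params, activation_params(0.9, 0.5, 0.1))) {
      z1 <- predict_sequence(mk, p, fixture_run)
      z2 <- predict_sequence(mk, p, fixture_run, engine = "step")
      expect_equal(as.numeric(z1), as.numeric(z2), tolerance = 1e-12,
                   info = mk)
    }
  }
})

test_that("activations stay in [0, 1] and never decrease", {
  d <- fixture_design
  for (mk in c("CAR", "IAR", "LS", "HLS")) {
    net <- build_network(mk, d)
    prev <- net$activation
    for (t in 1:40) {
      st <- step_trial(net, fixture_run[t, ], activation_params(0.9, 0.6, 0.3))
      net <- st$network
      expect_true(all(net$activation >= prev - 1e-12))
      expect_true(all(net$activation >= 0 & net$activation <= 1))
      prev <- net$activation
    }
  }
})

test_that("raw predicted RT is non-increasing over repetitions of one condition", {
  d <- fixture_design
  rep_seq <- do.call(rbind, replicate(10, make_trial(d, d$heldout_contexts[2],
                                                     "faces"), simplify = FALSE))
  for (mk in c("CAR", "IAR", "LS", "HLS")) {
    z <- predict_sequence(mk, activation_params(0.7, 0.3, 0.1), rep_seq,
                          design = d)
    raw <- attr(z, "raw")
    expect_true(all(diff(raw) <= 1e-12), info = mk)
  }
})

test_that("with alpha2 = alpha3 = 0 there is no cross-latent-state leakage", {
  d <- fixture_design
  p0 <- activation_params(0.8, 0, 0)
  ls_a <- taskstates:::context_ls(d, d$heldout_contexts[1])
  other_ctx <- d$heldout_contexts[taskstates:::context_ls(
    d, d$heldout_contexts) != ls_a][1]
  seqs <- rbind(do.call(rbind, replicate(5, make_trial(d, d$heldout_contexts[1],
                                                       "objects"),
                                         simplify = FALSE)),
                make_trial(d, other_ctx, "faces"))
  for (mk in c("LS", "HLS")) {
    z <- predict_sequence(mk, p0, seqs, design = d)
    raw <- attr(z, "raw")
    # first presentation of the other latent state is entirely unprimed
    expect_equal(raw[6], 2, info = mk)
  }
})

test_that("the four models make distinct predictions at generic parameters", {
  p <- activation_params(0.6, 0.35, 0.12)
  preds <- sapply(c("CAR", "IAR", "LS", "HLS"), function(mk)
    as.numeric(predict_sequence(mk, p, fixture_run)))
  cors <- stats::cor(preds)
  expect_true(all(cors[lower.tri(cors)] < 1 - 1e-6))
})

test_that("constant raw predictions degenerate to flagged zeros", {
  z <- predict_sequence("HLS", activation_params(0, 0, 0), fixture_run)
  expect_true(all(z == 0))
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_error(predict_sequence("HLS", fixture_params, fixture_run[1, ]),
               "at least 2")
})
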