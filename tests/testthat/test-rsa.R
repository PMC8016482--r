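test_that("hypothesis RDMs have the stated ordinal structure", {
  d <- fixture_design
  conds <- generalization_conditions(d)
  rls <- build_hypothesis_rdm("ls", d)
  expect_length(rdm_ltv(rls), 153L)
  expect_true(isSymmetric(rls$mat))
  # same-LS pairs sit at the smaller distance: 3 states x choose(6, 2) pairs
  same_ls <- outer(conds$latent_state, conds$latent_state, "==")
  expect_equal(sum(rdm_ltv(rls) == 1), 3 * choose(6, 2))
  off <- !diag(18)
  expect_true(all((rls$mat == 1)[off] == same_ls[off]))
  rcx <- build_hypothesis_rdm("context", d)
  expect_equal(sum(rdm_ltv(rcx) == 1), 6 * choose(3, 2))
  # category RDM: 1 within, faces-animals 2, animals-objects 3, faces-objects 4
  rcat <- build_hypothesis_rdm("category", d)
  pick <- function(c1, c2) rcat$mat[which(conds$category == c1)[1],
                                    which(conds$category == c2)[2]]
  expect_equal(pick("faces", "faces"), 1)
  expect_equal(pick("faces", "animals"), 2)
  expect_equal(pick("animals", "objects"), 3)
  expect_equal(pick("faces", "objects"), 4)
  # animacy ordering: faces-objects > animals-objects > within
  expect_gt(pick("faces", "objects"), pick("animals", "objects"))
  expect_gt(pick("animals", "objects"), pick("objects", "objects"))
  # visual RDM from coordinates
  coords <- generate_visual_similarity_coords(d, 4L)
  rv <- build_hypothesis_rdm("visual", d, coords)
  same_cx <- outer(conds$context, conds$context, "==")
  expect_true(all(rv$mat[same_cx] == 0))
  expect_error(build_hypothesis_rdm("visual", d), "coordinates")
})

test_that("interaction RDMs are products of z-scored lower triangles", {
  d <- fixture_design
  rls <- build_hypothesis_rdm("ls", d)
  rcat <- build_hypothesis_rdm("category", d)
  inter <- interaction_rdm(rls, rcat)
  za <- as.numeric(zscore(rdm_ltv(rls)))
  zb <- as.numeric(zscore(rdm_ltv(rcat)))
  expect_equal(rdm_ltv(inter), za * zb)
  # self-interaction is the squared z-score, all non-negative
  self <- interaction_rdm(rls, rls)
  expect_true(all(rdm_ltv(self) >= 0))
  # mean of the product equals the correlation times (n-1)/n
  n <- 153
  expect_equal(mean(rdm_ltv(inter)),
               cor(rdm_ltv(rls), rdm_ltv(rcat)) * (n - 1) / n)
  # degenerate constant input
  const <- rdm(matrix(1, 18, 18) - diag(18), rls$conditions)
  expect_warning(z0 <- interaction_rdm(rls, const), "degenerate")
  expect_true(all(rdm_ltv(z0) == 0))
})

# small synthetic pattern set with a known true structure
toy_patterns <- function(mu, n_runs = 8L, n_resid = 40L, noise_sd = 1,
                         seed = 1L) {
  set.seed(seed)
  V <- ncol(mu); C <- nrow(mu)
  est <- array(0, c(n_runs, C, V)); res <- array(0, c(n_runs, n_resid, V))
  for (r in seq_len(n_runs)) {
    est[r, , ] <- mu + matrix(rnorm(C * V, 0, noise_sd), C, V)
    res[r, , ] <- matrix(rnorm(n_resid * V, 0, noise_sd), n_resid, V)
  }
  list(estimates = est, residuals = res,
       conditions = paste0("c", seq_len(C)))
}

test_that("crossnobis is unbiased under the null and matches the analytic signal", {
  # identical true patterns: mean distance over simulations within 3 SE of 0
  dists <- vapply(1:150, function(s) {
    p <- toy_patterns(matrix(0, 2, 25), n_runs = 4L, seed = s)
    crossnobis_rdm(p)$mat[1, 2]
  }, 0)
  expect_lt(abs(mean(dists)), 3 * sd(dists) / sqrt(length(dists)))
  # planted difference d with unit noise: expectation ||d||^2 / V
  V <- 30L
  dvec <- rep(c(1, 0), length.out = V) * 0.8
  mu <- rbind(0, dvec)
  dists <- vapply(1:150, function(s)
    crossnobis_rdm(toy_patterns(mu, n_runs = 6L, seed = 1000 + s))$mat[1, 2], 0)
  expected <- sum(dvec^2) / V
  expect_lt(abs(mean(dists) - expected),
            3 * sd(dists) / sqrt(length(dists)) + 0.01)
})

test_that("crossnobis is invariant to channel permutation", {
  p <- toy_patterns(matrix(rnorm(3 * 20), 3, 20), n_runs = 5L, seed = 11)
  r1 <- crossnobis_rdm(p)
  perm <- sample(20)
  p2 <- list(estimates = p$estimates[, , perm],
             residuals = p$residuals[, , perm], conditions = p$conditions)
  r2 <- crossnobis_rdm(p2)
  expect_equal(r1$mat, r2$mat, tolerance = 1e-10)
  expect_error(crossnobis_rdm(list(estimates = p$estimates[1, , , drop = FALSE],
                                   residuals = p$residuals[1, , , drop = FALSE])),
               "2 runs")
})

test_that("rdm_regression recovers exact structure and flags rank deficiency", {
  d <- fixture_design
  rls <- build_hypothesis_rdm("ls", d)
  # empirical = affine function of one predictor: exact coefficients
  z <- as.numeric(zscore(rdm_ltv(rls)))
  emp_mat <- matrix(0, 18, 18)
  emp_mat[lower.tri(emp_mat)] <- 2.5 * z + 3
  emp <- rdm(emp_mat + t(emp_mat), rls$conditions)
  fit <- rdm_regression(emp, list(ls = rls))
  expect_equal(unname(fit$betas[["ls"]]), 2.5)
  expect_equal(fit$intercept, 3)
  expect_false(fit$rank_deficient)
  # duplicated predictor
  expect_warning(dup <- rdm_regression(emp, list(a = rls, b = rls)),
                 "rank-deficient")
  expect_true(dup$rank_deficient)
  # independent noise: betas shrink toward zero across simulations
  set.seed(2)
  betas <- replicate(50, {
    m <- matrix(0, 18, 18); v <- rnorm(153)
    m[lower.tri(m)] <- v
    rdm_regression(rdm(m + t(m), rls$conditions), list(ls = rls))$betas[["ls"]]
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(50))
})

test_that("group_test is calibrated and the sign-flip permutation agrees with the t-test", {
  # type-I error at the nominal 0.05 level across null cohorts of 16 subjects
  set.seed(3)
  p_vals <- replicate(2000, group_test(matrix(rnorm(16), 16, 1))$p)
  rate <- mean(p_vals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # permutation p agrees with parametric p for Gaussian data
  set.seed(4)
  diffs <- replicate(20, {
    g <- group_test(matrix(rnorm(16, mean = 0.3), 16, 1), n_perm = 2000L,
                    seed = sample.int(1e6, 1))
    abs(g$p - g$p_perm)
  })
  expect_lt(median(diffs), 0.03)
  # zero-variance betas are flagged
  g0 <- group_test(matrix(1, 5, 2))
  expect_true(all(g0$degenerate))
  expect_true(all(is.na(g0$t)))
  expect_error(group_test(matrix(1, 2, 1)), "3 subjects")
})
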