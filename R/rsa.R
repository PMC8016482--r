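# Representational similarity analysis: hypothesis RDMs over the 18
# generalization conditions, cross-validated Mahalanobis (crossnobis)
# empirical RDMs from multivoxel patterns, multiple regression of the
# empirical RDM on z-scored hypothesis predictors, and group-level tests.

#' Construct an RDM object
#'
#' @param mat symmetric dissimilarity matrix (crossnobis distances may be
#'   slightly negative, so no positivity is enforced).
#' @param conditions condition labels (defaults to `rownames(mat)`).
#' @return object of class `rdm`.
#' @export
rdm <- function(mat, conditions = rownames(mat)) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8) stop("RDM must be symmetric")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(nrow(mat)))
  dimnames(mat) <- list(conditions, conditions)
  structure(list(mat = mat, conditions = conditions), class = "rdm")
}

#' Lower-triangle vector view of an RDM
#'
#' The canonical vectorization used throughout: column-major strict lower
#' triangle, 153 entries for 18 conditions.
#'
#' @param x an `rdm`.
#' @return numeric vector of length n(n-1)/2.
#' @export
rdm_ltv <- function(x) {
  stopifnot(inherits(x, "rdm"))
  x$mat[lower.tri(x$mat)]
}

#' @export
print.rdm <- function(x, ...) {
  cat("RDM over", length(x$conditions), "conditions (",
      length(rdm_ltv(x)), "lower-triangle pairs )\n")
  invisible(x)
}

# condition labels in the canonical order
condition_labels <- function(conds) paste(conds$context, conds$category, sep = ":")

#' Hypothesis RDM for one task factor
#'
#' Builds the predicted condition-dissimilarity structure over the 18
#' generalization conditions. For latent state, context, and value the
#' distances are ordinal: 1 for condition pairs sharing the factor level, 2
#' otherwise. The category RDM uses graded animacy-based distances: 1 within a
#' category, 2 between faces and animals, 3 between animals and objects, and 4
#' between faces and objects (inanimate objects more similar to animals than
#' to faces). The visual RDM uses Euclidean distances between the conditions'
#' context coordinates from the similarity judgment task.
#'
#' @param factor one of `"ls"`, `"context"`, `"value"`, `"category"`,
#'   `"visual"`.
#' @param design a `task_design`.
#' @param coords for `factor = "visual"`: 2-D context coordinates, a matrix or
#'   data frame with rownames (or a `context` column) naming the contexts.
#' @return an `rdm`.
#' @export
build_hypothesis_rdm <- function(factor = c("ls", "context", "value",
                                            "category", "visual"),
                                 design, coords = NULL) {
  factor <- match.arg(factor)
  conds <- generalization_conditions(design)
  n <- nrow(conds)
  labels <- condition_labels(conds)
  mat <- matrix(0, n, n)
  if (factor %in% c("ls", "context", "value")) {
    f <- switch(factor, ls = conds$latent_state, context = conds$context,
                value = conds$value)
    mat <- 1 + outer(f, f, "!=")
  } else if (factor == "category") {
    catd <- matrix(c(1, 2, 4,
                     2, 1, 3,
                     4, 3, 1), 3, 3,
                   dimnames = list(c("faces", "animals", "objects"),
                                   c("faces", "animals", "objects")))
    mat <- catd[cbind(rep(conds$category, n),
                      rep(conds$category, each = n))]
    mat <- matrix(mat, n, n)
  } else {
    if (is.null(coords)) stop("visual RDM requires context coordinates")
    if (is.data.frame(coords) && !is.null(coords$context)) {
      rn <- coords$context
      coords <- as.matrix(coords[, setdiff(names(coords), "context")])
      rownames(coords) <- rn
    }
    xy <- coords[conds$context, , drop = FALSE]
    mat <- as.matrix(stats::dist(xy))
  }
  diag(mat) <- 0
  rdm(mat, labels)
}

#' Interaction RDM from two main-effect RDMs
#'
#' Extracts both lower-triangle vectors, z-scores each, and multiplies them
#' elementwise. A constant input degenerates under z-scoring and produces a
#' zero vector with a warning.
#'
#' @param rdm_a,rdm_b `rdm` objects over the same condition set.
#' @return an `rdm` whose lower triangle holds the interaction values
#'   (symmetrized, zero diagonal).
#' @export
interaction_rdm <- function(rdm_a, rdm_b) {
  if (!identical(rdm_a$conditions, rdm_b$conditions))
    stop("condition orders differ")
  za <- zscore(rdm_ltv(rdm_a))
  zb <- zscore(rdm_ltv(rdm_b))
  if (is_degenerate(za) || is_degenerate(zb))
    warning("degenerate (constant) RDM in interaction; returning zeros")
  v <- as.numeric(za) * as.numeric(zb)
  n <- length(rdm_a$conditions)
  mat <- matrix(0, n, n)
  mat[lower.tri(mat)] <- v
  mat <- mat + t(mat)
  rdm(mat, rdm_a$conditions)
}

# Shrinkage-regularized noise covariance from residuals: off-diagonal entries
# are shrunk toward zero with a Ledoit-Wolf / Schafer-Strimmer intensity
# estimated from the data; the diagonal is kept.
shrinkage_covariance <- function(residuals) {
  X <- residuals
  n <- nrow(X)
  if (n < 4L) stop("too few residual samples for covariance estimation")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  wbar <- S * (n - 1) / n
  sum_w2 <- crossprod(Xc^2)
  var_s <- n / (n - 1)^3 * (sum_w2 - n * wbar^2)
  off <- upper.tri(S) | lower.tri(S)
  denom <- sum(S[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(var_s[off]) / denom)) else 1
  Sigma <- (1 - lambda) * S
  diag(Sigma) <- diag(S)
  attr(Sigma, "lambda") <- lambda
  Sigma
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' For each condition pair (i, j), averages over all ordered run pairs (A, B),
#' A != B, the cross-validated quadratic form
#' `(b_iA - b_jA)' Sigma^-1 (b_iB - b_jB) / V`, where `Sigma` is a
#' shrinkage-regularized noise covariance estimated from the run residuals and
#' V the channel count. Cross-validation across independent runs makes the
#' distance unbiased: its expectation is zero when two conditions share the
#' same true pattern, so estimates can be negative.
#'
#' @param patterns list with `estimates` (runs x conditions x channels array),
#'   `residuals` (runs x samples x channels array), and optionally
#'   `conditions` (labels).
#' @return an `rdm` of crossnobis distances.
#' @export
crossnobis_rdm <- function(patterns) {
  E <- patterns$estimates
  res <- patterns$residuals
  stopifnot(length(dim(E)) == 3L, length(dim(res)) == 3L)
  R <- dim(E)[1]; C <- dim(E)[2]; V <- dim(E)[3]
  if (R < 2L) stop("crossnobis needs at least 2 runs")
  # pool run-centered residuals
  pooled <- do.call(rbind, lapply(seq_len(R), function(r)
    scale(res[r, , ], center = TRUE, scale = FALSE)))
  Sigma <- shrinkage_covariance(pooled)
  ch <- tryCatch(chol(Sigma),
                 error = function(e) stop("noise covariance singular after shrinkage"))
  Rinv <- backsolve(ch, diag(V))
  W <- array(0, dim = dim(E))
  for (r in seq_len(R)) W[r, , ] <- E[r, , ] %*% Rinv

  mat <- matrix(0, C, C)
  for (i in seq_len(C - 1L)) {
    for (j in seq((i + 1L), C)) {
      D <- W[, i, , drop = FALSE] - W[, j, , drop = FALSE]
      D <- matrix(D, R, V)
      s <- colSums(D)
      mat[i, j] <- mat[j, i] <-
        (sum(s^2) - sum(D^2)) / (R * (R - 1)) / V
    }
  }
  conds <- patterns$conditions
  if (is.null(conds)) conds <- paste0("cond", seq_len(C))
  rdm(mat, conds)
}

#' Regress an empirical RDM on hypothesis RDMs
#'
#' Ordinary least squares of the empirical lower-triangle vector on the
#' z-scored lower-triangle vectors of the hypothesis RDMs plus an intercept.
#' Main effects and interactions compete for variance simultaneously. The
#' empirical RDM itself is not standardized. A rank-deficient design matrix is
#' flagged and solved by pseudo-inverse.
#'
#' @param empirical an `rdm`.
#' @param hypotheses named list of `rdm` objects over the same conditions.
#' @return list with `betas` (one per predictor), `intercept`,
#'   `rank_deficient` flag, and `fitted` values.
#' @export
rdm_regression <- function(empirical, hypotheses) {
  stopifnot(length(hypotheses) >= 1L)
  if (is.null(names(hypotheses)) || any(names(hypotheses) == ""))
    names(hypotheses) <- paste0("rdm", seq_along(hypotheses))
  y <- rdm_ltv(empirical)
  X <- vapply(hypotheses, function(h) {
    stopifnot(length(rdm_ltv(h)) == length(y))
    as.numeric(zscore(rdm_ltv(h)))
  }, numeric(length(y)))
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  rank_deficient <- qrX$rank < ncol(Xd)
  if (rank_deficient) {
    warning("rank-deficient RDM design matrix; using pseudo-inverse")
    sv <- svd(Xd)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% y / sv$d[pos])
    coefs <- drop(coefs)
  } else {
    coefs <- qr.coef(qrX, y)
  }
  names(coefs) <- colnames(Xd)
  list(betas = coefs[-1], intercept = coefs[[1]],
       rank_deficient = rank_deficient,
       fitted = drop(Xd %*% coefs))
}

#' Group-level test of per-subject RDM regression coefficients
#'
#' One-sample t-test of each predictor's beta coefficients against zero across
#' subjects, optionally with a sign-flip permutation p-value.
#'
#' @param per_subject_betas subjects x predictors matrix (or data frame).
#' @param n_perm number of random sign-flip permutations (0 to skip).
#' @param seed integer seed for the permutations.
#' @return data frame with mean beta, t statistic, df, p-value, permutation
#'   p-value (`NA` if skipped), and a `degenerate` flag for zero-variance
#'   columns.
#' @export
group_test <- function(per_subject_betas, n_perm = 0L, seed = 1L) {
  B <- as.matrix(per_subject_betas)
  if (nrow(B) < 3L) stop("need at least 3 subjects")
  if (is.null(colnames(B))) colnames(B) <- paste0("beta", seq_len(ncol(B)))
  out <- do.call(rbind, lapply(seq_len(ncol(B)), function(j) {
    b <- B[, j]
    if (stats::sd(b) < 1e-12) {
      return(data.frame(predictor = colnames(B)[j], mean = mean(b),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        p_perm = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(b)
    p_perm <- NA_real_
    if (n_perm > 0L) {
      obs <- abs(mean(b))
      flips <- with_seed(seed + j, matrix(sample(c(-1, 1), n_perm * length(b),
                                                replace = TRUE),
                                          n_perm, length(b)))
      null_means <- abs(flips %*% b) / length(b)
      p_perm <- (1 + sum(null_means >= obs)) / (n_perm + 1)
    }
    data.frame(predictor = colnames(B)[j], mean = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_perm = p_perm, degenerate = FALSE)
  }))
  rownames(out) <- NULL
  out
}
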