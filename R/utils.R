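#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded by `seed`, restoring the caller's
# global .Random.seed afterwards so package functions never disturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive independent child seeds from one parent seed (kept < 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Standardize a numeric vector
#'
#' Centers and scales to unit standard deviation. If the standard deviation is
#' below `tol` the vector is degenerate: a zero vector is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param x numeric vector.
#' @param tol degeneracy tolerance on the standard deviation.
#' @return z-scored vector, possibly with a `degenerate` attribute.
#' @export
zscore <- function(x, tol = 1e-10) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (x - mean(x)) / s
}

is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))
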