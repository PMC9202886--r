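#' Permutation test result
#'
#' Common return type of the permutation tests. `p_value` is always
#' `exceedances / n_perm`, with ties (null equal to the observed statistic)
#' counted as exceedances; for exact enumeration `n_perm` is the full size
#' of the permutation space.
#'
#' @param observed Observed statistic.
#' @param null_values Null sample (may be `NULL` for large exact
#'   enumerations where only the count is kept).
#' @param exceedances Number of null statistics at least as extreme as the
#'   observed one.
#' @param n_perm Number of permutations (or the enumerated space size).
#' @param seed Seed used, or `NA` for exact enumeration.
#' @param method `"monte_carlo"` or `"exact"`.
#' @param extra Named list of test-specific details.
#' @return An object of class `perm_result`.
#' @export
perm_result <- function(observed, null_values, exceedances, n_perm,
                        seed = NA_integer_, method = "monte_carlo",
                        extra = list()) {
  stopifnot(exceedances >= 0, exceedances <= n_perm)
  structure(
    c(list(observed = observed, null_values = null_values,
           exceedances = exceedances, n_perm = n_perm,
           p_value = exceedances / n_perm, seed = seed, method = method),
      extra),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed = %.6g, p = %.4g (%s/%s)\n",
              x$method, x$observed, x$p_value,
              format(x$exceedances, big.mark = ","),
              format(x$n_perm, big.mark = ",")))
  invisible(x)
}

# Tie-tolerant comparison: floating sums reordered by permutation can differ
# in the last ulp from the observed value; "or greater" must still count.
exceeds <- function(null, observed) {
  null >= observed - 1e-9 * max(1, abs(observed))
}
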