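# Near-viewpoint asymmetry test. Raw Capture-C counts correlate strongly
# with distance from the viewpoint, so arbitrary permutation is invalid
# there; only permutations preserving each bin's distance are used. These
# are the mirror-pair swaps: exchanging the bin i steps upstream with the
# bin i steps downstream, independently for each i — equivalently a sign
# flip of each paired difference. With n pairs the permutation space has
# 2^n elements and is enumerated exactly when small.

#' Mirror pairs of fine bins around the viewpoint
#'
#' Pair `i` holds the fine-bin values `i` bins upstream (lower coordinates)
#' and `i` bins downstream of the viewpoint bin; the viewpoint bin itself is
#' excluded.
#'
#' @param fine A fine [binned_track()] whose grid covers the viewpoint and
#'   `n_pairs` bins on each side.
#' @param vp A [viewpoint()].
#' @param n_pairs Number of pairs; default 50 (the 50 x 1 kb bins flanking
#'   the viewpoint in a +/-50 kb window).
#' @return An object of class `mirror_pairs` with fields `up`, `down` and
#'   `diffs = up - down`.
#' @export
build_mirror_pairs <- function(fine, vp, n_pairs = 50) {
  stopifnot(inherits(fine, "binned_track"), inherits(vp, "viewpoint"))
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  i0 <- fine$viewpoint_bin
  if (is.na(i0))
    i0 <- as.integer(floor((vp$midpoint - fine$origin) / fine$bin_size) + 1)
  if (i0 - n_pairs < 1L || i0 + n_pairs > length(fine$values))
    stop(sprintf("track covers bins %d..%d but pairs need %d..%d",
                 1L, length(fine$values), i0 - n_pairs, i0 + n_pairs),
         call. = FALSE)
  up <- fine$values[i0 - seq_len(n_pairs)]
  down <- fine$values[i0 + seq_len(n_pairs)]
  structure(list(up = up, down = down, diffs = up - down,
                 n_pairs = n_pairs, viewpoint_bin = i0),
            class = "mirror_pairs")
}

#' Upstream-minus-downstream statistic
#'
#' @param pairs A [build_mirror_pairs()] object.
#' @return `sum(up) - sum(down)`.
#' @export
updown_statistic <- function(pairs) {
  stopifnot(inherits(pairs, "mirror_pairs"))
  sum(pairs$diffs)
}

#' Distance-preserving sign-flip asymmetry test
#'
#' Tests the null hypothesis that remodelling flanking the viewpoint is
#' symmetric. Each permutation independently swaps or keeps each mirror
#' pair, i.e. flips the sign of each paired difference, giving
#' `T' = sum(+/- x_i)`. Two-sided by default: `p` is the fraction of
#' permutations with `|T'| >= |T|` (ties count). With `n_pairs <=
#' exact_threshold` all `2^n` sign assignments are enumerated
#' (meet-in-the-middle) and `p` is exact; otherwise Monte Carlo with `seed`.
#'
#' @param pairs A [build_mirror_pairs()] object.
#' @param n_perm Monte-Carlo sample size, default 10000.
#' @param seed Integer seed (required for the Monte-Carlo path).
#' @param exact_threshold Enumerate exactly when `n_pairs` is at most this;
#'   default 20 (about a million assignments).
#' @param alternative `"two.sided"` (default), `"greater"` (upstream
#'   excess) or `"less"`.
#' @return A [perm_result()]; for the exact path `n_perm` is `2^n_pairs`
#'   and `null_values` is kept only when the space is small.
#' @export
asymmetry_test <- function(pairs, n_perm = 10000, seed = NULL,
                           exact_threshold = 20,
                           alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(pairs, "mirror_pairs"))
  alternative <- match.arg(alternative)
  x <- pairs$diffs
  n <- length(x)
  observed <- sum(x)
  tol <- 1e-9 * max(1, abs(observed))
  extreme <- switch(alternative,
    two.sided = function(t) abs(t) >= abs(observed) - tol,
    greater = function(t) t >= observed - tol,
    less = function(t) t <= observed + tol)

  if (n <= exact_threshold) {
    # meet-in-the-middle: all signed sums of each half, then count pairs
    half_sums <- function(xs) {
      s <- 0
      for (xi in xs) s <- c(s + xi, s - xi)
      s
    }
    a <- half_sums(x[seq_len(floor(n / 2))])
    b <- sort(half_sums(x[setdiff(seq_len(n), seq_len(floor(n / 2)))]))
    nb <- length(b)
    # pairs (a_i, b_j) with a_i + b_j >= thr, resp. <= thr (tie-tolerant)
    count_ge <- function(thr) sum(nb - findInterval(thr - a - tol, b))
    count_le <- function(thr) sum(findInterval(thr - a + tol, b))
    total <- 2^n
    exc <- switch(alternative,
      greater = count_ge(observed),
      less = count_le(observed),
      two.sided = if (abs(observed) <= tol) total
                  else count_ge(abs(observed)) + count_le(-abs(observed)))
    null_vals <- if (n <= 16) as.vector(outer(a, b, `+`)) else NULL
    return(perm_result(observed, null_vals, exc, total, NA_integer_,
                       method = "exact",
                       extra = list(alternative = alternative, n_pairs = n)))
  }

  if (is.null(seed)) stop("seed is required for Monte-Carlo testing", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  null_values <- as.vector(signs %*% x)
  exc <- sum(extreme(null_values))
  perm_result(observed, null_values, exc, n_perm, seed,
              method = "monte_carlo",
              extra = list(alternative = alternative, n_pairs = n))
}

#' Size of the distance-preserving permutation space
#'
#' `2^n_pairs`: each of the `n_pairs` mirror pairs is independently swapped
#' or kept. Exact as an integer up to `n_pairs = 53` (the value is held in
#' a double); with the default 50 pairs this is 2^50 = 1,125,899,906,842,624.
#'
#' @param n_pairs Non-negative integer.
#' @return `2^n_pairs` as a numeric scalar.
#' @export
count_permutations <- function(n_pairs) {
  n_pairs <- as.numeric(n_pairs)
  if (length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 0 ||
      n_pairs != floor(n_pairs))
    stop("n_pairs must be a non-negative integer", call. = FALSE)
  2^n_pairs
}
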