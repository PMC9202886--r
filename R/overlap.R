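# Enrichment of interacting fragments for ChIP-seq peak overlap. The null
# resamples fragments from the fragment universe (the grid Capture-C imposes)
# rather than shuffling peak positions; the resulting null is exactly
# hypergeometric in the number of peak-overlapping fragments drawn, which
# pins the Monte-Carlo implementation in tests.

#' Number of query intervals overlapping any peak
#'
#' Overlap means intersection by at least 1 bp under half-open semantics:
#' a query ending where a peak starts does not overlap it.
#'
#' @param query `GRanges` of fragments.
#' @param peaks `GRanges` of peaks.
#' @return Integer count of query intervals hitting >= 1 peak.
#' @export
overlap_count <- function(query, peaks) {
  sum(IRanges::countOverlaps(query, peaks, minoverlap = 1L) > 0L)
}

#' Peak-overlap permutation enrichment test
#'
#' Observed statistic: number of query fragments overlapping at least one
#' peak. Each permutation draws `length(query)` fragments uniformly without
#' replacement from the universe and recounts; `p` is the fraction of
#' permutations with a count at least the observed one (ties count).
#'
#' @param query `GRanges` of interacting fragments; must be a subset of
#'   `universe`.
#' @param peaks `GRanges` of peak intervals (e.g. H3K4me1 ChIP-seq peaks).
#' @param universe `GRanges` of all candidate fragments, e.g. every
#'   restriction fragment in the tested region.
#' @param n_perm Number of permutations, default 1000.
#' @param seed Integer seed (required).
#' @return A [perm_result()] with extras `n_query`, `n_universe` and
#'   `n_universe_hits`.
#' @export
overlap_test <- function(query, peaks, universe, n_perm = 1000, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  k <- length(query)
  n <- length(universe)
  if (k > n) stop("query larger than universe", call. = FALSE)
  if (!all(gr_keys(query) %in% gr_keys(universe)))
    stop("query fragments must belong to the universe", call. = FALSE)
  hit <- IRanges::countOverlaps(universe, peaks, minoverlap = 1L) > 0L
  observed <- overlap_count(query, peaks)
  set.seed(as.integer(seed))
  null_values <- vapply(seq_len(n_perm),
                        function(b) sum(hit[sample.int(n, k)]), 0L)
  exc <- sum(null_values >= observed)
  perm_result(observed, null_values, exc, n_perm, seed,
              extra = list(n_query = k, n_universe = n,
                           n_universe_hits = sum(hit)))
}
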