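# Median-of-ratios size-factor normalization and the per-condition mean
# difference ("delta") track. Replicates stay separate columns until
# delta_track() averages them within condition.

#' Median-of-ratios size factors
#'
#' For sample j the factor is the median over fragments i of
#' `count[i, j] / geometric_mean_k(count[i, k])`, taken over fragments with
#' strictly positive counts in every sample (the geometric mean is undefined
#' at zero; rows with any zero are excluded from the median but still get
#' normalized). Factors are scale-equivariant: multiplying one library's
#' counts by c multiplies its factor by `c^(1 - 1/m)` and the others by
#' `c^(-1/m)`.
#'
#' @param cm A [count_matrix()] (or bare numeric matrix).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(counts) < 1L) stop("need at least one sample", call. = FALSE)
  log_counts <- log(counts)
  all_pos <- rowSums(!is.finite(log_counts)) == 0L
  if (!any(all_pos))
    stop(paste("no fragment has positive counts in every sample;",
               "pre-filter or add a pseudo-row before estimating size factors"),
         call. = FALSE)
  lc <- log_counts[all_pos, , drop = FALSE]
  log_geo <- rowMeans(lc)
  sf <- exp(apply(lc - log_geo, 2L, stats::median))
  names(sf) <- colnames(counts)
  sf
}

#' Divide each sample's counts by its size factor
#'
#' @param cm A [count_matrix()].
#' @param factors Named vector from [size_factors()]; must cover all samples.
#' @return A [count_matrix()] of normalized (fractional) counts.
#' @export
normalize_counts <- function(cm, factors = size_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  ids <- cm$samples$sample_id
  if (!all(ids %in% names(factors)))
    stop(sprintf("missing size factor for sample(s): %s",
                 paste(setdiff(ids, names(factors)), collapse = ", ")),
         call. = FALSE)
  f <- factors[ids]
  if (any(!is.finite(f)) || any(f <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  out <- cm
  out$counts <- sweep(cm$counts, 2L, f, "/")
  out
}

#' Difference of mean normalized counts between two conditions
#'
#' Per fragment, `delta = mean over cond_a replicates - mean over cond_b
#' replicates`. Negative values indicate higher interaction counts in
#' `cond_b`; swapping the conditions negates the track exactly.
#'
#' @param cm A normalized [count_matrix()].
#' @param cond_a,cond_b Condition labels present in `cm$samples$condition`.
#' @return A `GRanges` with metadata column `delta` and the condition pair
#'   recorded in `S4Vectors::metadata()`.
#' @export
delta_track <- function(cm, cond_a, cond_b) {
  stopifnot(inherits(cm, "count_matrix"))
  cond <- cm$samples$condition
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% cond)
      stop(sprintf("unknown condition '%s' (have: %s)", cc,
                   paste(unique(cond), collapse = ", ")), call. = FALSE)
  }
  mean_a <- rowMeans(cm$counts[, cond == cond_a, drop = FALSE])
  mean_b <- rowMeans(cm$counts[, cond == cond_b, drop = FALSE])
  gr <- cm$fragments
  GenomicRanges::mcols(gr)$delta <- mean_a - mean_b
  S4Vectors::metadata(gr)$condition_pair <- c(cond_a, cond_b)
  gr
}
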