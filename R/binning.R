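# Trimming to the region of interest, fixed-width binning and re-binning.
# Fragment values are allocated to bins proportionally to overlap width so
# that total signal is conserved exactly; re-binning sums whole groups of
# fine bins, so fine and coarse tracks have identical totals.

#' Trim a delta track to the region of interest around a viewpoint
#'
#' Keeps fragments intersecting `[midpoint - radius, midpoint + radius)`;
#' fragments straddling the boundary are retained whole.
#'
#' @param track `GRanges` with a `delta` (or `score`) column.
#' @param vp A [viewpoint()] on the same chromosome.
#' @param radius ROI half-width in bp; default 500000 (the meso-scale
#'   analysis window of +/-500 kb around the viewpoint midpoint).
#' @return The trimmed `GRanges`.
#' @export
trim_to_roi <- function(track, vp, radius = 500000) {
  stopifnot(inherits(vp, "viewpoint"))
  chroms <- unique(as.character(GenomicRanges::seqnames(track)))
  if (!vp$chrom %in% chroms && length(track))
    stop(sprintf("viewpoint chromosome %s absent from track (%s)",
                 vp$chrom, paste(chroms, collapse = ",")), call. = FALSE)
  roi <- gr_from_bed0(vp$chrom, max(0, vp$midpoint - radius), vp$midpoint + radius)
  IRanges::subsetByOverlaps(track, roi)
}

#' Binned difference track
#'
#' Constructor for the fixed-width binned representation: bin `i` (1-based)
#' spans `[origin + (i-1) * bin_size, origin + i * bin_size)` in 0-based
#' genomic coordinates.
#'
#' @param chrom Chromosome.
#' @param origin 0-based start of the first bin.
#' @param bin_size Bin width in bp.
#' @param values Numeric vector of per-bin values.
#' @param viewpoint_bin Index of the bin containing the viewpoint midpoint,
#'   or `NA`.
#' @param partial_tail `TRUE` when the last bin of a re-binned track sums an
#'   incomplete group of fine bins.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(chrom, origin, bin_size, values,
                         viewpoint_bin = NA_integer_, partial_tail = FALSE) {
  # origin may extend below coordinate 0 when a boundary-straddling fragment
  # is retained whole; the grid alignment matters, not the leading empty bins
  stopifnot(bin_size >= 1, all(is.finite(values)))
  structure(list(chrom = as.character(chrom), origin = as.numeric(origin),
                 bin_size = as.numeric(bin_size), values = as.numeric(values),
                 viewpoint_bin = as.integer(viewpoint_bin),
                 partial_tail = isTRUE(partial_tail)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track %s: %d bins of %g bp from %g (total %.6g%s)\n",
              x$chrom, length(x$values), x$bin_size, x$origin, sum(x$values),
              if (x$partial_tail) ", partial tail" else ""))
  invisible(x)
}

#' Bin a fragment-level delta track to a fixed width
#'
#' Each fragment's value is split across the bins it overlaps in proportion
#' to the overlap width, so the sum over bins equals the sum over fragments.
#' The bin grid is anchored at `origin`; when fragments extend below it,
#' the grid is extended downward by whole bins (bin boundaries are
#' preserved). With `origin = midpoint - radius` the viewpoint midpoint
#' falls exactly on a bin boundary, making the up/downstream flanks
#' symmetric.
#'
#' @param track `GRanges` with a `delta` (or `score`) metadata column.
#' @param bin_size Bin width in bp, default 1000 (fine 1 kb bins).
#' @param origin 0-based coordinate of a bin boundary; default
#'   `vp$midpoint - radius` when `vp` is given, else the first fragment start.
#' @param vp Optional [viewpoint()] used to anchor the grid and record the
#'   viewpoint bin.
#' @param radius ROI half-width used for the default origin.
#' @return A [binned_track()].
#' @export
bin_track <- function(track, bin_size = 1000, origin = NULL, vp = NULL,
                      radius = 500000) {
  stopifnot(bin_size >= 1)
  val <- GenomicRanges::mcols(track)$delta %||% GenomicRanges::mcols(track)$score
  if (is.null(val)) stop("track needs a 'delta' or 'score' column", call. = FALSE)
  chroms <- unique(as.character(GenomicRanges::seqnames(track)))
  if (length(chroms) > 1L) stop("binning is per-chromosome", call. = FALSE)
  if (is.null(origin))
    origin <- if (!is.null(vp)) vp$midpoint - radius
              else GenomicRanges::start(track)[1L] - 1L
  if (length(track) == 0L)
    return(binned_track(chroms %||% "chr?", origin, bin_size, numeric(0)))
  s0 <- GenomicRanges::start(track) - 1
  e0 <- as.numeric(GenomicRanges::end(track))
  if (min(s0) < origin)  # extend down by whole bins, keeping boundaries
    origin <- origin - bin_size * ceiling((origin - min(s0)) / bin_size)
  n_bins <- ceiling((max(e0) - origin) / bin_size)
  bins <- numeric(n_bins)
  first <- floor((s0 - origin) / bin_size) + 1
  last <- floor((e0 - 1 - origin) / bin_size) + 1
  for (i in seq_along(val)) {
    idx <- first[i]:last[i]
    lo <- pmax(s0[i], origin + (idx - 1) * bin_size)
    hi <- pmin(e0[i], origin + idx * bin_size)
    bins[idx] <- bins[idx] + val[i] * (hi - lo) / (e0[i] - s0[i])
  }
  vp_bin <- NA_integer_
  if (!is.null(vp)) {
    vb <- floor((vp$midpoint - origin) / bin_size) + 1
    if (vb >= 1 && vb <= n_bins) vp_bin <- as.integer(vb)
  }
  binned_track(chroms, origin, bin_size, bins, vp_bin)
}

#' Re-bin a binned track to a coarser width
#'
#' Sums consecutive groups of `factor` fine bins. A trailing incomplete
#' group is summed as-is and flagged via `partial_tail`. Totals are
#' conserved exactly.
#'
#' @param track A [binned_track()].
#' @param factor Integer >= 1; default 10 (1 kb fine bins -> 10 kb bins).
#' @return A [binned_track()] with `bin_size * factor` wide bins.
#' @export
rebin <- function(track, factor = 10) {
  stopifnot(inherits(track, "binned_track"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(track)
  v <- track$values
  n <- length(v)
  n_coarse <- ceiling(n / factor)
  partial <- (n %% factor) != 0L
  if (partial) v <- c(v, numeric(n_coarse * factor - n))
  dim(v) <- c(factor, n_coarse)
  vp_bin <- if (is.na(track$viewpoint_bin)) NA_integer_
            else as.integer(ceiling(track$viewpoint_bin / factor))
  binned_track(track$chrom, track$origin, track$bin_size * factor,
               colSums(v), vp_bin, partial_tail = partial)
}
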