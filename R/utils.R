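# Internal helpers shared across modules.

#' @importFrom GenomicRanges GRanges start end width seqnames mcols mcols<-
#' @importFrom IRanges IRanges subsetByOverlaps countOverlaps findOverlaps
#' @importFrom S4Vectors metadata metadata<- queryHits subjectHits
NULL

# GRanges from BED-style (0-based half-open) coordinates.
gr_from_bed0 <- function(chrom, start0, end0) {
  if (any(start0 < 0)) stop("start must be >= 0", call. = FALSE)
  if (any(end0 <= start0)) stop("end must be > start", call. = FALSE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
}

# BED-style data.frame (chrom, start, end) from a GRanges.
bed0_from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Full-precision decimal rendering: round-trips doubles exactly.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

# Sort a GRanges by (chrom, start) without needing seqinfo levels.
sort_gr <- function(gr) {
  gr[order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))]
}

# Stable string key for a fragment interval (BED coordinates).
gr_keys <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

assert_overlap_free <- function(gr, what = "fragments") {
  gr2 <- sort_gr(gr)
  if (length(gr2) > 1L) {
    same <- as.character(GenomicRanges::seqnames(gr2))[-length(gr2)] ==
      as.character(GenomicRanges::seqnames(gr2))[-1L]
    # half-open abutment (end0 == next start0) is not an overlap
    clash <- same & (GenomicRanges::end(gr2)[-length(gr2)] >= GenomicRanges::start(gr2)[-1L])
    if (any(clash)) stop(sprintf("overlapping %s detected", what), call. = FALSE)
  }
  invisible(gr2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
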