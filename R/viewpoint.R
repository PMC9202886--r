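#' Capture viewpoint
#'
#' A viewpoint is the captured restriction fragment whose contacts are
#' profiled; every distance in the analysis is measured from its midpoint.
#' Coordinates are given BED-style (0-based start, exclusive end), the
#' convention of the fragment files the viewpoint is usually copied from.
#'
#' @param name Label, e.g. the promoter the viewpoint fragment contains.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open span of the viewpoint fragment.
#' @return An object of class `viewpoint` with fields `name`, `chrom`,
#'   `start`, `end` and `midpoint` (`floor((start + end) / 2)`, 0-based).
#' @examples
#' vp <- viewpoint("P1", "chr2", 105668000, 105669800)
#' vp$midpoint
#' @export
viewpoint <- function(name, chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("viewpoint takes scalar coordinates", call. = FALSE)
  if (start < 0 || end <= start) stop("need 0 <= start < end", call. = FALSE)
  mid <- floor((start + end) / 2)
  stopifnot(mid >= start, mid < end)
  structure(
    list(name = as.character(name), chrom = as.character(chrom),
         start = start, end = end, midpoint = mid),
    class = "viewpoint"
  )
}

#' @export
print.viewpoint <- function(x, ...) {
  cat(sprintf("viewpoint '%s' %s:%d-%d (midpoint %d)\n",
              x$name, x$chrom, x$start, x$end, x$midpoint))
  invisible(x)
}
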