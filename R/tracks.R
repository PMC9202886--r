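#' Per-fragment count track for one sample
#'
#' Holds an ordered, overlap-free set of restriction-fragment intervals and a
#' non-negative count (raw or normalized, hence real-valued) per fragment,
#' together with sample metadata. Fragments are stored as a [GenomicRanges::GRanges]
#' (1-based closed internally; file readers and writers convert from/to the
#' 0-based half-open BED convention).
#'
#' @param fragments A `GRanges` of fragment intervals.
#' @param counts Numeric vector, one non-negative value per fragment.
#' @param sample_id,condition,replicate Sample metadata labels.
#' @return An object of class `fragment_track`.
#' @export
fragment_track <- function(fragments, counts,
                           sample_id = "sample", condition = NA_character_,
                           replicate = NA_character_) {
  if (length(counts) != length(fragments))
    stop("counts length must equal fragment count", call. = FALSE)
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0", call. = FALSE)
  ord <- order(as.character(GenomicRanges::seqnames(fragments)),
               GenomicRanges::start(fragments))
  fragments <- fragments[ord]
  counts <- counts[ord]
  assert_overlap_free(fragments)
  structure(
    list(fragments = fragments, counts = counts,
      sample_id = as.character(sample_id),
      condition = as.character(condition),
      replicate = as.character(replicate)),
    class = "fragment_track"
  )
}

#' @export
print.fragment_track <- function(x, ...) {
  cat(sprintf("fragment_track '%s' (%s/%s): %d fragments, total count %.6g\n",
              x$sample_id, x$condition, x$replicate,
              length(x$fragments), sum(x$counts)))
  invisible(x)
}

#' Fragment-by-sample count matrix
#'
#' The container for a multi-sample Capture-C experiment: one row per
#' restriction fragment, one column per sample, with per-column condition and
#' replicate labels. At least two conditions are needed for differential work.
#'
#' @param fragments `GRanges` of fragment intervals (rows).
#' @param counts Numeric matrix, `length(fragments)` x `nrow(samples)`,
#'   finite and non-negative.
#' @param samples `data.frame` with columns `sample_id`, `condition`,
#'   `replicate`, one row per column of `counts`.
#' @return An object of class `count_matrix`.
#' @seealso [size_factors()], [normalize_counts()], [delta_track()]
#' @export
count_matrix <- function(fragments, counts, samples) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(fragments))
    stop("counts must have one row per fragment", call. = FALSE)
  if (ncol(counts) != nrow(samples))
    stop("counts must have one column per sample", call. = FALSE)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples needs columns sample_id, condition, replicate", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0", call. = FALSE)
  ord <- order(as.character(GenomicRanges::seqnames(fragments)),
               GenomicRanges::start(fragments))
  fragments <- fragments[ord]
  counts <- counts[ord, , drop = FALSE]
  assert_overlap_free(fragments)
  colnames(counts) <- samples$sample_id
  structure(
    list(fragments = fragments, counts = counts,
         samples = as.data.frame(samples)[, req]),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d fragments x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%s/%s", x$samples$sample_id,
                            x$samples$condition, x$samples$replicate),
                    collapse = ", ")))
  invisible(x)
}

#' Combine single-sample tracks into a count matrix
#'
#' All tracks must share the same fragment grid.
#'
#' @param tracks List of [fragment_track()] objects.
#' @return A [count_matrix()].
#' @export
bind_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  ref <- tracks[[1L]]$fragments
  for (t in tracks[-1L]) {
    if (length(t$fragments) != length(ref) ||
        !all(GenomicRanges::start(t$fragments) == GenomicRanges::start(ref)) ||
        !all(as.character(GenomicRanges::seqnames(t$fragments)) ==
             as.character(GenomicRanges::seqnames(ref))))
      stop("all tracks must share one fragment grid", call. = FALSE)
  }
  count_matrix(
    ref,
    vapply(tracks, function(t) t$counts, numeric(length(ref))),
    data.frame(sample_id = vapply(tracks, `[[`, "", "sample_id"),
               condition = vapply(tracks, `[[`, "", "condition"),
               replicate = vapply(tracks, `[[`, "", "replicate"),
               stringsAsFactors = FALSE)
  )
}
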