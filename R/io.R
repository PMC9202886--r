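# Readers and writers for the plain-text formats the pipeline touches:
# bedGraph (4-col), BED (3+ col), TSV count matrices and significance tables.
# Files use the BED convention (0-based half-open); conversion to the 1-based
# GRanges representation happens here and nowhere else.

read_tsv_checked <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < n_min_cols)
  if (length(bad))
    stop(sprintf("%s parse error at line %d: expected >= %d tab-separated fields",
                 what, bad[1L], n_min_cols), call. = FALSE)
  parts
}

num_field <- function(parts, i, path, what) {
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", i)))
  bad <- which(is.na(x))
  if (length(bad))
    stop(sprintf("%s parse error at line %d of %s: field %d not numeric",
                 what, bad[1L], path, i), call. = FALSE)
  x
}

#' Read a bedGraph track of per-fragment counts
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based half-open.
#' Intervals are validated to be non-overlapping and returned sorted.
#'
#' @param path bedGraph file.
#' @param sample_id,condition,replicate Metadata attached to the track;
#'   defaults derive `sample_id` from the file name. Metadata is never
#'   inferred beyond that.
#' @return A [fragment_track()].
#' @export
read_bedgraph <- function(path, sample_id = NULL, condition = NA, replicate = NA) {
  parts <- read_tsv_checked(path, 4L, "bedGraph")
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (is.null(parts)) {
    return(fragment_track(GenomicRanges::GRanges(), numeric(0),
                          sample_id, condition, replicate))
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- num_field(parts, 2L, path, "bedGraph")
  end0 <- num_field(parts, 3L, path, "bedGraph")
  value <- num_field(parts, 4L, path, "bedGraph")
  fragment_track(gr_from_bed0(chrom, start0, end0), value,
                 sample_id, condition, replicate)
}

#' Write a fragment track (or binned track) as bedGraph
#'
#' Values are rendered with full precision so that
#' `read_bedgraph(write_bedgraph(t))` reproduces `t` exactly and rewriting a
#' re-read file is byte-identical.
#'
#' @param track A [fragment_track()], [delta_track()] result, or
#'   [binned_track] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (inherits(track, "fragment_track")) {
    bed <- bed0_from_gr(track$fragments); val <- track$counts
  } else if (inherits(track, "binned_track")) {
    n <- length(track$values)
    bed <- data.frame(chrom = track$chrom,
                      start = track$origin + (seq_len(n) - 1) * track$bin_size,
                      end = track$origin + seq_len(n) * track$bin_size)
    val <- track$values
    # a grid anchored at the viewpoint can lead with bins below coordinate 0;
    # clip to representable BED space (the clipped span holds no fragments)
    keep <- bed$end > 0
    bed <- bed[keep, , drop = FALSE]
    val <- val[keep]
    bed$start <- pmax(bed$start, 0)
  } else if (inherits(track, "GRanges")) {
    bed <- bed0_from_gr(track)
    val <- GenomicRanges::mcols(track)$delta %||% GenomicRanges::mcols(track)$score
    if (is.null(val)) stop("GRanges needs a 'delta' or 'score' column", call. = FALSE)
  } else stop("unsupported track type", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s", bed$chrom, as.integer(bed$start),
                     as.integer(bed$end), fmt_full(val)), con)
  invisible(path)
}

#' Read ChIP-seq peak (or any) intervals from BED
#'
#' Accepts 3+ columns; extra columns (name, score, strand, ...) are ignored.
#' Output is sorted by (chrom, start), 1-based GRanges internally.
#'
#' @param path BED file.
#' @return A `GRanges` of peak intervals.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) && any(GenomicRanges::width(gr) < 1L))
    stop("BED interval with start >= end", call. = FALSE)
  GenomicRanges::mcols(gr) <- NULL
  unname(sort_gr(gr))
}

#' Write intervals as 3-column BED
#'
#' @param gr A `GRanges`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  bed <- bed0_from_gr(gr)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(bed))
    writeLines(sprintf("%s\t%d\t%d", bed$chrom, as.integer(bed$start),
                       as.integer(bed$end)), con)
  invisible(path)
}

#' Read a TSV count matrix plus sample metadata
#'
#' The matrix file has columns `chrom`, `start`, `end` (BED convention) then
#' one numeric column per sample; the sidecar metadata TSV has columns
#' `sample_id`, `condition`, `replicate`. Sample metadata always travels in
#' the sidecar (or is given programmatically), never parsed out of count
#' column names.
#'
#' @param path Count matrix TSV with a header line.
#' @param samples Either a path to the metadata TSV or a `data.frame`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, samples) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(tab)))
    stop("count matrix needs chrom/start/end columns", call. = FALSE)
  if (is.character(samples))
    samples <- utils::read.table(samples, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  cnt <- as.matrix(tab[, setdiff(names(tab), c("chrom", "start", "end")), drop = FALSE])
  cnt <- cnt[, samples$sample_id, drop = FALSE]
  count_matrix(gr_from_bed0(tab$chrom, tab$start, tab$end), cnt, samples)
}

#' Write a count matrix and its sample metadata as TSV
#'
#' @param cm A [count_matrix()].
#' @param path Output TSV for the counts.
#' @param samples_path Optional output TSV for the sample metadata.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, samples_path = NULL) {
  bed <- bed0_from_gr(cm$fragments)
  tab <- cbind(bed, as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a per-fragment significance table
#'
#' One row per fragment with BED coordinates and per-replicate p/q columns
#' (`p_rep1`, `q_rep1`, `p_rep2`, `q_rep2`, ...), the shape in which
#' fragment-level interaction callers report their output.
#'
#' @param path TSV with a header.
#' @return A `data.frame`, sorted by coordinate, with an attached `GRanges`
#'   in attribute `"granges"`.
#' @export
read_significance_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(tab)))
    stop("significance table needs chrom/start/end columns", call. = FALSE)
  qcols <- grep("^q_", names(tab), value = TRUE)
  if (!length(qcols)) stop("no q_* columns found", call. = FALSE)
  for (qc in qcols) {
    if (any(tab[[qc]] < 0 | tab[[qc]] > 1, na.rm = TRUE))
      stop(sprintf("%s outside [0, 1]", qc), call. = FALSE)
  }
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "granges") <- gr_from_bed0(tab$chrom, tab$start, tab$end)
  tab
}

#' Write a significance table as TSV
#'
#' @param tab Significance `data.frame` (see [read_significance_table()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_significance_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
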