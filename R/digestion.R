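# In-silico restriction digestion. DpnII cuts at ^GATC (blunt, cut offset 0),
# so every fragment after the first begins with the recognition site; the
# fragment grid produced here is the coordinate system for all count tracks.

#' Recognition motif for in-silico digestion
#'
#' @param sequence Uppercase DNA motif, default `"GATC"` (DpnII).
#' @param cut_offset Cut position in bp from the motif start; 0 for a
#'   blunt 5' cutter like DpnII.
#' @return An object of class `recognition_motif`.
#' @export
recognition_motif <- function(sequence = "GATC", cut_offset = 0L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence))
    stop("motif must be non-empty and contain only A, C, G, T", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(sequence))
    stop("cut_offset must lie within the motif", call. = FALSE)
  structure(list(sequence = sequence, cut_offset = cut_offset),
            class = "recognition_motif")
}

#' Digest one sequence into restriction fragments
#'
#' Fragments tile `[0, nchar(seq))` exactly; each internal boundary is a
#' motif occurrence start plus the cut offset. Matching is case-insensitive
#' (soft-masked lowercase matches); `N` never matches; overlapping motif
#' occurrences each contribute a cut. Zero-width fragments from cuts at the
#' sequence ends are dropped.
#'
#' @param seq DNA sequence: a character string or [Biostrings::DNAString].
#' @param chrom Chromosome name for the output intervals.
#' @param motif A [recognition_motif()] (or motif string).
#' @return A `GRanges` of fragments tiling the sequence.
#' @examples
#' digest_sequence("AAAAAGATCAAAGATCAAAA", "chrS")
#' @export
digest_sequence <- function(seq, chrom = "chr1", motif = recognition_motif()) {
  if (is.character(motif)) motif <- recognition_motif(motif)
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("seq must be one non-empty sequence", call. = FALSE)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside ACGTN", call. = FALSE)
  len <- nchar(seq)
  # fixed = TRUE: exact matching, N in the subject never matches
  hits <- Biostrings::matchPattern(motif$sequence, Biostrings::DNAString(seq),
                                   fixed = TRUE)
  cuts0 <- Biostrings::start(hits) - 1L + motif$cut_offset
  bounds <- sort(unique(c(0, cuts0[cuts0 > 0 & cuts0 < len], len)))
  gr_from_bed0(chrom, bounds[-length(bounds)], bounds[-1L])
}

#' Digest every sequence of a FASTA file
#'
#' @param path FASTA file (one or more sequences; names become chromosomes).
#' @param motif A [recognition_motif()] (or motif string).
#' @return A `GRanges` of fragments over all sequences.
#' @export
digest_fasta <- function(path, motif = recognition_motif()) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA", call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i)
    bed0_from_gr(digest_sequence(as.character(seqs[[i]]), nm[i], motif)))
  bed <- do.call(rbind, out)
  gr_from_bed0(bed$chrom, bed$start, bed$end)
}
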