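# Post-capture bookkeeping of fragment-level interaction significance:
# replicate q-value merging, replicated-interaction selection, curation of
# locally most significant fragments, and shared/specific classification.

#' Merge replicate q-values
#'
#' Two replicates are merged as `sqrt(q1 * q2)`, the geometric mean — on the
#' `-log10` scale this is the plain mean of the replicate scores. More than
#' two replicates generalize to `prod(q)^(1/n)`.
#'
#' @param q1 Numeric vector of q-values in `[0, 1]`, or a matrix with one
#'   column per replicate (then `q2` must be absent).
#' @param q2 Second replicate's q-values, same length as `q1`.
#' @return Merged q-values, bounded by `[min(q), max(q)]` componentwise.
#' @examples
#' merge_q(0.04, 0.09) # 0.06
#' @export
merge_q <- function(q1, q2 = NULL) {
  q <- if (is.null(q2)) as.matrix(q1) else cbind(as.numeric(q1), as.numeric(q2))
  if (any(q < 0 | q > 1, na.rm = TRUE))
    stop("q-values must lie in [0, 1]", call. = FALSE)
  # exp(mean(log(q))): log(0) = -Inf gives 0, as the product does
  out <- exp(rowMeans(log(q)))
  out[apply(q == 0, 1L, any)] <- 0
  unname(out)
}

#' Replicated significant interactions per cell type
#'
#' A fragment enters a cell type's interaction set iff its q-value is below
#' `q_threshold` in *both* (all) replicates of that cell type; the global
#' replicated set is the union over cell types.
#'
#' @param tables Named list (one element per cell type) of significance
#'   `data.frame`s with `chrom`, `start`, `end` and `q_rep*` columns (see
#'   [read_significance_table()]).
#' @param q_threshold Replication threshold, default 0.1.
#' @return An object of class `interaction_sets`: a named list of `GRanges`
#'   (one per cell type) plus attribute `all` with the union.
#' @export
replicated_significant <- function(tables, q_threshold = 0.1) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)", call. = FALSE)
  sets <- lapply(names(tables), function(ct) {
    tab <- tables[[ct]]
    qcols <- grep("^q_", names(tab), value = TRUE)
    if (length(qcols) < 2L)
      stop(sprintf("cell type '%s' has fewer than 2 replicates", ct),
           call. = FALSE)
    keep <- rowSums(as.matrix(tab[, qcols, drop = FALSE]) < q_threshold) ==
      length(qcols)
    gr_from_bed0(tab$chrom, tab$start, tab$end)[keep]
  })
  names(sets) <- names(tables)
  all_keys <- unique(unlist(lapply(sets, gr_keys)))
  structure(sets, class = "interaction_sets", all_keys = all_keys)
}

#' Curate locally most significant fragments
#'
#' Operationalizes "highest local statistical significance" as strict local
#' maxima of the merged `-log10(q)` profile: a fragment is curated when its
#' score is greater than every neighbour within `window` fragments on each
#' side and its merged q is below `q_threshold`. A tie between equal
#' neighbouring scores is resolved toward the leftmost fragment.
#'
#' @param tab Significance `data.frame` with `chrom`, `start`, `end` and
#'   either a `merged_q` column or `q_rep*` columns to merge.
#' @param window Neighbourhood half-width in fragments, default 2.
#' @param q_threshold Curation threshold on merged q, default 0.05.
#' @return The curated subset of `tab` (with `merged_q` filled in), sorted
#'   by coordinate.
#' @export
curate_local_peaks <- function(tab, window = 2, q_threshold = 0.05) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1", call. = FALSE)
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)", call. = FALSE)
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  if (is.null(tab$merged_q)) {
    qcols <- grep("^q_", names(tab), value = TRUE)
    if (!length(qcols)) stop("need merged_q or q_rep* columns", call. = FALSE)
    tab$merged_q <- merge_q(as.matrix(tab[, qcols, drop = FALSE]))
  }
  score <- -log10(tab$merged_q)
  n <- nrow(tab)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!(tab$merged_q[i] < q_threshold)) next
    left <- if (i > 1L) score[max(1L, i - window):(i - 1L)] else numeric(0)
    right <- if (i < n) score[(i + 1L):min(n, i + window)] else numeric(0)
    # leftmost wins ties: strictly above left neighbours, >= right neighbours
    keep[i] <- all(score[i] > left) && all(score[i] >= right)
  }
  rownames(tab) <- NULL
  tab[keep, , drop = FALSE]
}

#' Venn partition of interaction sets
#'
#' Counts every region of the Venn partition over the labelled sets:
#' shared-by-all, each exclusive pairwise overlap, label-specific, etc.
#'
#' @param sets An `interaction_sets` object from [replicated_significant()],
#'   or a named list of `GRanges` / character key vectors.
#' @return `data.frame` with columns `labels` (e.g. `"A&B"`), `count`, and
#'   attribute `total` (= size of the union). Counts sum to the union size.
#' @export
classify_sets <- function(sets) {
  if (inherits(sets, "interaction_sets")) sets <- unclass(sets)
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  keys <- lapply(sets, function(s)
    if (inherits(s, "GRanges")) gr_keys(s) else as.character(s))
  universe <- unique(unlist(keys))
  labs <- names(sets)
  membership <- vapply(keys, function(k) universe %in% k,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(m) paste(labs[m], collapse = "&"))
  # enumerate all non-empty label combinations so zero regions are reported
  combos <- unlist(lapply(seq_along(labs), function(k)
    utils::combn(labs, k, paste, collapse = "&")))
  counts <- vapply(combos, function(cb) sum(pattern == cb), 0L)
  out <- data.frame(labels = combos, count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- length(universe)
  out
}
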