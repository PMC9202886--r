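# Synthetic Capture-C data with known ground truth. Counts decay with
# distance from the viewpoint following a power law and are overdispersed
# (negative binomial), which is what distance-normalising interaction
# callers have to contend with in real libraries; injected effects are a
# multiplicative fold over a genomic region in one condition (a remodelled
# domain) and/or a per-flank amplitude multiplier (near-viewpoint
# asymmetry).

#' Distance-decay count model
#'
#' Expected count of a fragment at distance `d` from the viewpoint midpoint
#' is `amplitude * (1 + d / half_distance)^(-exponent)`; counts are drawn
#' negative-binomially with the given size (dispersion) parameter.
#'
#' @param amplitude Expected count at distance 0; default 300, a deep
#'   capture library's scale at the viewpoint-adjacent fragments.
#' @param half_distance Distance scale in bp; default 4000.
#' @param exponent Power-law decay exponent; default 1.3.
#' @param dispersion Negative-binomial size; default 5 (overdispersed —
#'   variance `mu + mu^2 / 5`).
#' @return An object of class `decay_model`.
#' @export
decay_model <- function(amplitude = 300, half_distance = 4000,
                        exponent = 1.3, dispersion = 5) {
  stopifnot(amplitude > 0, half_distance > 0, exponent > 0, dispersion > 0)
  structure(list(amplitude = amplitude, half_distance = half_distance,
                 exponent = exponent, dispersion = dispersion),
            class = "decay_model")
}

#' Injected differential effect
#'
#' @param region Optional `GRanges`; fragments overlapping it get their mean
#'   multiplied by `fold`.
#' @param fold Multiplicative factor on the mean inside `region`; default 1.
#' @param flank `"none"`, `"upstream"` or `"downstream"`: flank whose
#'   amplitude is scaled by `flank_scale` (asymmetry injection).
#' @param flank_scale Multiplier on the designated flank's mean; default 1.
#' @return An object of class `injected_effect`.
#' @export
injected_effect <- function(region = NULL, fold = 1,
                            flank = c("none", "upstream", "downstream"),
                            flank_scale = 1) {
  flank <- match.arg(flank)
  stopifnot(fold > 0, flank_scale > 0)
  structure(list(region = region, fold = fold, flank = flank,
                 flank_scale = flank_scale),
            class = "injected_effect")
}

# fragment distance to the viewpoint midpoint: 0 when the fragment contains
# the midpoint, else bp from the near edge (simulator convention)
fragment_distance <- function(fragments, vp) {
  s0 <- GenomicRanges::start(fragments) - 1
  e0 <- as.numeric(GenomicRanges::end(fragments))
  m <- vp$midpoint
  ifelse(m < s0, s0 - m, ifelse(m >= e0, m - e0 + 1, 0))
}

expected_counts <- function(fragments, vp, model, effects = list(),
                            depth_factor = 1) {
  d <- fragment_distance(fragments, vp)
  mu <- depth_factor * model$amplitude *
    (1 + d / model$half_distance)^(-model$exponent)
  s0 <- GenomicRanges::start(fragments) - 1
  e0 <- as.numeric(GenomicRanges::end(fragments))
  for (ef in effects) {
    if (!is.null(ef$region) && ef$fold != 1) {
      idx <- IRanges::countOverlaps(fragments, ef$region) > 0L
      mu[idx] <- mu[idx] * ef$fold
    }
    if (ef$flank != "none" && ef$flank_scale != 1) {
      idx <- if (ef$flank == "upstream") e0 <= vp$midpoint else s0 > vp$midpoint
      mu[idx] <- mu[idx] * ef$flank_scale
    }
  }
  mu
}

#' Simulate one sample's fragment count track
#'
#' @param fragments `GRanges` fragment grid (e.g. from [digest_sequence()]).
#' @param vp A [viewpoint()].
#' @param model A [decay_model()].
#' @param effects List of [injected_effect()]s active in this sample.
#' @param depth_factor Library-depth multiplier on all means.
#' @param seed Integer seed; required (tracks must be reproducible).
#' @param sample_id,condition,replicate Metadata for the track.
#' @return A [fragment_track()].
#' @export
simulate_track <- function(fragments, vp, model = decay_model(),
                           effects = list(), depth_factor = 1, seed,
                           sample_id = "sim", condition = NA, replicate = NA) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (inherits(effects, "injected_effect")) effects <- list(effects)
  mu <- expected_counts(fragments, vp, model, effects, depth_factor)
  set.seed(as.integer(seed))
  counts <- stats::rnbinom(length(mu), size = model$dispersion, mu = mu)
  fragment_track(fragments, counts, sample_id, condition, replicate)
}

#' Simulate a replicated two-condition experiment
#'
#' One negative-binomial track per sample; per-sample depth factors are
#' drawn from `depth_range` (default U(0.5, 2)) so that size-factor
#' normalization is genuinely exercised.
#'
#' @param fragments `GRanges` fragment grid.
#' @param vp A [viewpoint()].
#' @param conditions Condition labels; default `c("neuron", "esc")`.
#' @param n_replicates Replicates per condition; default 2.
#' @param model A single [decay_model()] shared by all conditions, or a
#'   named list with one model per condition.
#' @param effects Named list keyed by condition; each element a list of
#'   [injected_effect()]s applied to that condition's samples only.
#' @param depth_range Range for the uniform per-sample depth factors.
#' @param seed Master seed; per-sample seeds and depths derive from it.
#' @param seeds Optional explicit per-sample seeds (duplicates draw a
#'   warning).
#' @return A [count_matrix()] with attribute `"depth_factors"`.
#' @export
simulate_experiment <- function(fragments, vp,
                                conditions = c("neuron", "esc"),
                                n_replicates = 2, model = decay_model(),
                                effects = list(), depth_range = c(0.5, 2),
                                seed, seeds = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  samples <- expand.grid(replicate = paste0("rep", seq_len(n_replicates)),
                         condition = conditions, stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate")]
  samples$sample_id <- paste(samples$condition, samples$replicate, sep = "_")
  m <- nrow(samples)
  set.seed(as.integer(seed))
  depths <- stats::runif(m, depth_range[1L], depth_range[2L])
  if (is.null(seeds)) seeds <- sample.int(.Machine$integer.max - 1L, m)
  if (anyDuplicated(seeds))
    warning("duplicate per-sample seeds: samples will be correlated")
  tracks <- lapply(seq_len(m), function(j) {
    cond <- samples$condition[j]
    mdl <- if (inherits(model, "decay_model")) model else model[[cond]]
    simulate_track(fragments, vp, mdl, effects[[cond]] %||% list(),
                   depths[j], seeds[j], samples$sample_id[j], cond,
                   samples$replicate[j])
  })
  cm <- bind_tracks(tracks)
  attr(cm, "depth_factors") <- stats::setNames(depths, samples$sample_id)
  cm
}

#' Simulate fragment-level significance tables
#'
#' Emulates the output of an upstream fragment-level interaction caller:
#' fragments inside designated true-interaction regions draw
#' `q ~ U(0, 0.05)` in every replicate, background fragments draw
#' `q ~ U(0.2, 1)`; `p` is drawn in `[0, q]`. Background fragments can
#' therefore never pass a replication threshold of 0.1, and true fragments
#' always do.
#'
#' @param fragments `GRanges` fragment grid.
#' @param true_regions `GRanges` of true interaction regions (may differ per
#'   cell type: pass a named list).
#' @param cell_types Cell-type labels; default `c("neuron", "esc")`.
#' @param n_replicates Replicates per cell type; default 2.
#' @param seed Integer seed; required.
#' @return Named list of significance `data.frame`s, one per cell type.
#' @export
simulate_significance <- function(fragments, true_regions,
                                  cell_types = c("neuron", "esc"),
                                  n_replicates = 2, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  bed <- bed0_from_gr(fragments)
  n <- length(fragments)
  out <- lapply(cell_types, function(ct) {
    regions <- if (is.list(true_regions) && !inherits(true_regions, "GRanges"))
      true_regions[[ct]] else true_regions
    is_true <- if (is.null(regions) || !length(regions)) rep(FALSE, n)
               else IRanges::countOverlaps(fragments, regions) > 0L
    tab <- bed
    for (r in seq_len(n_replicates)) {
      q <- ifelse(is_true, stats::runif(n, 0, 0.05), stats::runif(n, 0.2, 1))
      tab[[paste0("p_rep", r)]] <- q * stats::runif(n)
      tab[[paste0("q_rep", r)]] <- q
    }
    tab
  })
  names(out) <- cell_types
  out
}
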