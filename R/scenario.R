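# The shipped simulation scenario: a 1 Mb synthetic chromosome digested
# in silico at GATC, a viewpoint at its centre, a 2x2 replicated design,
# and one 100 kb remodelled domain starting 350 kb downstream of the
# viewpoint with a 5-fold contact gain in one condition. The flat key=value
# file inst/extdata/default_scenario.cfg holds the same values for the
# command-line interface.

#' Default simulation scenario
#'
#' The study conditions exercised by the shipped end-to-end analysis:
#' +/-500 kb ROI on a synthetic chromosome whose base composition
#' (A=T=0.425, G=C=0.075) yields GATC roughly every kilobase, hence ~1000
#' restriction fragments across the ROI; 2 conditions x 2 replicates; a
#' fold-5 interaction domain spanning 100 kb, starting 350 kb downstream of
#' the viewpoint, present in the `neuron` condition only.
#'
#' @param ... Named overrides of individual scenario fields.
#' @return A named list of class `cc_scenario`.
#' @export
default_scenario <- function(...) {
  sc <- list(
    chrom = "chrS",
    seq_length = 1000000,
    base_prob = c(A = 0.425, C = 0.075, G = 0.075, T = 0.425),
    motif = "GATC",
    viewpoint_name = "VP",
    viewpoint_pos = 500000,
    roi_radius = 500000,
    conditions = c("neuron", "esc"),
    n_replicates = 2,
    amplitude = 300,
    half_distance = 4000,
    exponent = 1.3,
    dispersion = 5,
    depth_min = 0.5,
    depth_max = 2,
    domain_offset = 350000,
    domain_width = 100000,
    domain_fold = 5,
    domain_condition = "neuron",
    flank = "none",
    flank_scale = 1,
    flank_condition = "neuron",
    fine_bin = 1000,
    rebin_factor = 10,
    exclusion_radius = 50000,
    n_pairs = 50,
    n_perm_meso = 1000,
    n_perm_asym = 10000,
    seed = 20260929
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(sc))
  if (length(bad))
    stop(sprintf("unknown scenario key(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(names(sc), collapse = ", ")), call. = FALSE)
  sc[names(dots)] <- dots
  validate_scenario(sc)
}

#' Null variant of the default scenario
#'
#' Identical conditions in both cell types: no injected domain, no flank
#' asymmetry. Used for calibration of the permutation tests.
#'
#' @param ... Overrides passed on to [default_scenario()].
#' @return A `cc_scenario`.
#' @export
null_scenario <- function(...) {
  default_scenario(domain_fold = 1, flank_scale = 1, flank = "none", ...)
}

validate_scenario <- function(sc) {
  stopifnot(sc$seq_length > 0, sc$roi_radius > 0, sc$n_replicates >= 1,
            sc$domain_fold > 0, sc$flank_scale > 0,
            sc$fine_bin >= 1, sc$rebin_factor >= 1, sc$n_pairs >= 1)
  if (sc$exclusion_radius > sc$roi_radius)
    stop("exclusion_radius must not exceed roi_radius", call. = FALSE)
  if (!sc$domain_condition %in% sc$conditions ||
      !sc$flank_condition %in% sc$conditions)
    stop("effect conditions must be among the scenario conditions", call. = FALSE)
  structure(sc, class = "cc_scenario")
}

#' Read a scenario from a flat key=value file
#'
#' Unknown keys are rejected with the list of valid keys. `base_prob` is
#' given as four keys `base_prob_a` .. `base_prob_t`; `conditions` as a
#' comma-separated list.
#'
#' @param path Config file with one `key=value` per line; `#` comments
#'   allowed.
#' @return A `cc_scenario`.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(vapply(kv, length, 0L) != 2L))
    stop("scenario file must contain one key=value per line", call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  sc <- as.list(stats::setNames(vals, keys))
  pk <- c("base_prob_a", "base_prob_c", "base_prob_g", "base_prob_t")
  if (all(pk %in% keys)) {
    sc$base_prob <- stats::setNames(as.numeric(sc[pk]), c("A", "C", "G", "T"))
    sc[pk] <- NULL
  }
  if (!is.null(sc$conditions))
    sc$conditions <- trimws(strsplit(sc$conditions, ",")[[1L]])
  num_keys <- c("seq_length", "viewpoint_pos", "roi_radius", "n_replicates",
                "amplitude", "half_distance", "exponent", "dispersion",
                "depth_min", "depth_max", "domain_offset", "domain_width",
                "domain_fold", "flank_scale", "fine_bin", "rebin_factor",
                "exclusion_radius", "n_pairs", "n_perm_meso", "n_perm_asym",
                "seed")
  for (k in intersect(num_keys, names(sc))) sc[[k]] <- as.numeric(sc[[k]])
  do.call(default_scenario, sc)
}

#' Generate the synthetic chromosome, fragment grid and viewpoint
#'
#' @param sc A `cc_scenario`.
#' @param seed Seed for the sequence draw; default the scenario's.
#' @return List with `sequence` (character), `fragments` (`GRanges`) and
#'   `vp` (the [viewpoint()] at the fragment containing `viewpoint_pos`).
#' @export
scenario_genome <- function(sc = default_scenario(), seed = sc$seed) {
  set.seed(as.integer(seed))
  seq <- paste(sample(names(sc$base_prob), sc$seq_length, replace = TRUE,
                      prob = sc$base_prob), collapse = "")
  fragments <- digest_sequence(seq, sc$chrom, recognition_motif(sc$motif))
  s0 <- GenomicRanges::start(fragments) - 1
  e0 <- GenomicRanges::end(fragments)
  hit <- which(s0 <= sc$viewpoint_pos & sc$viewpoint_pos < e0)
  vp <- viewpoint(sc$viewpoint_name, sc$chrom, s0[hit], e0[hit])
  list(sequence = seq, fragments = fragments, vp = vp)
}

scenario_effects <- function(sc, vp) {
  eff <- stats::setNames(vector("list", length(sc$conditions)), sc$conditions)
  for (cc in sc$conditions) eff[[cc]] <- list()
  if (sc$domain_fold != 1) {
    dom <- gr_from_bed0(sc$chrom, vp$midpoint + sc$domain_offset,
                        vp$midpoint + sc$domain_offset + sc$domain_width)
    eff[[sc$domain_condition]] <-
      c(eff[[sc$domain_condition]], list(injected_effect(dom, sc$domain_fold)))
  }
  if (sc$flank != "none" && sc$flank_scale != 1) {
    eff[[sc$flank_condition]] <-
      c(eff[[sc$flank_condition]],
        list(injected_effect(flank = sc$flank, flank_scale = sc$flank_scale)))
  }
  eff
}

#' Simulate a full experiment from a scenario
#'
#' Draws the synthetic chromosome, digests it, and simulates one count
#' column per sample under the scenario's decay model and injected effects.
#'
#' @param sc A `cc_scenario`.
#' @param seed Master seed; default the scenario's own.
#' @param genome Optional pre-built [scenario_genome()] result, so repeated
#'   simulations can share one fragment grid.
#' @return List with `counts` ([count_matrix()]), `fragments`, `vp`,
#'   `truth` (injected-effect description) and `scenario`.
#' @export
simulate_scenario <- function(sc = default_scenario(), seed = sc$seed,
                              genome = NULL) {
  seed <- as.integer(seed)
  if (is.null(genome)) genome <- scenario_genome(sc, seed)
  eff <- scenario_effects(sc, genome$vp)
  model <- decay_model(sc$amplitude, sc$half_distance, sc$exponent,
                       sc$dispersion)
  # counts seeded distinctly from the genome draw
  cm <- simulate_experiment(genome$fragments, genome$vp, sc$conditions,
                            sc$n_replicates, model, eff,
                            c(sc$depth_min, sc$depth_max),
                            seed = (seed + 1L) %% .Machine$integer.max)
  truth <- list(
    domain = if (sc$domain_fold != 1)
      gr_from_bed0(sc$chrom, genome$vp$midpoint + sc$domain_offset,
                   genome$vp$midpoint + sc$domain_offset + sc$domain_width)
      else NULL,
    domain_fold = sc$domain_fold, domain_condition = sc$domain_condition,
    flank = sc$flank, flank_scale = sc$flank_scale,
    flank_condition = sc$flank_condition)
  list(counts = cm, fragments = genome$fragments, vp = genome$vp,
       truth = truth, scenario = sc)
}
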