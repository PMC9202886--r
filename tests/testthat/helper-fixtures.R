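# Shared fixture builders. Everything is generated in code; no data files.

# GRanges from BED-style coordinates
gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0))
}

# GRanges carrying a delta column, from BED-style coordinates
delta_gr <- function(chrom, start0, end0, delta) {
  gr <- gr0(chrom, start0, end0)
  GenomicRanges::mcols(gr)$delta <- delta
  gr
}

# contiguous fragment grid of given widths starting at 0
frag_grid <- function(widths, chrom = "chrT") {
  ends <- cumsum(widths)
  gr0(chrom, c(0, ends[-length(ends)]), ends)
}

# mirror_pairs object straight from up/down values
mk_pairs <- function(up, down) {
  structure(list(up = up, down = down, diffs = up - down,
                 n_pairs = length(up), viewpoint_bin = NA_integer_),
            class = "mirror_pairs")
}

# random 4-sample count matrix on a small grid
random_cm <- function(n = 50, seed = 1) {
  set.seed(seed)
  counts <- matrix(rnbinom(n * 4, size = 5, mu = 20) + 1, n, 4)
  count_matrix(frag_grid(rep(100, n)), counts,
               data.frame(sample_id = paste0("s", 1:4),
                          condition = rep(c("a", "b"), each = 2),
                          replicate = rep(c("r1", "r2"), 2)))
}

# independent brute-force oracle for the sign-flip test (n small)
brute_force_signflip_p <- function(x, alternative = "two.sided") {
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(x))))
  tp <- as.vector(signs %*% x)
  t_obs <- sum(x)
  tol <- 1e-9 * max(1, abs(t_obs))
  mean(switch(alternative,
              two.sided = abs(tp) >= abs(t_obs) - tol,
              greater = tp >= t_obs - tol,
              less = tp <= t_obs + tol))
}

# independent oracle for the toy meso-scale placement problem: exhaustive
# enumeration of the positions of the nonzero values among the fine bins
enumerate_placement_p <- function(values, rebin_factor) {
  nz <- values[values != 0]
  n <- length(values)
  observed <- local({
    g <- ceiling(seq_len(n) / rebin_factor)
    cv <- as.vector(tapply(values, g, sum))
    runs_max(cv)
  })
  slots <- utils::combn(n, length(nz))
  stats <- apply(slots, 2L, function(pos) {
    v <- numeric(n)
    v[pos] <- nz
    g <- ceiling(seq_len(n) / rebin_factor)
    runs_max(as.vector(tapply(v, g, sum)))
  })
  mean(stats >= observed)
}

# plain-loop constant-sign run maximum (kept independent of the package)
runs_max <- function(v) {
  best <- 0; cur <- 0; cur_sign <- 0
  for (x in v) {
    s <- sign(x)
    if (s == 0) { cur <- 0; cur_sign <- 0; next }
    if (s == cur_sign) cur <- cur + abs(x) else { cur <- abs(x); cur_sign <- s }
    best <- max(best, cur)
  }
  best
}
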