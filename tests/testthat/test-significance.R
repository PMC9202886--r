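test_that("q-value merging is the geometric mean with its boundary cases", {
  expect_equal(merge_q(0.01, 0.01), 0.01)
  expect_equal(merge_q(0.04, 0.09), 0.06)
  expect_equal(merge_q(0, 0.5), 0)
  expect_error(merge_q(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(merge_q(0.5, 1.2), "\\[0, 1\\]")

  set.seed(1)
  q1 <- runif(50); q2 <- runif(50)
  m <- merge_q(q1, q2)
  expect_equal(m, merge_q(q2, q1))                      # symmetric
  expect_true(all(m >= pmin(q1, q2) & m <= pmax(q1, q2)))  # bounded
  m_up <- merge_q(pmin(q1 * 1.5, 1), q2)                # monotone
  expect_true(all(m_up >= m))
  # >2 replicates: geometric mean
  expect_equal(merge_q(cbind(0.1, 0.1, 0.1)), 0.1)
  expect_equal(merge_q(cbind(1e-4, 1e-2, 1)), 1e-2)
})

test_that("replicated selection requires significance in all replicates of a cell type", {
  tab <- function(q1, q2) data.frame(
    chrom = "c", start = seq(0, by = 100, length.out = length(q1)),
    end = seq(100, by = 100, length.out = length(q1)),
    q_rep1 = q1, q_rep2 = q2)
  tabs <- list(A = tab(c(0.05, 0.05, 0.5), c(0.2, 0.09, 0.5)),
               B = tab(c(0.5, 0.01, 0.5), c(0.5, 0.02, 0.5)))
  sets <- replicated_significant(tabs, q_threshold = 0.1)
  expect_length(sets$A, 1L)  # (0.05, 0.2) excluded, (0.05, 0.09) included
  expect_equal(GenomicRanges::start(sets$A) - 1L, 100)
  expect_length(sets$B, 1L)
  # fragment 2 replicated in both cell types -> one entry in the union
  expect_length(attr(sets, "all_keys"), 1L)

  only_a <- replicated_significant(list(A = tab(0.01, 0.02), B = tab(0.5, 0.5)))
  expect_length(only_a$A, 1L)
  expect_length(only_a$B, 0L)
  expect_length(attr(only_a, "all_keys"), 1L)

  expect_error(
    replicated_significant(list(A = data.frame(chrom = "c", start = 0, end = 1,
                                               q_rep1 = 0.1))),
    "fewer than 2")
})

test_that("curation keeps strict local maxima of -log10 merged q above threshold", {
  tab <- data.frame(chrom = "c", start = seq(0, 500, 100),
                    end = seq(100, 600, 100),
                    merged_q = 10^-c(1, 3, 2, 0.5, 5, 4))
  cur <- curate_local_peaks(tab, window = 1, q_threshold = 0.05)
  expect_equal(cur$start, c(100, 400))  # scores 3 and 5

  mono <- data.frame(chrom = "c", start = seq(0, 400, 100),
                     end = seq(100, 500, 100), merged_q = 10^-(1:5))
  expect_equal(curate_local_peaks(mono, window = 2)$start, 400)

  flat <- data.frame(chrom = "c", start = c(0, 100), end = c(100, 200),
                     merged_q = c(1, 1))
  expect_equal(nrow(curate_local_peaks(flat)), 0L)

  # ties resolve to the leftmost fragment
  tie <- data.frame(chrom = "c", start = seq(0, 200, 100),
                    end = seq(100, 300, 100), merged_q = c(0.01, 0.01, 0.5))
  expect_equal(curate_local_peaks(tie, window = 1)$start, 0)

  expect_error(curate_local_peaks(tab, window = 0), ">= 1")

  # merged_q computed from q_rep columns when absent; curated subset is
  # significant and mutually separated by more than the window
  set.seed(6)
  n <- 60
  big <- data.frame(chrom = "c", start = seq(0, by = 100, length.out = n),
                    end = seq(100, by = 100, length.out = n),
                    q_rep1 = runif(n, 0, 0.3), q_rep2 = runif(n, 0, 0.3))
  cur <- curate_local_peaks(big, window = 2, q_threshold = 0.05)
  expect_true(all(cur$merged_q < 0.05))
  if (nrow(cur) > 1L)
    expect_true(all(diff(cur$start) / 100 > 2))
})

test_that("set classification partitions the union and counts every region", {
  sets <- list(A = c("f1", "f2"), B = c("f2"), C = character(0))
  out <- classify_sets(sets)
  get <- function(lab) out$count[out$labels == lab]
  expect_equal(get("A"), 1L)       # f1 A-specific
  expect_equal(get("A&B"), 1L)     # f2
  expect_equal(get("B"), 0L)
  expect_equal(get("C"), 0L)
  expect_equal(get("A&B&C"), 0L)
  expect_equal(sum(out$count), attr(out, "total"))

  same <- list(X = c("a", "b"), Y = c("a", "b"), Z = c("a", "b"))
  out2 <- classify_sets(same)
  expect_equal(out2$count[out2$labels == "X&Y&Z"], 2L)
  expect_equal(sum(out2$count), 2L)

  disj <- list(X = "a", Y = "b")
  out3 <- classify_sets(disj)
  expect_equal(out3$count[out3$labels %in% c("X", "Y")], c(1L, 1L))
  expect_equal(out3$count[out3$labels == "X&Y"], 0L)

  grs <- list(A = gr0("c", c(0, 100), c(100, 200)), B = gr0("c", 100, 200))
  out4 <- classify_sets(grs)
  expect_equal(sum(out4$count), 2L)
  expect_equal(out4$count[out4$labels == "A&B"], 1L)
})
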