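test_that("CpG classification uses any-overlap and the states use strict >1", {
  prom <- toy_intervals(c(0L, 5000L, 9000L), c(1000L, 6000L, 10000L))
  islands <- toy_intervals(c(999L, 7000L), c(1200L, 7100L))
  expect_equal(classify_cpg(prom, islands), c("HCG", "LCG", "LCG"))
  expect_equal(classify_cpg(prom, islands[0, ]), rep("LCG", 3))
  # island containing the promoter
  expect_equal(classify_cpg(toy_intervals(100L, 200L),
                            toy_intervals(0L, 500L)), "HCG")

  expect_equal(promoter_state(c(2.5, 1.0, 1.2, 0.2), c(0.3, 1.0, 3.0, 9.0)),
               c("K4", "None", "K4K27", "K27"))
  expect_error(promoter_state(-1, 0), "non-negative")
})

test_that("promoter state is monotone in each mark", {
  set.seed(3)
  for (i in 1:50) {
    k4 <- runif(1, 0, 3); k27 <- runif(1, 0, 3)
    s0 <- promoter_state(k4, k27)
    s1 <- promoter_state(k4 + runif(1, 0, 3), k27)
    # raising K4 never removes the K4 component
    expect_true(!grepl("K4", s0) || grepl("K4", s1))
  }
})

test_that("promoter RPKM counts tags in the 1-kb interval", {
  prom <- data.frame(gene_id = "g1", chrom = "chr1", start = 4500L,
                     end = 5500L)
  tags <- toy_tags(c(rep(5000L, 20L), rep(40000L, 80L)))
  # 20 tags / 1 kb / (100 tags / 1e6) = 2e5
  expect_equal(promoter_rpkm(tags, prom), 2e5)
})

test_that("state transition fractions are per CpG class and sum to 1", {
  rec <- data.frame(
    gene_id = sprintf("g%d", 1:8),
    cpg_class = c(rep("HCG", 6), "LCG", "LCG"),
    state_MEF = c(rep("K4K27", 4), "K4", "K4", "K27", "K27"),
    state_iPSC = c("K4", "K4", "K4", "K27", "K4", "K4", "K27", "None"),
    stringsAsFactors = FALSE)
  tr <- suppressMessages(state_transitions(rec, "MEF", "iPSC"))
  expect_equal(unname(tr$HCG["K4K27", "K4"]), 0.75)
  expect_equal(unname(tr$HCG["K4K27", "K27"]), 0.25)
  expect_true(all(abs(rowSums(tr$HCG) - 1) < 1e-12))
  expect_false("K4K27" %in% rownames(tr$LCG))  # empty rows omitted
  expect_error(state_transitions(rec, "MEF", "missing"), "missing")
})

test_that("expression splits by state change and detects planted shifts", {
  set.seed(21)
  n <- 100
  rec <- data.frame(
    gene_id = sprintf("g%03d", 1:(2 * n)),
    cpg_class = "HCG",
    state_MEF = "K4K27",
    state_iPSC = rep(c("K4", "K27"), each = n),
    stringsAsFactors = FALSE)
  fpkm <- setNames(c(rlnorm(n, log(40), 0.4), rlnorm(n, log(5), 0.4)),
                   rec$gene_id)
  res <- expression_by_state_change(rec, fpkm, "K4K27", "MEF", "iPSC")
  expect_setequal(names(res$groups), c("K4", "K27"))
  expect_lt(res$tests$p_value, 0.01)
  expect_gt(res$tests$t * ifelse(res$tests$group_a == "K4", 1, -1), 0)

  # identical (non-degenerate) distributions give t = 0
  v <- rlnorm(n, 2, 0.5)
  fpkm2 <- setNames(c(v, v), rec$gene_id)
  res2 <- expression_by_state_change(rec, fpkm2, "K4K27", "MEF", "iPSC")
  expect_equal(res2$tests$t, 0)
  # single-group case: no tests
  rec3 <- rec; rec3$state_iPSC <- "K4"
  res3 <- expression_by_state_change(rec3, fpkm, "K4K27", "MEF", "iPSC")
  expect_equal(nrow(res3$tests), 0)
})

test_that("promoter records recover planted states from tag RPKM", {
  genes <- toy_genes(c(10000L, 30000L, 50000L, 70000L), chrom = "chr1")
  cpg <- toy_intervals(9800L, 10200L)
  mk <- function(tss_set) {
    pos <- unlist(lapply(tss_set, function(t)
      rep(seq(t - 400L, t + 400L, by = 40L), 3)))   # 63 tags per promoter
    filler <- seq(1000L, 99000L, by = 5000L)        # 0.2 RPKM background
    toy_tags(c(pos, filler))
  }
  # library size fixed at 1e6 so planted promoters sit at ~63 RPKM and
  # background at ~0.2 RPKM, well clear of the 1-RPKM threshold
  k4 <- list(MEF = mk(c(10000L, 30000L)))
  k27 <- list(MEF = mk(c(30000L, 50000L)))
  rec <- promoter_records(genes, cpg, k4, k27,
                          k4_totals = c(MEF = 1e6),
                          k27_totals = c(MEF = 1e6))
  expect_equal(rec$cpg_class, c("HCG", "LCG", "LCG", "LCG"))
  expect_equal(rec$state_MEF, c("K4", "K4K27", "K27", "None"))
})
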