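genome <- toy_genome(chr1 = 30000L, chr2 = 25000L)  # 25 kb ends in a partial bin

test_that("binning conserves tags and computes RPKM on true bin widths", {
  tags <- toy_tags(c(rep(5000L, 50L), 12000L, 24500L), chrom = "chr1")
  tr <- bin_counts(tags, genome, 10000L, "rpkm", total = 1e6)
  expect_equal(sum(tr$count), nrow(tags))
  expect_equal(tr$value[tr$chrom == "chr1" & tr$start == 0], 5.0)  # 50/10kb/1M
  # trailing partial bin of chr2 is 5 kb wide
  last <- tr[tr$chrom == "chr2" & tr$start == 20000L, ]
  expect_equal(last$end, 25000L)
  tags2 <- toy_tags(c(21000L, 22000L), chrom = "chr2")
  tr2 <- bin_counts(tags2, genome, 10000L, "rpkm", total = 1e6)
  expect_equal(tr2$value[tr2$chrom == "chr2" & tr2$start == 20000L],
               2 / 5 / 1)  # 2 tags / 5 kb / 1 M
  expect_true(all(bin_counts(toy_tags(integer(0)), genome, 10000L,
                             "count")$value == 0))
  expect_error(bin_counts(tags, genome, 0L), "bin_size")
})

test_that("fold classifier matches the four-colour partition rules", {
  mk <- function(vals) {
    tr <- bin_counts(toy_tags(integer(0)), genome, 10000L, "count")
    tr$value <- rep_len(vals, nrow(tr))
    tr
  }
  a <- mk(c(2.0e-4, 0, 1.0e-4, 1.0e-4, 0, 3.0e-4))
  b <- mk(c(3.0e-4, 0, 1.2e-4, 0,      1e-5, 1.0e-4))
  cls <- classify_bins(a, b)
  expect_equal(cls$category[1:6],
               c("gain",           # ratio exactly 1.5 counts as changed
                 "none_detected",  # both zero
                 "unchanged",      # 1.2-fold
                 "loss",           # query zero, reference positive
                 "gain",           # reference zero, query positive
                 "loss"))
  expect_equal(sum(attr(cls, "fractions")), 1)

  # self-comparison yields no gain or loss among detected bins
  self <- classify_bins(a, a)
  expect_false(any(self$category %in% c("gain", "loss")))

  # swapping conditions swaps gain and loss exactly
  swapped <- classify_bins(b, a)
  f1 <- attr(cls, "fractions"); f2 <- attr(swapped, "fractions")
  expect_equal(unname(f1["gain"]), unname(f2["loss"]))
  expect_equal(unname(f1["loss"]), unname(f2["gain"]))
})

test_that("replicate correlation behaves on identity and toy reversals", {
  tags <- toy_tags(sort(sample.int(30000L, 500L)), chrom = "chr1")
  tr <- bin_counts(tags, genome, 10000L, "rpkm")
  expect_equal(replicate_correlation(tr, tr), 1)
  two <- tr[1:2, ]; two$value <- c(1, 5)
  rev2 <- two; rev2$value <- c(5, 1)
  expect_equal(replicate_correlation(two, rev2), -1)
  expect_error(replicate_correlation(tr[1, ], tr[1, ]), "2 bins")
})

test_that("coverage rate equals the interval-union oracle", {
  regions <- toy_intervals(0L, 1000L)
  nucs <- toy_intervals(c(100L, 200L), c(247L, 347L))
  cov <- coverage_rate(nucs, regions)
  expect_equal(cov$coverage, 0.247)  # union [100,347) = 247 bp

  expect_equal(coverage_rate(toy_intervals(integer(0), integer(0)),
                             regions)$coverage, 0)
  tiled <- toy_intervals(seq(0L, 900L, 100L), seq(100L, 1000L, 100L))
  expect_equal(coverage_rate(tiled, regions)$coverage, 1)
  # regions under 150 bp are excluded
  short <- toy_intervals(c(0L, 5000L), c(100L, 6000L))
  expect_equal(nrow(coverage_rate(nucs, short)), 1)

  # randomised agreement with a per-bp counting oracle
  set.seed(7)
  for (i in 1:20) {
    s <- sort(sample.int(900L, 8L)); iv <- toy_intervals(s, s + 60L)
    got <- coverage_rate(iv, regions)$coverage
    bp <- logical(1000)
    for (j in seq_len(8)) bp[(s[j] + 1):(s[j] + 60)] <- TRUE
    expect_equal(got, mean(bp))
  }
})

test_that("detailed region fractions partition all tags", {
  genes <- toy_genes(c(5000L, 20000L), strand = c("+", "-"),
                     chrom = "chr1", span = 3000L)
  # tags placed in known categories (plus-strand gene at 5000)
  tags <- toy_tags(c(4800L,          # 300 bp upstream of TSS
                     5200L,          # 600 bp downstream of TSS
                     7900L,          # 300 bp upstream of TTS (genic side)
                     8100L,          # 300 bp downstream of TTS
                     6500L,          # genic rest
                     12000L),        # intergenic
                   chrom = "chr1")
  fr <- region_read_fractions(tags, genes, genome)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr[c("tss_up300", "tss_down600", "tts_up300",
                           "tts_down300", "genic_rest", "intergenic")]),
               rep(1 / 6, 6))
  # minus-strand gene: upstream window lies at higher coordinates
  fr2 <- region_read_fractions(toy_tags(20100L), genes, genome)
  expect_equal(unname(fr2["tss_up300"]), 1)
})
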