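genome1 <- toy_genome(chr1 = 10000L)  # ten 1-kb windows

# place `count` tags inside window `idx` (0-based)
window_tags <- function(counts, chrom = "chr1") {
  pos <- unlist(lapply(seq_along(counts), function(i) {
    if (counts[i] == 0) return(integer(0))
    (i - 1L) * 1000L + seq(10L, by = 7L, length.out = counts[i])
  }))
  toy_tags(pos, chrom = chrom)
}

test_that("window scan applies the at-least-six-reads threshold", {
  tags <- window_tags(c(7, 3, 8, 2, 2, 9, 0, 6))
  sc <- window_scan(tags, genome1)
  expect_equal(sc$windows$index, c(0L, 2L, 5L, 7L))  # count 6 included
  expect_equal(sc$windows$count, c(7L, 8L, 9L, 6L))
  expect_equal(nrow(window_scan(toy_tags(integer(0)), genome1)$windows), 0)
})

test_that("gap-tolerant merging sums reads over the merged span", {
  # windows 0 and 2 pass; the single sub-threshold gap window contributes
  sc <- window_scan(window_tags(c(7, 3, 8)), genome1)
  g <- merge_windows(sc)
  expect_equal(nrow(g), 1)
  expect_equal(g$reads, 18L)   # 7 + 3 + 8
  expect_equal(c(g$start, g$end), c(0L, 3000L))

  # two sub-threshold windows between -> two groups
  sc2 <- window_scan(window_tags(c(7, 0, 0, 8)), genome1)
  expect_equal(nrow(merge_windows(sc2)), 2)

  # single window is its own group
  sc3 <- window_scan(window_tags(c(0, 9)), genome1)
  g3 <- merge_windows(sc3)
  expect_equal(g3$reads, 9L)
  expect_equal(c(g3$start, g3$end), c(1000L, 2000L))
})

test_that("island total threshold includes gap-window reads", {
  # windows [40, 5, 30]: gap merge gives one 3-kb island with 75 reads
  isl <- islands_from_tags(window_tags(c(40, 5, 30)), genome1)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$reads, 75L)
  expect_equal(c(isl$start, isl$end), c(0L, 3000L))

  # 59 reads is below the 60-read floor; 60 passes
  expect_equal(nrow(islands_from_tags(window_tags(c(30, 29)), genome1)), 0)
  expect_equal(nrow(islands_from_tags(window_tags(c(30, 30)), genome1)), 1)
})

test_that("island calls equal brute-force enumeration on random toys", {
  set.seed(17)
  for (i in 1:100) {
    n_win <- sample.int(50L, 1L)
    counts <- rpois(n_win, sample(c(1, 5, 9), n_win, replace = TRUE))
    got <- islands_from_tags(window_tags(counts),
                             genome_index(c(chr1 = n_win * 1000L)))
    want <- nucdyn:::brute_force_islands(counts)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$reads, as.integer(want$reads))
  }
})

test_that("bivalency follows the worked 50%-overlap arithmetic", {
  k4 <- data.frame(chrom = "chr1", start = 0L, end = 3000L, reads = 100)
  k27 <- data.frame(chrom = "chr1", start = 1000L, end = 4000L, reads = 100)
  d <- classify_domains(k4, k27)
  expect_equal(nrow(d), 1)
  expect_equal(d$state, "bivalent")       # 2000/3000 = 0.67 >= 0.5
  expect_equal(c(d$start, d$end), c(0L, 4000L))  # union interval

  # identical islands: overlap 1.0
  d2 <- classify_domains(k4, k4)
  expect_equal(d2$state, "bivalent")

  # no K27 anywhere -> active; no K4 -> repressive
  none <- k4[0, ]
  expect_equal(classify_domains(k4, none)$state, "active")
  expect_equal(classify_domains(none, k27)$state, "repressive")

  # sub-threshold overlap keeps each island's own state, flagged
  k27_far <- data.frame(chrom = "chr1", start = 2600L, end = 13000L,
                        reads = 100)
  d3 <- classify_domains(k4, k27_far)  # overlap 400/3000 = 0.13
  expect_equal(sort(d3$state), c("active", "repressive"))
  expect_true(all(d3$partial_overlap))
})

test_that("domain transitions assign reference domains by best overlap", {
  mk <- function(start, end, state)
    data.frame(chrom = "chr1", start = as.integer(start),
               end = as.integer(end), state = state,
               partial_overlap = FALSE, stringsAsFactors = FALSE)
  ref <- mk(seq(0, 9000, 1000), seq(800, 9800, 1000), "repressive")
  # only the first two reference domains persist in the target
  tgt <- mk(c(0, 1000), c(800, 1800), "repressive")
  tr <- domain_transitions(ref, tgt)
  expect_equal(unname(tr["repressive", "repressive"]), 0.2)
  expect_equal(unname(tr["repressive", "none"]), 0.8)
  expect_equal(sum(tr["repressive", ]), 1)

  # identical domain sets give an identity mapping
  mix <- rbind(mk(0, 1000, "active"), mk(5000, 6000, "bivalent"))
  tri <- domain_transitions(mix, mix)
  expect_equal(unname(tri["active", "active"]), 1)
  expect_equal(unname(tri["bivalent", "bivalent"]), 1)

  # no overlap at all -> mass on "none"
  far <- mk(50000, 51000, "active")
  trn <- domain_transitions(mk(0, 1000, "bivalent"), far)
  expect_equal(unname(trn["bivalent", "none"]), 1)
})
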