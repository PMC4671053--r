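test_that("caller resolves single and conflicting tag clusters", {
  one <- toy_tags(rep(5000L, 40L))
  calls <- call_nucleosomes(one)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$dyad, 5000L)
  expect_equal(calls$n_tags, 40L)
  expect_equal(calls$fuzziness, 0)

  # 1000 (50 tags) vs 1100 (40 tags): 100 bp < 147 bp exclusion
  conflict <- toy_tags(c(rep(1000L, 50L), rep(1100L, 40L)))
  c1 <- call_nucleosomes(conflict)
  expect_equal(c1$dyad, 1000L)

  # 1000 vs 1200: 200 bp > 147 bp -> both called
  apart <- toy_tags(c(rep(1000L, 50L), rep(1200L, 40L)))
  c2 <- call_nucleosomes(apart)
  expect_equal(c2$dyad, c(1000L, 1200L))

  # accepted dyads always respect the exclusion zone
  set.seed(31)
  messy <- toy_tags(sort(sample.int(20000L, 800L, replace = TRUE)))
  cm <- call_nucleosomes(messy)
  if (nrow(cm) > 1) expect_true(all(diff(cm$dyad) >= 147))
  expect_true(all(cm$n_tags >= 3))
})

test_that("fuzziness is the RMS deviation about the dyad", {
  expect_equal(fuzziness(c(100, 100, 100), 100), 0)
  expect_equal(fuzziness(c(90, 100, 110), 100), sqrt(200 / 3))
  expect_error(fuzziness(numeric(0), 100), "zero tags")
  # translation invariance
  set.seed(5)
  pos <- round(rnorm(200, 1000, 15))
  expect_equal(fuzziness(pos + 5000, 1000 + 5000), fuzziness(pos, 1000))
  # sampling consistency at known dispersion
  pos2 <- round(rnorm(2000, 50000, 8))
  expect_equal(fuzziness(pos2, 50000), 8, tolerance = 0.5 / 8)
})

test_that("greedy caller agrees with the exhaustive exclusion-zone oracle", {
  set.seed(99)
  for (i in 1:100) {
    pos <- random_peak_toy()
    want <- oracle_peaks(pos)
    got <- call_nucleosomes(toy_tags(pos), min_tags = 1L)
    expect_equal(got$dyad, want, info = paste("toy", i))
  }
})

test_that("common-nucleosome matching is one-to-one below 73 bp", {
  mk_calls <- function(dyads, fuzz = 10) {
    data.frame(chrom = "chr1", dyad = as.integer(dyads),
               n_tags = 10L, fuzziness = fuzz,
               start = as.integer(dyads - 73L),
               end = as.integer(dyads + 74L), stringsAsFactors = FALSE)
  }
  p <- match_common(mk_calls(c(1000, 5000)), mk_calls(c(1050, 5200)))
  expect_equal(nrow(p), 1)
  expect_equal(p$dyad_a, 1000L)
  expect_equal(p$distance, 50L)

  # boundary: distance exactly 73 is excluded (strict less-than)
  expect_equal(nrow(match_common(mk_calls(1000), mk_calls(1073))), 0)
  expect_equal(nrow(match_common(mk_calls(1000), mk_calls(1072))), 1)

  # identity: perfect matching at distance zero
  a <- mk_calls(seq(1000, 9000, 500))
  self <- match_common(a, a)
  expect_equal(nrow(self), nrow(a))
  expect_true(all(self$distance == 0))

  # one-to-one: two B calls near one A call use distinct partners
  p2 <- match_common(mk_calls(c(1000, 1060)), mk_calls(c(1010, 1050)))
  expect_equal(nrow(p2), 2)
  expect_equal(anyDuplicated(p2$dyad_b), 0)
})

test_that("paired fuzziness comparison detects planted shifts", {
  mk_pairs <- function(fa, fb) {
    data.frame(chrom = "chr1", dyad_a = seq_along(fa), dyad_b = seq_along(fa),
               distance = 0L, fuzziness_a = fa, fuzziness_b = fb,
               n_tags_a = 10L, n_tags_b = 10L)
  }
  same <- mk_pairs(c(10, 20, 30), c(10, 20, 30))
  r <- compare_fuzziness(same)
  expect_equal(r$t, 0)
  expect_equal(r$mean_difference, 0)

  set.seed(8)
  fa <- runif(200, 20, 40)
  shifted <- compare_fuzziness(mk_pairs(fa, fa + 5))
  expect_equal(shifted$mean_difference, 5)
  expect_lt(shifted$p_value, 1e-10)
  expect_error(compare_fuzziness(mk_pairs(1, 2)[0, ]), "2 pairs")
})

test_that("planted dyads are recovered within 10 bp when well separated", {
  set.seed(12)
  dyads <- seq(1000L, by = 300L, length.out = 50L)
  pos <- unlist(lapply(dyads, function(d) round(rnorm(60, d, 20))))
  calls <- call_nucleosomes(toy_tags(pos))
  expect_equal(nrow(calls), 50)
  expect_true(all(abs(calls$dyad - dyads) <= 10))
})
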