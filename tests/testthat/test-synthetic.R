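test_that("genome simulation is deterministic and honours hcg_fraction", {
  cfg <- sim_config(seed = 11L, n_genes = 20L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a, b)

  cfg1 <- sim_config(seed = 3L, n_genes = 10L, hcg_fraction = 1.0)
  sim <- simulate_genome(cfg1)
  prom <- promoter_intervals(sim$genes)
  expect_true(all(classify_cpg(prom, sim$cpg_islands) == "HCG"))

  sim0 <- simulate_genome(sim_config(seed = 1L, n_genes = 0L))
  expect_equal(nrow(sim0$genes), 0)
  expect_s3_class(sim0$genes, "data.frame")
})

test_that("genes are placed without overlap", {
  sim <- simulate_genome(sim_config(seed = 5L, n_genes = 30L))
  for (chrom in unique(sim$genes$chrom)) {
    g <- sim$genes[sim$genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("nucleosome map honours depletion windows and multipliers", {
  cfg <- sim_config(seed = 2L, n_genes = 10L)
  sim <- simulate_genome(cfg)
  sim$genes$active <- TRUE
  maps <- simulate_nucleosome_map(
    sim$genome, sim$genes,
    list(A = condition_params(1, 1, 20, tss_depletion = TRUE),
         B = condition_params(0.5, 1, 20, tss_depletion = TRUE)),
    seed = 2L)
  # no dyad in [tss-150, tss+50] for any active gene (strand-aware)
  for (i in seq_len(nrow(sim$genes))) {
    g <- sim$genes[i, ]
    dirn <- if (g$strand == "+") 1 else -1
    rel <- (maps$A$dyad[maps$A$chrom == g$chrom] - g$tss) * dirn
    expect_false(any(rel >= -150 & rel <= 50))
  }
  # planted intergenic ratio recovered from the map weights themselves
  ia <- maps$A[!maps$A$genic, ]
  ib <- maps$B[!maps$B$genic, ]
  expect_equal(sum(ib$occupancy_weight) / sum(ia$occupancy_weight), 0.5,
               tolerance = 1e-6)
})

test_that("read simulation inverts the 73-bp shift exactly", {
  genome <- toy_genome(chr1 = 50000L)
  nuc <- data.frame(chrom = "chr1", dyad = 5000L, fuzziness_sd = 0,
                    occupancy_weight = 5, genic = TRUE, marks = "H3")
  reads <- simulate_reads(nuc, genome, depth_scale = 20, seed = 9L)
  tags <- shift_to_dyad(reads, genome)
  expect_true(all(tags$pos == 5000L))

  nuc$fuzziness_sd <- 8
  nuc$occupancy_weight <- 100
  reads2 <- simulate_reads(nuc, genome, depth_scale = 20, seed = 10L)
  tags2 <- shift_to_dyad(reads2, genome)
  expect_true(nrow(tags2) > 1500)
  expect_equal(sd(tags2$pos), 8, tolerance = 0.5)
  expect_equal(tags2$pos, attr(reads2, "true_dyads"))
})

test_that("duplicate injection resamples existing reads", {
  genome <- toy_genome(chr1 = 50000L)
  nuc <- data.frame(chrom = "chr1", dyad = c(2000L, 9000L),
                    fuzziness_sd = 10, occupancy_weight = 20,
                    genic = TRUE, marks = "H3")
  r0 <- simulate_reads(nuc, genome, depth_scale = 20, duplicate_rate = 0,
                       seed = 4L)
  r1 <- simulate_reads(nuc, genome, depth_scale = 20, duplicate_rate = 0.3,
                       seed = 4L)
  expect_gt(nrow(r1), nrow(r0))
  extra <- r1[-seq_len(nrow(r0)), ]
  key <- function(x) paste(x$start, x$strand)
  expect_true(all(key(extra) %in% key(r0)))
})

test_that("mark-specific reads come only from labelled nucleosomes", {
  genome <- toy_genome(chr1 = 50000L)
  nuc <- data.frame(chrom = "chr1", dyad = c(2000L, 9000L),
                    fuzziness_sd = 0, occupancy_weight = 20,
                    genic = TRUE, marks = c("H3,K4me3", "H3"))
  k4 <- simulate_reads(nuc, genome, depth_scale = 10, mark = "K4me3",
                       seed = 1L)
  tags <- shift_to_dyad(k4, genome)
  expect_true(all(tags$pos == 2000L))
})

test_that("planted expression survives its own DE filter exactly", {
  sim <- simulate_genome(sim_config(seed = 8L, n_genes = 40L))
  tab <- simulate_expression(sim$genes, n_per_cluster = 5L, seed = 8L)
  expect_equal(sum(tab$planted_cluster != "null"), 30L)
  de <- de_genes(tab)
  expect_equal(as.vector(de), tab$planted_cluster != "null")
  # C1 archetype decreases monotonically
  c1 <- tab[tab$planted_cluster == "C1", ]
  expect_true(all(c1$fpkm_MEF > c1$fpkm_preiPSC &
                  c1$fpkm_preiPSC > c1$fpkm_iPSC))
})

test_that("a written simulation round-trips through the format readers", {
  cfg <- sim_config(seed = 13L, n_chroms = 1L, n_genes = 6L)
  sim <- simulate_genome(cfg)
  maps <- simulate_nucleosome_map(sim$genome, sim$genes,
                                  list(A = condition_params()), seed = 13L)
  reads <- list(A = list(H3 = simulate_reads(maps$A, sim$genome,
                                             depth_scale = 2, seed = 13L)))
  expr <- simulate_expression(sim$genes, n_per_cluster = 0L, seed = 13L)
  dir <- tempfile("simout")
  write_simulation(sim, maps, reads, expr, dir)

  genome2 <- read_chrom_sizes(file.path(dir, "genome.sizes.tsv"))
  expect_equal(unclass(genome2), unclass(sim$genome),
               ignore_attr = TRUE)
  genes2 <- read_gene_annotation(file.path(dir, "genes.bed"))
  expect_equal(genes2$tss, sim$genes$tss)
  expect_equal(genes2$strand, sim$genes$strand)
  back <- read_alignments(file.path(dir, "reads_H3_A.bed"), sim$genome)
  expect_equal(back$start, reads$A$H3$start)
  expect_equal(back$strand, reads$A$H3$strand)
  expr2 <- read.delim(file.path(dir, "expression.tsv"))
  expect_equal(expr2$fpkm_MEF, expr$fpkm_MEF, tolerance = 1e-9)
})
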