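# End-to-end orchestration: run every stage on a data set (real or
# simulated), and a planted-truth recovery benchmark that quantifies how
# well each stage recovers what the generator put in.

#' Run the full pipeline on a synthetic data set
#'
#' Generates a toy reprogramming experiment (three conditions, four marks),
#' then runs preprocess -> occupancy -> positioning -> profiles -> domains
#' -> promoters -> expression, writing tracks, calls, domains, promoter
#' tables and a summary JSON when `dir` is given. Stage order and outputs
#' are deterministic under the seed.
#'
#' @param seed Integer seed for all randomness.
#' @param dir Optional output directory; when NULL nothing is written.
#' @param depth_scale Expected tags per unit nucleosome weight.
#' @param config A [sim_config()]; defaults to the standard toy design.
#' @return List with the simulated inputs, per-stage results and a
#'   `summary` list of headline numbers.
#' @export
demo_run <- function(seed = 1L, dir = NULL, depth_scale = 20,
                     config = NULL) {
  if (is.null(config))
    config <- sim_config(seed = seed, n_genes = 24L, gene_length = 20000L,
                         gene_region_fraction = 0.75)
  sim <- simulate_genome(config)
  expr_tab <- simulate_expression(sim$genes, n_per_cluster = 3,
                                  conditions = config$conditions,
                                  seed = seed + 1L)

  # per-condition fuzziness and genic/intergenic multipliers emulate the
  # reprogramming course: the intermediate state is globally more open
  # (intergenic loss, genic gain) with better-phased nucleosomes
  params <- list(
    condition_params(1.0, 1.0, fuzziness_sd = 31),
    condition_params(0.5, 1.2, fuzziness_sd = 26),
    condition_params(1.0, 1.0, fuzziness_sd = 32))
  names(params) <- config$conditions
  # condition-specific promoter classes follow that condition's expression;
  # the shared seed keeps the underlying lattice and weights identical
  maps <- list()
  for (cond in config$conditions) {
    fp <- expr_tab[[paste0("fpkm_", cond)]]
    g <- sim$genes
    g$active <- fp >= 2
    g$promoter_class <- ifelse(fp >= 2, "K4",
                               ifelse(fp >= 0.5, "K4K27", "K27"))
    maps[[cond]] <- simulate_nucleosome_map(sim$genome, g, params[cond],
                                            seed = seed + 2L)[[cond]]
  }

  marks <- c("H3", "K4me3", "K27me3")
  tags <- list(); caps <- list()
  sd_off <- 10L
  for (cond in names(maps)) {
    tags[[cond]] <- list()
    for (mk in marks) {
      sd_off <- sd_off + 1L
      reads <- simulate_reads(maps[[cond]], sim$genome,
                              depth_scale = depth_scale, mark = mk,
                              duplicate_rate = 0.05, seed = seed + sd_off)
      pp <- cap_duplicates(shift_to_dyad(reads, sim$genome))
      tags[[cond]][[mk]] <- pp$tags
      caps[[paste(cond, mk)]] <- pp$cap
    }
  }

  conds <- names(maps)
  tracks <- lapply(conds, function(cond)
    bin_counts(tags[[cond]]$H3, sim$genome, 10000L, "fraction"))
  names(tracks) <- conds
  cls <- classify_bins(tracks[[1]], tracks[[2]])

  calls <- lapply(conds, function(cond)
    call_nucleosomes(tags[[cond]]$H3))
  names(calls) <- conds
  pairs12 <- match_common(calls[[1]], calls[[2]])
  pairs23 <- match_common(calls[[2]], calls[[3]])
  fuzz12 <- compare_fuzziness(pairs12)
  fuzz23 <- compare_fuzziness(pairs23)

  prof <- gene_group_profiles(tags[[conds[1]]]$H3, sim$genes,
                              expr_tab[[paste0("fpkm_", conds[1])]])

  domains <- lapply(conds, function(cond) {
    k4 <- islands_from_tags(tags[[cond]]$K4me3, sim$genome, mark = "K4me3")
    k27 <- islands_from_tags(tags[[cond]]$K27me3, sim$genome, mark = "K27me3")
    classify_domains(k4, k27)
  })
  names(domains) <- conds
  trans <- domain_transitions(domains[[1]], domains[[3]])

  k4_tags <- lapply(tags, `[[`, "K4me3")
  k27_tags <- lapply(tags, `[[`, "K27me3")
  prom <- promoter_records(sim$genes, sim$cpg_islands, k4_tags, k27_tags)
  prom_trans <- state_transitions(prom, conds[1], conds[3])

  de <- de_genes(expr_tab)
  clusters <- if (sum(de) >= 6) cluster_de(expr_tab[de, ], seed = seed)
              else NULL
  cond_cor <- condition_correlation(expr_tab)

  summary <- list(
    seed = seed,
    n_genes = nrow(sim$genes),
    duplicate_caps = caps,
    bin_fractions = as.list(attr(cls, "fractions")),
    n_calls = vapply(calls, nrow, integer(1)),
    fuzziness = list(first_vs_second = fuzz12, second_vs_third = fuzz23),
    n_domains = vapply(domains, nrow, integer(1)),
    domain_transitions = trans,
    promoter_hcg_fraction = mean(prom$cpg_class == "HCG"),
    n_de = sum(de),
    condition_correlation = cond_cor)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in conds) {
      write_track(tracks[[cond]],
                  file.path(dir, sprintf("occupancy10kb_%s.bedGraph", cond)))
      cc <- calls[[cond]]
      write_intervals(data.frame(chrom = cc$chrom, start = cc$start,
                                 end = cc$end,
                                 name = sprintf("nuc%06d", seq_len(nrow(cc))),
                                 score = cc$n_tags, strand = "+"),
                      file.path(dir, sprintf("nucleosomes_%s.bed", cond)))
      dd <- domains[[cond]]
      write_intervals(data.frame(chrom = dd$chrom, start = dd$start,
                                 end = dd$end, name = dd$state,
                                 score = 0L, strand = "+"),
                      file.path(dir, sprintf("domains_%s.bed", cond)))
    }
    data.table::fwrite(prom, file.path(dir, "promoters.tsv"), sep = "\t")
    data.table::fwrite(expr_tab, file.path(dir, "expression.tsv"), sep = "\t")
    jsonlite::write_json(summary_for_json(summary),
                         file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(sim = sim, maps = maps, tags = tags, tracks = tracks,
                 classification = cls, calls = calls,
                 pairs = list(pairs12, pairs23), profiles = prof,
                 domains = domains, promoters = prom,
                 promoter_transitions = prom_trans,
                 expression = expr_tab, de = de, clusters = clusters,
                 summary = summary))
}

summary_for_json <- function(s) {
  s$domain_transitions <- as.data.frame(as.table(s$domain_transitions))
  s$condition_correlation <- as.data.frame(s$condition_correlation)
  s$n_calls <- as.list(s$n_calls)
  s$n_domains <- as.list(s$n_domains)
  s
}

#' Planted-truth recovery benchmark
#'
#' Runs the generator and every analysis stage on scaled-down synthetic
#' data and measures how faithfully each stage recovers the planted truth:
#' the dyad round trip, the duplicate-cap closed form against exhaustive
#' search, the 10-kb fold-class recovery of a planted intergenic occupancy
#' halving, the fuzziness estimator on planted dispersions (8/26/31/32 bp),
#' the nucleosome caller's dyad recall and precision, the island caller
#' against brute-force enumeration, the bivalency interval arithmetic,
#' promoter-state and DE recovery, and the replicate log-RPKM correlation.
#'
#' @param seed Integer seed.
#' @return Named list of metrics; each entry is a list(value, n) where `n`
#'   is the problem size the metric was measured on.
#' @export
recovery_benchmark <- function(seed = 1L) {
  out <- list()

  ## dyad round trip at zero fuzziness
  cfg <- sim_config(seed = seed, n_chroms = 1L, n_genes = 10L)
  sim <- simulate_genome(cfg)
  map <- simulate_nucleosome_map(sim$genome, sim$genes,
                                 list(A = condition_params(fuzziness_sd = 0)),
                                 seed = seed)$A
  reads <- simulate_reads(map, sim$genome, depth_scale = 40, seed = seed)
  tags <- shift_to_dyad(reads, sim$genome)
  out$dyad_roundtrip_match <- list(
    value = mean(tags$pos == attr(reads, "true_dyads")) * 100,
    n = nrow(tags))

  ## duplicate cap: closed form vs exhaustive search
  set.seed(seed + 1L)
  agree <- vapply(seq_len(200), function(i) {
    mult <- sample.int(12L, sample.int(60L, 1L), replace = TRUE)
    ret <- sample(c(0.9, 0.95, 0.99, 1.0), 1L)
    brute <- Find(function(D) sum(pmin(mult, D)) >= ret * sum(mult),
                  seq_len(max(mult)))
    duplicate_cap(mult, ret) == brute
  }, logical(1))
  out$duplicate_cap_oracle_agreement <- list(value = mean(agree) * 100,
                                             n = 200L)

  ## planted intergenic occupancy halving in the 10-kb classifier
  bc <- benchmark_bin_classifier(seed + 2L)
  out$intergenic_loss_recovery <- list(value = bc$loss_recovery * 100,
                                       n = bc$n_intergenic)
  out$genic_misclassification <- list(value = bc$genic_miscls * 100,
                                      n = bc$n_genic)

  ## fuzziness estimator on planted dispersions
  fz <- benchmark_fuzziness(seed + 3L)
  out$fuzziness_recovered_sd8 <- list(value = fz$means[["8"]], n = 500L)
  out$fuzziness_recovered_sd26 <- list(value = fz$means[["26"]], n = 500L)
  out$fuzziness_recovered_sd31 <- list(value = fz$means[["31"]], n = 500L)
  out$fuzziness_recovered_sd32 <- list(value = fz$means[["32"]], n = 500L)
  out$fuzziness_26v31_log10p <- list(value = fz$log10p, n = 500L)

  ## nucleosome caller recall/precision on well-separated planted dyads
  cr <- benchmark_caller(seed + 4L)
  out$dyad_recall <- list(value = cr$recall * 100, n = cr$n_true)
  out$dyad_precision <- list(value = cr$precision * 100, n = cr$n_called)

  ## island caller vs brute force
  isl <- benchmark_islands(seed + 5L, n_cases = 200L)
  out$island_oracle_agreement <- list(value = isl * 100, n = 200L)

  ## bivalency worked interval arithmetic
  biv <- classify_domains(
    data.frame(chrom = "chr1", start = 0L, end = 3000L, reads = 100),
    data.frame(chrom = "chr1", start = 1000L, end = 4000L, reads = 100))
  out$bivalent_domain_span <- list(
    value = if (nrow(biv) == 1 && biv$state == "bivalent")
              biv$end - biv$start else NA_real_,
    n = 1L)

  ## promoter-state recovery with safe margins
  ps <- benchmark_promoter_states(seed + 6L)
  out$promoter_state_accuracy <- list(value = ps$accuracy * 100, n = ps$n)

  ## DE filter + clustering recovery
  de <- benchmark_expression(seed + 7L)
  out$de_filter_accuracy <- list(value = de$accuracy * 100, n = de$n)
  out$de_cluster_ari <- list(value = de$ari, n = de$n_de)

  ## replicate correlation at high depth
  out$replicate_log_rpkm_r <- benchmark_replicates(seed + 8L)

  out
}

benchmark_bin_classifier <- function(seed) {
  # gene-dense layout: because tracks are depth-normalised, a genome-wide
  # intergenic halving is only identifiable when genic mass anchors the
  # library total; 30-kb genes over 75% of each chromosome leave a clean
  # intergenic desert for fully-intergenic 10-kb bins
  cfg <- sim_config(seed = seed, n_chroms = 2L, chrom_length = 500000L,
                    n_genes = 20L, gene_length = 30000L,
                    gene_region_fraction = 0.75)
  sim <- simulate_genome(cfg)
  params <- list(A = condition_params(1, 1, fuzziness_sd = 20),
                 B = condition_params(0.5, 1, fuzziness_sd = 20))
  maps <- simulate_nucleosome_map(sim$genome, sim$genes, params, seed = seed)
  depth <- 80
  tag <- lapply(names(maps), function(cond)
    shift_to_dyad(simulate_reads(maps[[cond]], sim$genome,
                                 depth_scale = depth,
                                 seed = seed + match(cond, names(maps))),
                  sim$genome))
  names(tag) <- names(maps)
  ta <- bin_counts(tag$A, sim$genome, 10000L, "fraction")
  tb <- bin_counts(tag$B, sim$genome, 10000L, "fraction")
  cls <- classify_bins(ta, tb)
  # expected tags per bin per condition from the planted map
  exp_a <- expected_bin_tags(maps$A, sim$genome, 10000L, depth)
  exp_b <- expected_bin_tags(maps$B, sim$genome, 10000L, depth)
  genic_bp <- bin_genic_bp(sim$genes, ta)
  intergenic <- genic_bp == 0 & pmin(exp_a, exp_b) >= 100
  genic <- genic_bp == (ta$end - ta$start) & exp_a >= 100
  list(loss_recovery = mean(cls$category[intergenic] == "loss"),
       n_intergenic = sum(intergenic),
       genic_miscls = if (any(genic))
         mean(cls$category[genic] %in% c("gain", "loss")) else 0,
       n_genic = sum(genic))
}

expected_bin_tags <- function(map, genome, bin_size, depth) {
  grid_key <- function(chrom, pos) paste(chrom, pos %/% bin_size)
  track <- bin_counts(data.frame(chrom = character(), pos = integer(),
                                 strand = character()),
                      genome, bin_size, "count")
  key <- grid_key(track$chrom, track$start)
  w <- tapply(map$occupancy_weight * depth, grid_key(map$chrom, map$dyad), sum)
  out <- rep(0, length(key))
  out[match(names(w), key)] <- as.numeric(w)
  out
}

bin_genic_bp <- function(genes, track) {
  gg <- GenomicRanges::reduce(as_granges0(genes))
  tg <- as_granges0(track)
  hits <- GenomicRanges::findOverlaps(tg, gg)
  bp <- tapply(IRanges::width(IRanges::pintersect(
    tg[S4Vectors::queryHits(hits)], gg[S4Vectors::subjectHits(hits)])),
    S4Vectors::queryHits(hits), sum)
  out <- rep(0L, nrow(track))
  out[as.integer(names(bp))] <- as.integer(bp)
  out
}

benchmark_fuzziness <- function(seed, n_nuc = 500L, n_tags = 1000L) {
  set.seed(seed)
  sds <- c(8, 26, 31, 32)
  est <- sapply(sds, function(s) {
    vapply(seq_len(n_nuc), function(i) {
      dyad <- 100000L
      pos <- as.integer(round(stats::rnorm(n_tags, dyad, s)))
      fuzziness(pos, dyad)
    }, numeric(1))
  })
  colnames(est) <- as.character(sds)
  pairs <- data.frame(fuzziness_a = est[, "31"], fuzziness_b = est[, "26"],
                      chrom = "chr1", dyad_a = 0L, dyad_b = 0L,
                      distance = 0L, n_tags_a = n_tags, n_tags_b = n_tags)
  cmp <- compare_fuzziness(pairs)
  list(means = colMeans(est), log10p = log10(max(cmp$p_value, 1e-300)))
}

benchmark_caller <- function(seed, n_nuc = 300L) {
  set.seed(seed)
  spacing <- 250L
  dyads <- seq(500L, by = spacing, length.out = n_nuc) +
    sample(-20:20, n_nuc, replace = TRUE)
  n_tags <- sample(50:120, n_nuc, replace = TRUE)
  pos <- unlist(lapply(seq_len(n_nuc), function(i)
    as.integer(round(stats::rnorm(n_tags[i], dyads[i], 20)))))
  tags <- data.frame(chrom = "chr1", pos = pos, strand = "+",
                     stringsAsFactors = FALSE)
  calls <- call_nucleosomes(tags)
  d <- abs(outer(dyads, calls$dyad, "-"))
  recall <- mean(apply(d, 1, min) <= 10)
  precision <- mean(apply(d, 2, min) <= 10)
  list(recall = recall, precision = precision,
       n_true = n_nuc, n_called = nrow(calls))
}

# brute-force island enumeration on a vector of window counts
brute_force_islands <- function(counts, win = 1000L, min_reads = 6L,
                                gap = 1L, min_total = 60L) {
  above <- which(counts >= min_reads)
  if (length(above) == 0)
    return(data.frame(start = integer(), end = integer(), reads = integer()))
  groups <- list()
  cur <- c(above[1])
  for (i in above[-1]) {
    if (i - cur[length(cur)] <= gap + 1L) cur <- c(cur, i)
    else { groups[[length(groups) + 1L]] <- cur; cur <- c(i) }
  }
  groups[[length(groups) + 1L]] <- cur
  rows <- lapply(groups, function(g) {
    reads <- sum(counts[g[1]:g[length(g)]])
    data.frame(start = (g[1] - 1L) * win, end = g[length(g)] * win,
               reads = reads)
  })
  res <- do.call(rbind, rows)
  res[res$reads >= min_total, , drop = FALSE]
}

benchmark_islands <- function(seed, n_cases = 200L) {
  set.seed(seed)
  agree <- vapply(seq_len(n_cases), function(i) {
    n_win <- sample.int(50L, 1L)
    counts <- stats::rpois(n_win, sample(c(1, 4, 8, 15), n_win,
                                         replace = TRUE))
    genome <- genome_index(c(chrT = n_win * 1000L))
    pos <- unlist(lapply(seq_len(n_win), function(w)
      if (counts[w] > 0) (w - 1L) * 1000L +
        sample.int(1000L, counts[w], replace = TRUE) - 1L else integer(0)))
    tags <- data.frame(chrom = "chrT",
                       pos = if (is.null(pos)) integer(0) else pos,
                       strand = "+", stringsAsFactors = FALSE)
    got <- islands_from_tags(tags, genome)
    want <- brute_force_islands(counts)
    nrow(got) == nrow(want) &&
      (nrow(got) == 0 || (all(got$start == want$start) &&
                          all(got$end == want$end) &&
                          all(got$reads == want$reads)))
  }, logical(1))
  mean(agree)
}

benchmark_promoter_states <- function(seed) {
  cfg <- sim_config(seed = seed, n_chroms = 1L, n_genes = 40L)
  sim <- simulate_genome(cfg)
  prom <- promoter_intervals(sim$genes)
  set.seed(seed)
  # plant states with RPKM margins at least twice the 1-RPKM threshold
  truth <- sample(c("K4", "K27", "K4K27", "None"), nrow(prom), replace = TRUE)
  total <- 1e6L
  mk_tags <- function(high) {
    n_high <- 10L   # 10 tags / 1 kb / 1e6 total = 10 RPKM >> 1
    idx <- which(high)
    pos <- unlist(lapply(idx, function(i)
      prom$start[i] + sample.int(prom$end[i] - prom$start[i], n_high,
                                 replace = TRUE) - 1L))
    filler <- sample.int(cfg$chrom_length, total, replace = TRUE) - 1L
    # filler kept off promoters so low states stay below threshold
    gpos <- c(pos, setdiff_positions(filler, prom))
    data.frame(chrom = "chr1", pos = as.integer(gpos), strand = "+",
               stringsAsFactors = FALSE)
  }
  k4 <- mk_tags(truth %in% c("K4", "K4K27"))
  k27 <- mk_tags(truth %in% c("K27", "K4K27"))
  got <- promoter_state(promoter_rpkm(k4, prom, total = nrow(k4)),
                        promoter_rpkm(k27, prom, total = nrow(k27)))
  list(accuracy = mean(got == truth), n = nrow(prom))
}

setdiff_positions <- function(pos, intervals) {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 1L, width = 1L))
  pos[!IRanges::overlapsAny(g, as_granges0(intervals))]
}

benchmark_expression <- function(seed) {
  cfg <- sim_config(seed = seed, n_genes = 400L, chrom_length = 2000000L)
  sim <- simulate_genome(cfg)
  tab <- simulate_expression(sim$genes, n_per_cluster = 50L,
                             noise_sd = 0.1, seed = seed)
  de <- de_genes(tab)
  truth_de <- tab$planted_cluster != "null"
  labels <- cluster_de(tab[de, ], k = 6L, seed = seed)
  ari <- mclust::adjustedRandIndex(labels, tab$planted_cluster[de])
  list(accuracy = mean(de == truth_de), n = nrow(tab),
       ari = ari, n_de = sum(de))
}

benchmark_replicates <- function(seed) {
  cfg <- sim_config(seed = seed, n_chroms = 2L, chrom_length = 500000L,
                    n_genes = 20L)
  sim <- simulate_genome(cfg)
  map <- simulate_nucleosome_map(sim$genome, sim$genes,
                                 list(A = condition_params(fuzziness_sd = 25)),
                                 seed = seed)$A
  depth <- 200  # ~1e6 tags over the 1-Mb toy genome
  mk <- function(s) {
    t <- shift_to_dyad(simulate_reads(map, sim$genome, depth_scale = depth,
                                      seed = s), sim$genome)
    bin_counts(t, sim$genome, 100000L, "rpkm")
  }
  r1 <- mk(seed + 100L)
  r2 <- mk(seed + 200L)
  list(value = replicate_correlation(r1, r2), n = nrow(r1))
}
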