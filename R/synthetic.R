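# Ground-truthed synthetic data: toy genomes, nucleosome maps, pre-aligned
# reads per histone mark, and FPKM/q-value expression tables. Everything is
# deterministic under a fixed seed so downstream stages can be tested
# against planted truth without any download.

#' Simulation configuration
#'
#' Bundles the knobs shared by all generator stages. Defaults emulate the
#' reprogramming study design: three conditions (MEF, pre-iPSC, iPSC),
#' 36-bp single-end reads, 147-bp nucleosomes.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_chroms Number of toy chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Number of genes to place.
#' @param gene_length Genic span in bp.
#' @param read_length Read length in bp (must be < nucleosome_size).
#' @param nucleosome_size Nucleosome footprint in bp.
#' @param linker Linker length between lattice positions in bp.
#' @param conditions Condition names, in temporal order.
#' @param hcg_fraction Fraction of promoters overlapping a CpG island.
#' @param gene_region_fraction Fraction of each chromosome (from the start)
#'   holding the gene array; the remainder is an intergenic desert. 1 means
#'   genes are spread over the whole chromosome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 500000L,
                       n_genes = 40L, gene_length = 4000L,
                       read_length = 36L, nucleosome_size = 147L,
                       linker = 50L,
                       conditions = c("MEF", "preiPSC", "iPSC"),
                       hcg_fraction = 0.6, gene_region_fraction = 1) {
  if (read_length >= nucleosome_size)
    stop("read_length must be smaller than nucleosome_size")
  if (chrom_length < 10L * gene_length)
    stop("chrom_length must be at least 10 x gene span")
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 read_length = as.integer(read_length),
                 nucleosome_size = as.integer(nucleosome_size),
                 linker = as.integer(linker),
                 conditions = conditions,
                 hcg_fraction = hcg_fraction,
                 gene_region_fraction = gene_region_fraction),
            class = "sim_config")
}

#' Simulate a toy genome, gene annotation and CpG-island set
#'
#' Genes are placed non-overlapping (with a one-gene-length margin) on the
#' toy chromosomes, alternating strand at random. A configurable fraction of
#' promoters (TSS +/- 500 bp) are given an overlapping CpG island; these
#' become the HCG promoters downstream.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (genome_index), `genes` (gene table) and
#'   `cpg_islands` (interval table).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  genome <- genome_index(stats::setNames(
    rep(config$chrom_length, config$n_chroms),
    paste0("chr", seq_len(config$n_chroms))))
  if (config$n_genes == 0)
    return(list(genome = genome,
                genes = data.frame(gene_id = character(), chrom = character(),
                                   strand = character(), tss = integer(),
                                   tts = integer(), start = integer(),
                                   end = integer()),
                cpg_islands = data.frame(chrom = character(), start = integer(),
                                         end = integer())))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  span <- config$gene_length
  genes <- list()
  gid <- 0L
  for (ci in seq_len(config$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    region <- floor(config$chrom_length * config$gene_region_fraction)
    # one slot per gene; random offset keeps a >= 1-kb gap between genes
    slot <- floor((region - 2L * span) / max(k, 1L))
    jmax <- slot - span - 1000L
    if (jmax < 0L)
      stop("genes cannot be placed without overlap; use a longer chromosome")
    for (j in seq_len(k)) {
      gid <- gid + 1L
      offset <- sample.int(jmax + 1L, 1L) - 1L
      start <- as.integer(span + (j - 1L) * slot + offset)
      end <- start + span
      strand <- sample(c("+", "-"), 1L)
      genes[[gid]] <- data.frame(
        gene_id = sprintf("gene%03d", gid), chrom = paste0("chr", ci),
        strand = strand,
        tss = if (strand == "+") start else end,
        tts = if (strand == "+") end else start,
        start = start, end = end, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  n_hcg <- round(config$hcg_fraction * nrow(genes))
  hcg <- sort(sample.int(nrow(genes), n_hcg))
  genes$hcg <- seq_len(nrow(genes)) %in% hcg
  cpg <- if (n_hcg > 0) {
    data.frame(chrom = genes$chrom[hcg],
               start = pmax(0L, genes$tss[hcg] - 300L),
               end = genes$tss[hcg] + 300L,
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), start = integer(), end = integer())
  list(genome = genome, genes = genes, cpg_islands = cpg)
}

#' Per-condition parameters for the nucleosome map
#'
#' @param intergenic_multiplier Occupancy-weight multiplier applied to
#'   intergenic nucleosomes.
#' @param genic_multiplier Multiplier for genic nucleosomes.
#' @param fuzziness_sd SD in bp of tag positions around each dyad.
#' @param tss_depletion If TRUE, active genes get a nucleosome-depleted
#'   region spanning 150 bp upstream to 50 bp downstream of the TSS and
#'   phased -1..+3 nucleosomes.
#' @return A `condition_params` list.
#' @export
condition_params <- function(intergenic_multiplier = 1,
                             genic_multiplier = 1,
                             fuzziness_sd = 20,
                             tss_depletion = TRUE) {
  if (intergenic_multiplier < 0 || genic_multiplier < 0)
    stop("occupancy multipliers must be non-negative")
  if (fuzziness_sd < 0) stop("fuzziness_sd must be non-negative")
  structure(list(intergenic_multiplier = intergenic_multiplier,
                 genic_multiplier = genic_multiplier,
                 fuzziness_sd = fuzziness_sd,
                 tss_depletion = tss_depletion),
            class = "condition_params")
}

#' Simulate a ground-truth nucleosome map per condition
#'
#' Nucleosomes are placed on a lattice with spacing nucleosome_size + linker
#' and +/-10 bp jitter. For conditions with TSS depletion, active genes
#' (those flagged `active` in the gene table, or every gene when the flag is
#' absent) lose dyads in the window \[tss - 150, tss + 50\] and instead carry
#' phased -1..+3 nucleosomes anchored at the TSS. Occupancy weights are
#' multiplied per condition for genic and intergenic placements. Histone
#' mark labels: every nucleosome carries H3; nucleosomes within gene bodies
#' of active genes carry K4me3 around the TSS; inactive-gene promoters carry
#' K27me3; distal intergenic nucleosomes carry K9me3.
#'
#' @param genome A `genome_index`.
#' @param genes Gene table from [simulate_genome()].
#' @param params Named list of [condition_params()], one per condition.
#' @param seed Integer seed.
#' @return Named list (per condition) of nucleosome tables with columns
#'   chrom, dyad, fuzziness_sd, occupancy_weight, genic, marks
#'   (comma-separated labels).
#' @export
simulate_nucleosome_map <- function(genome, genes, params, seed = 1L) {
  set.seed(seed)
  spacing <- 197L  # 147-bp core + 50-bp linker
  base <- list()
  for (chrom in names(genome)) {
    lat <- seq(100L, unclass(genome)[[chrom]] - 100L, by = spacing)
    jit <- as.integer(round(stats::runif(length(lat), -10, 10)))
    base[[chrom]] <- data.frame(chrom = chrom, dyad = lat + jit,
                                stringsAsFactors = FALSE)
  }
  base <- do.call(rbind, base)
  rownames(base) <- NULL
  base$occupancy_weight <- stats::rgamma(nrow(base), shape = 20, rate = 20)
  # large-scale occupancy heterogeneity: per-50-kb-block lognormal
  # multipliers emulate chromatin compartments/domains; shared across
  # conditions because they are drawn with the base map
  blk <- paste(base$chrom, base$dyad %/% 50000L)
  blk_mult <- stats::setNames(exp(stats::rnorm(length(unique(blk)), 0, 0.25)),
                              unique(blk))
  base$occupancy_weight <- base$occupancy_weight * blk_mult[blk]
  gg <- genes[genes$chrom %in% names(genome), , drop = FALSE]
  base$genic <- interval_member(base$chrom, base$dyad, gg)
  if (is.null(genes$active)) genes$active <- TRUE
  # promoter mark class: explicit genes$promoter_class ("K4", "K27",
  # "K4K27", "None") or derived from activity (active -> K4, else K27)
  pclass <- if (!is.null(genes$promoter_class)) genes$promoter_class
            else ifelse(genes$active, "K4", "K27")
  base$marks <- "H3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    near <- base$chrom == g$chrom & abs(base$dyad - g$tss) <= 1000L
    if (pclass[i] %in% c("K4", "K4K27"))
      base$marks[near] <- paste(base$marks[near], "K4me3", sep = ",")
    if (pclass[i] %in% c("K27", "K4K27"))
      base$marks[near] <- paste(base$marks[near], "K27me3", sep = ",")
  }
  far <- !base$genic & !grepl("K4me3|K27me3", base$marks)
  base$marks[far] <- paste(base$marks[far], "K9me3", sep = ",")

  out <- list()
  for (cond in names(params)) {
    p <- params[[cond]]
    nuc <- base
    nuc$fuzziness_sd <- p$fuzziness_sd
    nuc$occupancy_weight <- nuc$occupancy_weight *
      ifelse(nuc$genic, p$genic_multiplier, p$intergenic_multiplier)
    if (isTRUE(p$tss_depletion)) {
      act_idx <- which(genes$active)
      if (length(act_idx) > 0) {
        drop <- rep(FALSE, nrow(nuc))
        add <- list()
        for (i in act_idx) {
          g <- genes[i, ]
          dirn <- if (g$strand == "+") 1L else -1L
          rel <- (nuc$dyad - g$tss) * dirn
          # clear a window wide enough to hold the phased array, then re-lay it
          drop <- drop | (nuc$chrom == g$chrom & rel >= -250L & rel <= 700L)
          ph_rel <- c(-190L, 120L, 320L, 520L)  # -1, +1, +2, +3
          mk <- paste(c("H3",
                        if (pclass[i] %in% c("K4", "K4K27")) "K4me3",
                        if (pclass[i] %in% c("K27", "K4K27")) "K27me3"),
                      collapse = ",")
          add[[length(add) + 1L]] <- data.frame(
            chrom = g$chrom, dyad = as.integer(g$tss + dirn * ph_rel),
            occupancy_weight = c(1.2, 1.5, 1.3, 1.1),
            genic = TRUE,
            marks = mk,
            fuzziness_sd = p$fuzziness_sd,
            stringsAsFactors = FALSE)
        }
        nuc <- rbind(nuc[!drop, , drop = FALSE],
                     do.call(rbind, add)[, names(nuc)])
      }
    }
    o <- order(nuc$chrom, nuc$dyad)
    nuc <- nuc[o, , drop = FALSE]
    rownames(nuc) <- NULL
    out[[cond]] <- nuc
  }
  out
}

interval_member <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  s <- as_granges0(intervals)
  IRanges::overlapsAny(q, s)
}

#' Simulate pre-aligned reads from a true nucleosome map
#'
#' Tag counts per nucleosome are Poisson(occupancy_weight x depth_scale).
#' Each tag's dyad is Normal(nucleosome dyad, fuzziness_sd) rounded to an
#' integer; strand is Bernoulli(0.5); plus-strand reads start at dyad - 73,
#' minus-strand reads end at dyad + 74, so the downstream 73-bp shift
#' recovers the sampled dyad exactly. Tags whose read would leave the
#' chromosome are resampled. PCR duplicates are added by resampling emitted
#' reads with probability `duplicate_rate`. Only nucleosomes carrying the
#' requested mark emit reads for it.
#'
#' @param nuc_map One condition's nucleosome table.
#' @param genome A `genome_index`.
#' @param depth_scale Expected tags per unit occupancy weight.
#' @param mark Histone mark to sample ("H3", "K4me3", "K27me3", "K9me3").
#' @param duplicate_rate Probability of a PCR duplicate per emitted read.
#' @param read_length Read length in bp.
#' @param shift Half-nucleosome shift used downstream (73 bp).
#' @param seed Integer seed.
#' @return Read data.frame (chrom, start, end, strand) with the sampled
#'   dyads attached as attribute `true_dyads`.
#' @export
simulate_reads <- function(nuc_map, genome, depth_scale = 20,
                           mark = "H3", duplicate_rate = 0,
                           read_length = 36L, shift = 73L, seed = 1L) {
  if (depth_scale <= 0) stop("depth_scale must be > 0")
  set.seed(seed)
  has_mark <- vapply(strsplit(nuc_map$marks, ","), function(m) mark %in% m,
                     logical(1))
  nuc <- nuc_map[has_mark, , drop = FALSE]
  n_tags <- stats::rpois(nrow(nuc), nuc$occupancy_weight * depth_scale)
  idx <- rep.int(seq_len(nrow(nuc)), n_tags)
  dyad <- as.integer(round(stats::rnorm(length(idx), nuc$dyad[idx],
                                        nuc$fuzziness_sd[idx])))
  chrom <- nuc$chrom[idx]
  len <- unclass(genome)[chrom]
  # resample tags whose read or dyad would leave the chromosome
  bad <- which(dyad - shift < 0L | dyad + shift >= len)
  tries <- 0L
  while (length(bad) > 0 && tries < 50L) {
    dyad[bad] <- as.integer(round(stats::rnorm(length(bad), nuc$dyad[idx[bad]],
                                               nuc$fuzziness_sd[idx[bad]])))
    bad <- bad[dyad[bad] - shift < 0L | dyad[bad] + shift >= len[bad]]
    tries <- tries + 1L
  }
  if (length(bad) > 0) {
    dyad <- dyad[-bad]; idx <- idx[-bad]; chrom <- chrom[-bad]
  }
  strand <- ifelse(stats::runif(length(dyad)) < 0.5, "+", "-")
  start <- ifelse(strand == "+", dyad - shift, dyad + shift + 1L - read_length)
  reads <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(start + read_length), strand = strand,
                      stringsAsFactors = FALSE)
  true_dyads <- dyad
  if (duplicate_rate > 0 && nrow(reads) > 0) {
    n_dup <- stats::rbinom(1L, nrow(reads), duplicate_rate)
    if (n_dup > 0) {
      di <- sample.int(nrow(reads), n_dup, replace = TRUE)
      reads <- rbind(reads, reads[di, , drop = FALSE])
      true_dyads <- c(true_dyads, true_dyads[di])
    }
  }
  rownames(reads) <- NULL
  attr(reads, "true_dyads") <- true_dyads
  attr(reads, "true_nuc_index") <- idx
  reads
}

#' Simulate an FPKM/q-value expression table with planted DE clusters
#'
#' Six temporal archetypes over the three conditions (on the FPKM scale):
#' C1 monotone down, C2 low with a mid-course dip, C3 monotone up, C4
#' up-then-down, C5 low with a mid-course bump, C6 down-then-up. Planted DE
#' genes have fold changes >= 4 in at least one pairwise comparison and
#' small q-values there; null genes get flat trajectories and q >= 0.05
#' everywhere, so the fold >= 2 & q < 0.05 filter separates them exactly.
#'
#' @param genes Gene table; trajectories are assigned to its gene_ids.
#' @param n_per_cluster Number of DE genes per archetype (recycled to 6).
#' @param noise_sd Log2-scale Gaussian noise added to each FPKM.
#' @param conditions Condition names (3 expected).
#' @param seed Integer seed.
#' @return data.frame with gene_id, fpkm_<condition> columns,
#'   q_<a>_<b> columns per pairwise comparison, and planted_cluster
#'   ("C1".."C6" or "null").
#' @export
simulate_expression <- function(genes, n_per_cluster = 10,
                                noise_sd = 0.1,
                                conditions = c("MEF", "preiPSC", "iPSC"),
                                seed = 1L) {
  set.seed(seed)
  # six trajectory shapes chosen to stay distinct after per-gene z-scoring
  # (their log-scale shapes point along six well-separated directions):
  # C1 monotone down, C2 early shut-off, C3 monotone up, C4 up-then-down,
  # C5 late activation, C6 down-then-up
  arche <- list(C1 = c(40, 10, 2), C2 = c(20, 2, 2), C3 = c(2, 10, 40),
                C4 = c(3, 30, 3), C5 = c(2, 2, 20), C6 = c(30, 3, 25))
  n_per_cluster <- rep_len(n_per_cluster, 6L)
  n_de <- sum(n_per_cluster)
  if (n_de > nrow(genes))
    stop("not enough genes for the requested DE clusters")
  labels <- c(rep(names(arche), times = n_per_cluster),
              rep("null", nrow(genes) - n_de))
  fpkm <- matrix(0, nrow(genes), length(conditions),
                 dimnames = list(genes$gene_id, conditions))
  for (i in seq_len(nrow(genes))) {
    mu <- if (labels[i] == "null") rep(stats::runif(1, 0.2, 20), 3)
          else arche[[labels[i]]]
    fpkm[i, ] <- pmax(0, 2^(log2(mu + 1) +
                            stats::rnorm(length(mu), 0, noise_sd)) - 1)
  }
  cmp <- utils::combn(conditions, 2)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (j in seq_along(conditions))
    out[[paste0("fpkm_", conditions[j])]] <- fpkm[, j]
  for (k in seq_len(ncol(cmp))) {
    a <- cmp[1, k]; b <- cmp[2, k]
    fold <- pmax(fpkm[, a] + 1, fpkm[, b] + 1) /
            pmin(fpkm[, a] + 1, fpkm[, b] + 1)
    q <- ifelse(labels != "null" & fold >= 2,
                stats::runif(nrow(genes), 0, 0.01),
                stats::runif(nrow(genes), 0.05, 1))
    out[[paste0("q_", a, "_", b)]] <- q
  }
  out$planted_cluster <- labels
  out
}

#' Write a full synthetic data set to disk
#'
#' Emits BED6 reads per mark and condition, BED truth files (nucleosomes as
#' BED6 with the dyad in the name column, CpG islands), BED12 genes, a
#' chrom-sizes TSV and the expression TSV.
#'
#' @param sim Output of [simulate_genome()].
#' @param nuc_maps Output of [simulate_nucleosome_map()].
#' @param reads Named list (condition) of named lists (mark) of read tables.
#' @param expression Expression table.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, nuc_maps, reads, expression, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(
    data.table::data.table(names(sim$genome), as.integer(sim$genome)),
    file.path(dir, "genome.sizes.tsv"), sep = "\t", col.names = FALSE)
  write_gene_bed(sim$genes, file.path(dir, "genes.bed"))
  write_intervals(sim$cpg_islands, file.path(dir, "cpg_islands.bed"))
  for (cond in names(nuc_maps)) {
    nm <- nuc_maps[[cond]]
    write_intervals(data.frame(chrom = nm$chrom, start = nm$dyad,
                               end = nm$dyad + 1L,
                               name = sprintf("nuc_%s", seq_len(nrow(nm))),
                               score = nm$occupancy_weight, strand = "+"),
                    file.path(dir, sprintf("truth_nucleosomes_%s.bed", cond)))
  }
  for (cond in names(reads)) for (mark in names(reads[[cond]])) {
    r <- reads[[cond]][[mark]]
    write_intervals(data.frame(chrom = r$chrom, start = r$start, end = r$end,
                               name = ".", score = 0L, strand = r$strand),
                    file.path(dir, sprintf("reads_%s_%s.bed", mark, cond)))
  }
  data.table::fwrite(expression, file.path(dir, "expression.tsv"), sep = "\t")
  invisible(dir)
}
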