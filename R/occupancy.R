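# Binned occupancy comparison between conditions, replicate correlation,
# nucleosome coverage rates and detailed-region read fractions.

#' Bin dyad tags across the genome
#'
#' Fixed-width bins tile each chromosome; the trailing partial bin keeps its
#' true width (used for RPKM). Normalisation modes: "count" (raw tags),
#' "fraction" (tags per bin divided by the total mapped tags, the 10-kb
#' comparison mode), "rpkm" (reads per kb of bin per million mapped tags,
#' the 100-kb correlation mode).
#'
#' @param tags Tag data.frame (chrom, pos, strand).
#' @param genome A `genome_index`.
#' @param bin_size Bin width in bp.
#' @param normalize One of "count", "fraction", "rpkm".
#' @param total Total mapped tags for normalisation (defaults to nrow(tags)).
#' @return data.frame with chrom, start, end, count, value; attribute
#'   `bin_size` records the grid.
#' @export
bin_counts <- function(tags, genome, bin_size = 10000L,
                       normalize = c("fraction", "rpkm", "count"),
                       total = nrow(tags)) {
  normalize <- match.arg(normalize)
  if (bin_size <= 0) stop("bin_size must be > 0")
  sizes <- unclass(genome)
  grids <- lapply(names(sizes), function(chrom) {
    starts <- seq.int(0L, sizes[[chrom]] - 1L, by = bin_size)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + bin_size, sizes[[chrom]]),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grids)
  key <- paste(grid$chrom, grid$start %/% bin_size)
  tag_key <- paste(tags$chrom, tags$pos %/% bin_size)
  cnt <- table(factor(tag_key, levels = key))
  grid$count <- as.integer(cnt)
  grid$value <- switch(normalize,
    count = as.numeric(grid$count),
    fraction = if (total > 0) grid$count / total else rep(0, nrow(grid)),
    rpkm = {
      width_kb <- (grid$end - grid$start) / 1000
      mill <- max(total, 1) / 1e6
      grid$count / width_kb / mill
    })
  attr(grid, "bin_size") <- as.integer(bin_size)
  attr(grid, "total_tags") <- total
  grid
}

#' Classify bins by occupancy fold change between two conditions
#'
#' Per bin with normalised values a (reference) and b (query): both zero ->
#' "none_detected"; b >= fold x a (including a = 0, b > 0) -> "gain";
#' a >= fold x b (including b = 0, a > 0) -> "loss"; otherwise "unchanged".
#' A ratio of exactly `fold` counts as changed (the >= 1.5-fold rule).
#'
#' @param track_ref,track_query Tracks from [bin_counts()] on one grid.
#' @param fold Fold-change threshold.
#' @return The grid with `ref`, `query`, `category` columns; attribute
#'   `fractions` gives the genome fraction per category (sums to 1).
#' @export
classify_bins <- function(track_ref, track_query, fold = 1.5) {
  if (nrow(track_ref) != nrow(track_query) ||
      !all(track_ref$chrom == track_query$chrom &
           track_ref$start == track_query$start))
    stop("tracks are not on the same bin grid")
  a <- track_ref$value
  b <- track_query$value
  eps <- 1 - 1e-9  # a ratio of exactly `fold` counts as changed
  category <- rep("unchanged", length(a))
  category[a == 0 & b == 0] <- "none_detected"
  category[b >= fold * a * eps & b > 0 & !(a == 0 & b == 0)] <- "gain"
  category[a >= fold * b * eps & a > 0 & !(a == 0 & b == 0)] <- "loss"
  out <- track_ref[, c("chrom", "start", "end")]
  out$ref <- a
  out$query <- b
  out$category <- category
  frac <- table(factor(category,
                       levels = c("gain", "loss", "none_detected", "unchanged")))
  attr(out, "fractions") <- stats::setNames(as.numeric(frac) / length(category),
                                            names(frac))
  out
}

#' Replicate consistency as Pearson correlation of log RPKM
#'
#' Correlates log10(RPKM + pseudocount) between two tracks on the same grid
#' (the 100-kb replicate-consistency check).
#'
#' @param track_a,track_b RPKM tracks from [bin_counts()].
#' @param pseudocount Added before the log to admit zero bins.
#' @param log_base Logarithm base.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(track_a, track_b, pseudocount = 0.01,
                                  log_base = 10) {
  if (nrow(track_a) < 2) stop("need at least 2 bins")
  if (nrow(track_a) != nrow(track_b))
    stop("tracks are not on the same bin grid")
  stats::cor(log(track_a$value + pseudocount, base = log_base),
             log(track_b$value + pseudocount, base = log_base))
}

#' Fraction of each region covered by nucleosome footprints
#'
#' Coverage of a region is |union of footprints intersected with the
#' region| / |region|. Regions shorter than `min_region_len` are excluded.
#'
#' @param footprints Interval data.frame of nucleosome footprints
#'   (e.g. dyad +/- 73 from the positioning module).
#' @param regions Interval data.frame of regions to score.
#' @param min_region_len Minimum region length in bp.
#' @return `regions` (filtered) with a `coverage` column in \[0, 1\].
#' @export
coverage_rate <- function(footprints, regions, min_region_len = 150L) {
  regions <- regions[(regions$end - regions$start) >= min_region_len, ,
                     drop = FALSE]
  rownames(regions) <- NULL
  if (nrow(regions) == 0) {
    regions$coverage <- numeric(0)
    return(regions)
  }
  if (nrow(footprints) == 0) {
    regions$coverage <- 0
    return(regions)
  }
  rg <- as_granges0(regions)
  fg <- GenomicRanges::reduce(as_granges0(footprints))
  hits <- GenomicRanges::findOverlaps(rg, fg)
  inter <- IRanges::pintersect(rg[S4Vectors::queryHits(hits)],
                               fg[S4Vectors::subjectHits(hits)])
  cov_bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(hits), sum)
  regions$coverage <- 0
  idx <- as.integer(names(cov_bp))
  regions$coverage[idx] <- as.numeric(cov_bp) / (regions$end - regions$start)[idx]
  regions
}

#' Fraction of tags falling in detailed genomic region categories
#'
#' Six categories partition the genome: 300 bp upstream of TSSs, 600 bp
#' downstream of TSSs, 300 bp upstream of TTSs, 300 bp downstream of TTSs,
#' the remaining genic regions, and intergenic regions. Upstream/downstream
#' are strand-aware. Precedence where windows collide: TSS windows > TTS
#' windows > genic rest > intergenic.
#'
#' @param tags Tag data.frame.
#' @param genes Gene table.
#' @param genome A `genome_index`.
#' @return Named numeric vector of tag fractions summing to 1.
#' @export
region_read_fractions <- function(tags, genes, genome) {
  dirn <- ifelse(genes$strand == "+", 1L, -1L)
  win <- function(anchor, lo, hi) {
    s <- ifelse(dirn == 1L, anchor + lo, anchor - hi)
    data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(s)),
               end = as.integer(s + (hi - lo)), stringsAsFactors = FALSE)
  }
  cats <- list(
    tss_up300 = win(genes$tss, -300L, 0L),
    tss_down600 = win(genes$tss, 0L, 600L),
    tts_up300 = win(genes$tts, -300L, 0L),
    tts_down300 = win(genes$tts, 0L, 300L),
    genic_rest = data.frame(chrom = genes$chrom, start = genes$start,
                            end = genes$end, stringsAsFactors = FALSE))
  qt <- GenomicRanges::GRanges(tags$chrom,
                               IRanges::IRanges(tags$pos + 1L, width = 1L))
  assigned <- rep(NA_character_, nrow(tags))
  for (nm in names(cats)) {
    iv <- cats[[nm]]
    iv <- iv[iv$end > iv$start, , drop = FALSE]
    if (nrow(iv) == 0) next
    hit <- IRanges::overlapsAny(qt, as_granges0(iv))
    assigned[is.na(assigned) & hit] <- nm
  }
  assigned[is.na(assigned)] <- "intergenic"
  frac <- table(factor(assigned, levels = c(names(cats), "intergenic")))
  stats::setNames(as.numeric(frac) / max(nrow(tags), 1), names(frac))
}
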