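# Histone-mark island calling by genome-wide window scanning with
# single-window gap tolerance, active/repressive/bivalent domain
# classification, and domain-state transitions between conditions.

#' Scan fixed windows for read enrichment
#'
#' Counts tags in non-overlapping `win`-bp windows tiling each chromosome
#' and reports windows holding at least `min_reads` tags. The full per-
#' window counts are kept so that gap windows can contribute reads when
#' groups are merged.
#'
#' @param tags Tag data.frame.
#' @param genome A `genome_index`.
#' @param win Window width in bp.
#' @param min_reads Minimum reads for a window to pass.
#' @return A `window_scan` list: `windows` (data.frame of passing windows:
#'   chrom, index, start, end, count) and `counts` (per-chromosome integer
#'   vectors of all window counts).
#' @export
window_scan <- function(tags, genome, win = 1000L, min_reads = 6L) {
  sizes <- unclass(genome)
  counts <- list()
  rows <- list()
  for (chrom in names(sizes)) {
    n_win <- ceiling(sizes[[chrom]] / win)
    p <- tags$pos[tags$chrom == chrom]
    cnt <- tabulate(p %/% win + 1L, nbins = n_win)
    counts[[chrom]] <- cnt
    idx <- which(cnt >= min_reads)
    if (length(idx) > 0)
      rows[[chrom]] <- data.frame(
        chrom = chrom, index = idx - 1L,
        start = (idx - 1L) * win,
        end = pmin(idx * win, sizes[[chrom]]),
        count = cnt[idx], stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, rows)
  if (is.null(windows))
    windows <- data.frame(chrom = character(), index = integer(),
                          start = integer(), end = integer(),
                          count = integer())
  rownames(windows) <- NULL
  structure(list(windows = windows, counts = counts, win = as.integer(win),
                 min_reads = as.integer(min_reads)),
            class = "window_scan")
}

#' Merge above-threshold windows allowing sub-threshold gaps
#'
#' Passing windows whose indices differ by at most `gap + 1` are merged
#' into one group; the group's read total sums every window in the merged
#' span (gap windows included) and its interval runs from the first window
#' start to the last window end.
#'
#' @param scan A `window_scan`.
#' @param gap Number of tolerated sub-threshold windows between passing
#'   windows.
#' @return data.frame of groups: chrom, start, end, reads, n_windows.
#' @export
merge_windows <- function(scan, gap = 1L) {
  w <- scan$windows
  out <- list()
  for (chrom in unique(w$chrom)) {
    ww <- w[w$chrom == chrom, , drop = FALSE]
    idx <- ww$index
    brk <- c(0L, which(diff(idx) > gap + 1L), length(idx))
    cnt <- scan$counts[[chrom]]
    for (gi in seq_len(length(brk) - 1L)) {
      sel <- (brk[gi] + 1L):brk[gi + 1L]
      first <- idx[sel[1]]; last <- idx[sel[length(sel)]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = ww$start[sel[1]],
        end = ww$end[sel[length(sel)]],
        reads = sum(cnt[(first + 1L):(last + 1L)]),
        n_windows = last - first + 1L, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), reads = integer(),
                      n_windows = integer())
  rownames(res) <- NULL
  res
}

#' Call islands from merged window groups
#'
#' Groups whose summed reads reach `min_total` become islands.
#'
#' @param groups Output of [merge_windows()].
#' @param min_total Minimum reads per island (default 60).
#' @param mark Optional mark label attached to the islands.
#' @return data.frame of islands: chrom, start, end, reads, mark.
#' @export
call_islands <- function(groups, min_total = 60L, mark = NA_character_) {
  isl <- groups[groups$reads >= min_total, , drop = FALSE]
  isl$mark <- rep(mark, nrow(isl))
  rownames(isl) <- NULL
  isl
}

#' Convenience wrapper: tags -> islands
#' @inheritParams window_scan
#' @inheritParams merge_windows
#' @inheritParams call_islands
#' @return Island data.frame as from [call_islands()].
#' @export
islands_from_tags <- function(tags, genome, win = 1000L, min_reads = 6L,
                              gap = 1L, min_total = 60L,
                              mark = NA_character_) {
  call_islands(merge_windows(window_scan(tags, genome, win, min_reads), gap),
               min_total, mark)
}

#' Classify active/repressive/bivalent chromatin domains
#'
#' K4/K27 island pairs with an overlap fraction (intersection over the
#' smaller island) of at least `min_overlap` form one bivalent domain
#' spanning their union; both islands are consumed (pairs taken greedily by
#' descending overlap fraction). Remaining K4 islands are active and
#' remaining K27 islands repressive; islands with a partial (below-
#' threshold) overlap keep their own mark's state and are flagged in the
#' `partial_overlap` column. Overlapping same-mark islands are merged
#' first with a warning.
#'
#' @param k4,k27 Island data.frames for H3K4me3 and H3K27me3.
#' @param min_overlap Minimum overlap fraction for bivalency.
#' @return data.frame of domains: chrom, start, end, state
#'   ("active"/"repressive"/"bivalent"), partial_overlap.
#' @export
classify_domains <- function(k4, k27, min_overlap = 0.5) {
  k4 <- merge_same_mark(k4)
  k27 <- merge_same_mark(k27)
  n4 <- nrow(k4); n27 <- nrow(k27)
  used4 <- rep(FALSE, n4); used27 <- rep(FALSE, n27)
  partial4 <- rep(FALSE, n4); partial27 <- rep(FALSE, n27)
  domains <- list()
  if (n4 > 0 && n27 > 0) {
    g4 <- as_granges0(k4); g27 <- as_granges0(k27)
    hits <- GenomicRanges::findOverlaps(g4, g27)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      inter <- IRanges::width(IRanges::pintersect(g4[qi], g27[si]))
      frac <- inter / pmin(k4$end[qi] - k4$start[qi],
                           k27$end[si] - k27$start[si])
      o <- order(-frac, k4$start[qi])
      for (h in o) {
        i <- qi[h]; j <- si[h]
        if (frac[h] >= min_overlap) {
          if (used4[i] || used27[j]) next
          used4[i] <- TRUE; used27[j] <- TRUE
          domains[[length(domains) + 1L]] <- data.frame(
            chrom = k4$chrom[i],
            start = min(k4$start[i], k27$start[j]),
            end = max(k4$end[i], k27$end[j]),
            state = "bivalent", partial_overlap = FALSE,
            stringsAsFactors = FALSE)
        } else {
          partial4[i] <- TRUE; partial27[j] <- TRUE
        }
      }
    }
  }
  rest4 <- which(!used4)
  if (length(rest4) > 0)
    domains[[length(domains) + 1L]] <- data.frame(
      chrom = k4$chrom[rest4], start = k4$start[rest4], end = k4$end[rest4],
      state = "active", partial_overlap = partial4[rest4],
      stringsAsFactors = FALSE)
  rest27 <- which(!used27)
  if (length(rest27) > 0)
    domains[[length(domains) + 1L]] <- data.frame(
      chrom = k27$chrom[rest27], start = k27$start[rest27],
      end = k27$end[rest27],
      state = "repressive", partial_overlap = partial27[rest27],
      stringsAsFactors = FALSE)
  res <- do.call(rbind, domains)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), state = character(),
                      partial_overlap = logical())
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

merge_same_mark <- function(isl) {
  if (nrow(isl) < 2) return(isl)
  gr <- as_granges0(isl)
  red <- GenomicRanges::reduce(gr)
  if (length(red) < length(gr)) {
    warning("overlapping same-mark islands merged")
    hit <- GenomicRanges::findOverlaps(gr, red)
    reads <- tapply(isl$reads[S4Vectors::queryHits(hit)],
                    S4Vectors::subjectHits(hit), sum)
    isl <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                      start = GenomicRanges::start(red) - 1L,
                      end = GenomicRanges::end(red),
                      reads = as.numeric(reads),
                      mark = isl$mark[1], stringsAsFactors = FALSE)
  }
  isl
}

#' Domain-state transitions between two conditions
#'
#' Each reference domain takes the state of the target-condition domain
#' that overlaps at least `min_overlap` of the reference domain's length
#' (highest overlap wins; ties go to the lower-coordinate target domain),
#' or "none" when no such domain exists. Fractions are per starting state
#' and each row sums to 1.
#'
#' @param ref_domains,target_domains Domain tables from
#'   [classify_domains()].
#' @param min_overlap Minimum overlap fraction of the reference domain.
#' @return Matrix of fractions; rows = reference states present, columns =
#'   active/repressive/bivalent/none. Attribute `counts` holds the raw
#'   count matrix.
#' @export
domain_transitions <- function(ref_domains, target_domains,
                               min_overlap = 0.5) {
  states <- c("active", "repressive", "bivalent")
  target_state <- rep("none", nrow(ref_domains))
  if (nrow(ref_domains) > 0 && nrow(target_domains) > 0) {
    gr <- as_granges0(ref_domains)
    gt <- as_granges0(target_domains)
    hits <- GenomicRanges::findOverlaps(gr, gt)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      inter <- IRanges::width(IRanges::pintersect(gr[qi], gt[si]))
      frac <- inter / (ref_domains$end[qi] - ref_domains$start[qi])
      keep <- frac >= min_overlap
      qi <- qi[keep]; si <- si[keep]; frac <- frac[keep]
      o <- order(qi, -frac, target_domains$start[si])
      best <- !duplicated(qi[o])
      target_state[qi[o][best]] <- target_domains$state[si[o][best]]
    }
  }
  cnt <- table(factor(ref_domains$state, levels = states),
               factor(target_state, levels = c(states, "none")))
  cnt <- unclass(cnt)
  present <- rowSums(cnt) > 0
  frac <- cnt[present, , drop = FALSE] / rowSums(cnt)[present]
  attr(frac, "counts") <- cnt[present, , drop = FALSE]
  frac
}
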