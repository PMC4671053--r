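# CpG-class (HCG/LCG) promoter classification and four-class
# H3K4me3/H3K27me3 promoter-state dynamics with coupled expression.

#' Build promoter intervals (TSS +/- flank)
#'
#' @param genes Gene table.
#' @param flank Flank in bp on each side of the TSS.
#' @return data.frame with gene_id, chrom, start, end (clipped at 0).
#' @export
promoter_intervals <- function(genes, flank = 500L) {
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, as.integer(genes$tss - flank)),
             end = as.integer(genes$tss + flank),
             stringsAsFactors = FALSE)
}

#' Classify promoters as HCG or LCG by CpG-island overlap
#'
#' Any overlap of at least 1 bp with a CpG island makes a promoter HCG;
#' the rest are LCG.
#'
#' @param promoters Promoter intervals from [promoter_intervals()].
#' @param cpg_islands CpG-island interval data.frame.
#' @return Character vector ("HCG"/"LCG") aligned with `promoters`.
#' @export
classify_cpg <- function(promoters, cpg_islands) {
  if (nrow(cpg_islands) == 0) return(rep("LCG", nrow(promoters)))
  hit <- IRanges::overlapsAny(as_granges0(promoters),
                              as_granges0(cpg_islands))
  ifelse(hit, "HCG", "LCG")
}

#' RPKM of dyad tags over promoter intervals
#'
#' Tag count within each interval, divided by interval length in kb and by
#' millions of mapped tags.
#'
#' @param tags Tag data.frame for one mark.
#' @param promoters Promoter intervals.
#' @param total Total mapped tags for the mark (defaults to nrow(tags)).
#' @return Numeric RPKM vector aligned with `promoters`.
#' @export
promoter_rpkm <- function(tags, promoters, total = nrow(tags)) {
  qt <- GenomicRanges::GRanges(tags$chrom,
                               IRanges::IRanges(tags$pos + 1L, width = 1L))
  cnt <- GenomicRanges::countOverlaps(as_granges0(promoters), qt)
  width_kb <- (promoters$end - promoters$start) / 1000
  cnt / width_kb / (max(total, 1) / 1e6)
}

#' Four-class promoter state from H3K4me3/H3K27me3 RPKM
#'
#' Strictly-greater-than-1-RPKM rule: both marks above the threshold ->
#' "K4K27"; only H3K4me3 -> "K4"; only H3K27me3 -> "K27"; otherwise
#' "None". Exactly 1 RPKM does not qualify.
#'
#' @param k4_rpkm,k27_rpkm Numeric RPKM vectors.
#' @param threshold RPKM threshold (strict).
#' @return Character vector of states.
#' @export
promoter_state <- function(k4_rpkm, k27_rpkm, threshold = 1) {
  if (any(k4_rpkm < 0) || any(k27_rpkm < 0)) stop("RPKM must be non-negative")
  k4 <- k4_rpkm > threshold
  k27 <- k27_rpkm > threshold
  out <- rep("None", length(k4))
  out[k4 & !k27] <- "K4"
  out[!k4 & k27] <- "K27"
  out[k4 & k27] <- "K4K27"
  out
}

#' Build the full promoter record table across conditions
#'
#' @param genes Gene table.
#' @param cpg_islands CpG-island intervals.
#' @param k4_tags,k27_tags Named lists (per condition) of tag data.frames.
#' @param flank Promoter half-width in bp.
#' @param threshold State threshold in RPKM.
#' @param k4_totals,k27_totals Optional named numeric vectors (per
#'   condition) of library sizes for the per-million factor; default is the
#'   number of tags supplied.
#' @return data.frame: gene_id, cpg_class, then per condition
#'   k4_rpkm_<cond>, k27_rpkm_<cond>, state_<cond>.
#' @export
promoter_records <- function(genes, cpg_islands, k4_tags, k27_tags,
                             flank = 500L, threshold = 1,
                             k4_totals = NULL, k27_totals = NULL) {
  stopifnot(identical(names(k4_tags), names(k27_tags)))
  prom <- promoter_intervals(genes, flank)
  out <- data.frame(gene_id = prom$gene_id,
                    cpg_class = classify_cpg(prom, cpg_islands),
                    stringsAsFactors = FALSE)
  for (cond in names(k4_tags)) {
    t4 <- if (is.null(k4_totals)) nrow(k4_tags[[cond]]) else k4_totals[[cond]]
    t27 <- if (is.null(k27_totals)) nrow(k27_tags[[cond]])
           else k27_totals[[cond]]
    k4 <- promoter_rpkm(k4_tags[[cond]], prom, total = t4)
    k27 <- promoter_rpkm(k27_tags[[cond]], prom, total = t27)
    out[[paste0("k4_rpkm_", cond)]] <- k4
    out[[paste0("k27_rpkm_", cond)]] <- k27
    out[[paste0("state_", cond)]] <- promoter_state(k4, k27, threshold)
  }
  out
}

#' Promoter-state transition fractions between two conditions
#'
#' For each CpG class and starting state, the fraction of promoters ending
#' in each of the four states; rows sum to 1. Start states with no
#' promoters in a class are omitted.
#'
#' @param records Promoter table from [promoter_records()] (or any frame
#'   with cpg_class and state_<cond> columns).
#' @param from,to Condition names.
#' @return Named list (per CpG class) of fraction matrices with a `counts`
#'   attribute.
#' @export
state_transitions <- function(records, from, to) {
  s_from <- records[[paste0("state_", from)]]
  s_to <- records[[paste0("state_", to)]]
  if (is.null(s_from) || is.null(s_to)) stop("missing condition states")
  states <- c("K4", "K27", "K4K27", "None")
  out <- list()
  for (cls in c("HCG", "LCG")) {
    sel <- records$cpg_class == cls
    cnt <- table(factor(s_from[sel], levels = states),
                 factor(s_to[sel], levels = states))
    cnt <- unclass(cnt)
    present <- rowSums(cnt) > 0
    if (!all(present))
      message(cls, ": no promoters start in state ",
              paste(states[!present], collapse = "/"), "; rows omitted")
    frac <- cnt[present, , drop = FALSE] / rowSums(cnt)[present]
    attr(frac, "counts") <- cnt[present, , drop = FALSE]
    out[[cls]] <- frac
  }
  out
}

#' Expression distributions grouped by promoter-state change
#'
#' Restricts to promoters starting in `start_state` in condition `from`,
#' groups them by their state in condition `to`, and returns per-group
#' log2(FPKM + 1) vectors with pairwise two-tailed t-tests between groups
#' (groups of fewer than 2 genes are reported without tests).
#'
#' @param records Promoter table from [promoter_records()].
#' @param fpkm Named numeric vector of FPKM (names = gene_id) in the
#'   condition of interest.
#' @param start_state Starting state to condition on.
#' @param from,to Condition names.
#' @return List with `groups` (named list of log2 expression vectors) and
#'   `tests` (data.frame group_a, group_b, t, p_value), which is empty if
#'   fewer than two groups are testable.
#' @export
expression_by_state_change <- function(records, fpkm, start_state, from, to) {
  s_from <- records[[paste0("state_", from)]]
  s_to <- records[[paste0("state_", to)]]
  sel <- s_from == start_state
  grp <- split(records$gene_id[sel], s_to[sel])
  groups <- lapply(grp, function(ids) log2(fpkm[ids] + 1))
  testable <- names(groups)[vapply(groups, length, integer(1)) >= 2]
  tests <- list()
  if (length(testable) >= 2) {
    pairs <- utils::combn(testable, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      tt <- stats::t.test(groups[[a]], groups[[b]])
      tests[[k]] <- data.frame(group_a = a, group_b = b,
                               t = unname(tt$statistic),
                               p_value = tt$p.value,
                               stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests) > 0) do.call(rbind, tests)
           else data.frame(group_a = character(), group_b = character(),
                           t = numeric(), p_value = numeric())
  list(groups = groups, tests = tests)
}
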