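# TSS-anchored average occupancy profiles, per-gene heatmap matrices and
# K-means clustering of occupancy profiles.

# signed distance of tag positions from each gene's TSS (downstream > 0)
tss_relative_positions <- function(tags, genes, window) {
  rel <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    p <- tags$pos[tags$chrom == g$chrom &
                  tags$pos >= g$tss - window & tags$pos <= g$tss + window]
    r <- p - g$tss
    if (g$strand == "-") r <- -r
    rel[[i]] <- r[r >= -window & r < window]
  }
  rel
}

#' Average occupancy profile around TSSs
#'
#' Tags within `window` bp of each TSS are counted by their strand-aware
#' relative distance (downstream positive), summed across genes, binned at
#' `bin` bp, normalised to RPKM (per kb of bin per gene per million mapped
#' tags) and smoothed with a centred `smooth_bins`-bin moving average with
#' 1-bin step; edge bins use shrinking windows.
#'
#' @param tags Tag data.frame.
#' @param genes Gene table (one row per TSS).
#' @param window Half-window in bp.
#' @param bin Bin width in bp.
#' @param smooth_bins Moving-average width in bins.
#' @param total Total mapped tags for the per-million factor.
#' @return data.frame with `position` (bin centre relative to TSS, bp),
#'   `raw` (summed counts), `value` (smoothed RPKM).
#' @export
tss_profile <- function(tags, genes, window = 2000L, bin = 10L,
                        smooth_bins = 5L, total = nrow(tags)) {
  if (nrow(genes) == 0) stop("no genes supplied")
  rel <- unlist(tss_relative_positions(tags, genes, window))
  breaks <- seq(-window, window, by = bin)
  counts <- tabulate(findInterval(rel, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  width_kb <- bin / 1000
  mill <- max(total, 1) / 1e6
  rpkm <- counts / nrow(genes) / width_kb / mill
  data.frame(position = breaks[-length(breaks)] + bin / 2,
             raw = counts,
             value = moving_average(rpkm, smooth_bins))
}

# centred moving average; edges use shrinking windows (no padding)
moving_average <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' TSS profiles for expression-defined gene groups
#'
#' Genes are partitioned into the top expressed fraction, silent genes
#' (FPKM below `silent_fpkm`) and the rest; a profile is computed per
#' non-empty group. The top group holds `ceiling(top_quantile x number of
#' expressed genes)` genes by descending FPKM.
#'
#' @param tags Tag data.frame.
#' @param genes Gene table.
#' @param fpkm Numeric FPKM per gene, aligned with `genes` rows.
#' @param top_quantile Fraction of expressed genes in the top group.
#' @param silent_fpkm FPKM floor below which a gene is silent.
#' @inheritParams tss_profile
#' @return Named list of profiles (subset of top, others, silent) plus a
#'   `groups` factor aligned with `genes`.
#' @export
gene_group_profiles <- function(tags, genes, fpkm, top_quantile = 0.05,
                                silent_fpkm = 0.5, window = 2000L,
                                bin = 10L, smooth_bins = 5L,
                                total = nrow(tags)) {
  stopifnot(length(fpkm) == nrow(genes))
  group <- rep("others", nrow(genes))
  group[fpkm < silent_fpkm] <- "silent"
  expressed <- which(group != "silent")
  n_top <- ceiling(top_quantile * length(expressed))
  if (n_top > 0) {
    top_idx <- expressed[order(-fpkm[expressed])][seq_len(n_top)]
    group[top_idx] <- "top"
  }
  group <- factor(group, levels = c("top", "others", "silent"))
  out <- list()
  for (g in levels(group)) {
    sel <- genes[group == g, , drop = FALSE]
    if (nrow(sel) == 0) {
      warning("empty gene group omitted: ", g)
      next
    }
    out[[g]] <- tss_profile(tags, sel, window = window, bin = bin,
                            smooth_bins = smooth_bins, total = total)
  }
  out$groups <- group
  out
}

#' Per-gene occupancy matrix around TSSs
#'
#' One row per gene over a TSS-relative window at 1-bp resolution.
#' Nucleosome calls are painted over \[dyad - fuzziness, dyad + fuzziness\]
#' (the fuzziness-extended footprint), weighted by tag count; rows are
#' sorted by `rank_by` descending, and the ordering is recorded in the
#' `gene_order` attribute for reuse across conditions.
#'
#' @param calls Call table from [call_nucleosomes()].
#' @param genes Gene table.
#' @param window Integer c(upstream, downstream) relative bounds, e.g.
#'   c(-500, 1500).
#' @param rank_by Per-gene scalar used to order rows (names or order
#'   aligned with genes$gene_id); alternatively a previously exported
#'   character vector of gene_ids via `gene_order`.
#' @param gene_order Optional explicit gene_id ordering overriding rank_by.
#' @return Numeric matrix (genes x positions) with dimnames; attribute
#'   `gene_order`.
#' @export
profile_matrix <- function(calls, genes, window = c(-500L, 1500L),
                           rank_by = NULL, gene_order = NULL) {
  npos <- window[2] - window[1] + 1L
  mat <- matrix(0, nrow(genes), npos,
                dimnames = list(genes$gene_id, window[1]:window[2]))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cc <- calls[calls$chrom == g$chrom, , drop = FALSE]
    if (nrow(cc) == 0) next
    dirn <- if (g$strand == "+") 1L else -1L
    rel_dyad <- (cc$dyad - g$tss) * dirn
    half <- pmax(1L, as.integer(round(cc$fuzziness)))
    for (j in seq_len(nrow(cc))) {
      lo <- max(window[1], rel_dyad[j] - half[j])
      hi <- min(window[2], rel_dyad[j] + half[j])
      if (lo > hi) next
      cols <- (lo - window[1] + 1L):(hi - window[1] + 1L)
      mat[i, cols] <- mat[i, cols] + cc$n_tags[j]
    }
  }
  if (!is.null(gene_order)) {
    missing <- setdiff(gene_order, rownames(mat))
    if (length(missing) > 0) stop("gene_order contains unknown gene_ids")
    mat <- mat[gene_order, , drop = FALSE]
  } else if (!is.null(rank_by)) {
    if (!is.null(names(rank_by))) rank_by <- rank_by[rownames(mat)]
    drop_rows <- is.na(rank_by)
    if (any(drop_rows)) {
      warning(sum(drop_rows), " genes without rank_by dropped")
      mat <- mat[!drop_rows, , drop = FALSE]
      rank_by <- rank_by[!drop_rows]
    }
    mat <- mat[order(-rank_by, rownames(mat)), , drop = FALSE]
  }
  attr(mat, "gene_order") <- rownames(mat)
  mat
}

#' K-means clustering of per-gene occupancy profiles
#'
#' Clusters the rows of a profile matrix restricted to a TSS-relative
#' subwindow (default 300 bp upstream to 600 bp downstream). Deterministic
#' under a fixed seed; clusters are relabelled by descending cluster mean
#' occupancy so labels are stable across runs.
#'
#' @param mat Profile matrix from [profile_matrix()].
#' @param k Number of clusters.
#' @param subwindow Integer c(from, to) TSS-relative bounds used as
#'   features.
#' @param seed Integer seed.
#' @param nstart Number of random restarts.
#' @return Integer vector of cluster labels (1 = highest mean occupancy),
#'   named by gene_id, with the fitted `kmeans` object as attribute `fit`.
#' @export
kmeans_profiles <- function(mat, k = 4L, subwindow = c(-300L, 600L),
                            seed = 1L, nstart = 50L) {
  if (k > nrow(mat)) stop("k exceeds the number of genes")
  cols <- as.character(subwindow[1]:subwindow[2])
  cols <- cols[cols %in% colnames(mat)]
  feat <- mat[, cols, drop = FALSE]
  set.seed(seed)
  if (k == 1L) {
    labels <- stats::setNames(rep(1L, nrow(mat)), rownames(mat))
    return(labels)
  }
  fit <- stats::kmeans(feat, centers = k, nstart = nstart, iter.max = 100L)
  relabel <- order(-rowMeans(fit$centers))
  new_label <- match(seq_len(k), relabel)
  labels <- stats::setNames(new_label[fit$cluster], rownames(mat))
  attr(labels, "fit") <- fit
  labels
}
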