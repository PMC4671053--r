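# Differential-expression filtering, six-cluster temporal K-means and
# condition correlation matrices from an FPKM + q-value table.

fpkm_columns <- function(table) {
  grep("^fpkm_", names(table), value = TRUE)
}

#' Filter differentially expressed genes
#'
#' A gene is DE iff some pairwise comparison shows a fold change of at
#' least `fold` together with q below `q_max`. Fold change is computed on
#' FPKM with a pseudocount of 1 as (max + 1)/(min + 1), so it is symmetric
#' in the two conditions. Comparisons are taken from the `q_<a>_<b>`
#' columns; genes with a missing q-value in a comparison skip it with a
#' warning.
#'
#' @param table Expression table with fpkm_<cond> and q_<a>_<b> columns.
#' @param fold Minimum fold change.
#' @param q_max Maximum q-value (strict).
#' @return Logical vector (is DE) aligned with rows; attribute
#'   `per_comparison` holds the per-comparison DE logical matrix.
#' @export
de_genes <- function(table, fold = 2, q_max = 0.05) {
  qcols <- grep("^q_", names(table), value = TRUE)
  if (length(qcols) == 0) stop("no q_<a>_<b> comparison columns found")
  per <- matrix(FALSE, nrow(table), length(qcols),
                dimnames = list(table$gene_id, qcols))
  for (qc in qcols) {
    ab <- strsplit(sub("^q_", "", qc), "_")[[1]]
    fa <- table[[paste0("fpkm_", ab[1])]]
    fb <- table[[paste0("fpkm_", ab[2])]]
    fc <- pmax(fa + 1, fb + 1) / pmin(fa + 1, fb + 1)
    q <- table[[qc]]
    if (anyNA(q)) warning("missing q-values in ", qc, "; comparisons skipped")
    per[, qc] <- !is.na(q) & fc >= fold & q < q_max
  }
  de <- rowSums(per) > 0
  attr(de, "per_comparison") <- per
  de
}

#' K-means clustering of DE-gene temporal trajectories
#'
#' Features are per-gene z-scored log2(FPKM + 1) across conditions
#' (zero-variance rows are centred only). Deterministic under a fixed
#' seed. Clusters are relabelled canonically by their centroid
#' trajectories — ascending (net change, early change) — so that C1 is the
#' most-decreasing and the last cluster the most-increasing pattern,
#' stable across seeds.
#'
#' @param table Expression table restricted to DE genes.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param zscore If FALSE, cluster raw log2(FPKM + 1) rows instead.
#' @param nstart Random restarts.
#' @return Character vector of labels "C1".."Ck" named by gene_id, with
#'   the fitted object in attribute `fit` and centroids (on the feature
#'   scale) in attribute `centers`.
#' @export
cluster_de <- function(table, k = 6L, seed = 1L, zscore = TRUE,
                       nstart = 50L) {
  fc <- fpkm_columns(table)
  x <- log2(as.matrix(table[, fc]) + 1)
  rownames(x) <- table$gene_id
  if (nrow(x) < k) stop("fewer DE genes than clusters")
  feat <- x
  if (zscore) {
    mu <- rowMeans(feat)
    s <- apply(feat, 1, stats::sd)
    feat <- (feat - mu) / ifelse(s > 0, s, 1)  # zero-variance rows: centre only
  }
  set.seed(seed)
  fit <- stats::kmeans(feat, centers = k, nstart = nstart, iter.max = 100L)
  cen <- fit$centers
  net <- cen[, ncol(cen)] - cen[, 1]
  early <- cen[, 2] - cen[, 1]
  relabel <- order(net, early)
  new_id <- match(fit$cluster, relabel)
  labels <- stats::setNames(paste0("C", new_id), rownames(feat))
  attr(labels, "fit") <- fit
  attr(labels, "centers") <- cen[relabel, , drop = FALSE]
  labels
}

#' Pearson correlation matrix across condition FPKM profiles
#'
#' Correlates log(FPKM + pseudocount) between every pair of fpkm_ columns.
#' Zero-variance columns yield NA against every other column.
#'
#' @param table Expression table.
#' @param pseudocount Added before the log.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
condition_correlation <- function(table, pseudocount = 1) {
  fc <- fpkm_columns(table)
  if (length(fc) < 2) stop("need at least 2 condition columns")
  x <- log2(as.matrix(table[, fc]) + pseudocount)
  colnames(x) <- sub("^fpkm_", "", fc)
  suppressWarnings(r <- stats::cor(x))
  diag(r) <- 1
  r
}
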