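# Read -> dyad-tag preprocessing: the half-nucleosome 3' shift and the
# duplicate-retention cap applied before any downstream counting.

#' Shift aligned reads to their inferred dyad positions
#'
#' Each read is shifted half a nucleosome (default 73 bp) in its 3'
#' direction: plus-strand tags land at `start + shift`, minus-strand tags at
#' `(end - 1) - shift` (the 5' base of a minus-strand read is `end - 1`).
#' Tags shifted off either chromosome end are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param reads Read data.frame (chrom, start, end, strand).
#' @param genome A `genome_index`.
#' @param shift Shift in bp toward 3' (half the nucleosome size).
#' @return Tag data.frame (chrom, pos, strand).
#' @export
shift_to_dyad <- function(reads, genome, shift = 73L) {
  pos <- ifelse(reads$strand == "+",
                reads$start + shift,
                (reads$end - 1L) - shift)
  tags <- data.frame(chrom = reads$chrom, pos = as.integer(pos),
                     strand = reads$strand, stringsAsFactors = FALSE)
  len <- unclass(genome)[tags$chrom]
  ok <- tags$pos >= 0L & tags$pos < len
  dropped <- sum(!ok)
  tags <- tags[ok, , drop = FALSE]
  rownames(tags) <- NULL
  if (dropped > 0)
    message(sprintf("%d tags shifted off chromosome ends were dropped", dropped))
  attr(tags, "n_dropped") <- dropped
  tags
}

#' Cap PCR-duplicate tags at a retention-preserving multiplicity
#'
#' Duplicates are tags sharing (chromosome, position, strand). The cap is
#' the smallest integer D such that truncating every duplicate group at D
#' still retains at least `retention` of all tags; groups are then truncated
#' to D, keeping the first-encountered tags (deterministic).
#'
#' @param tags Tag data.frame (chrom, pos, strand).
#' @param retention Minimum fraction of tags that must survive (the
#'   default 0.99).
#' @return List with `tags` (filtered, input order preserved) and `cap`
#'   (list: cap, retained, total).
#' @export
cap_duplicates <- function(tags, retention = 0.99) {
  total <- nrow(tags)
  if (total == 0) {
    warning("no tags; duplicate cap undefined")
    return(list(tags = tags, cap = list(cap = NA_integer_, retained = 0L,
                                        total = 0L)))
  }
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  key <- paste(tags$chrom, tags$pos, tags$strand, sep = "\r")
  mult <- table(key)
  cap <- duplicate_cap(as.integer(mult), retention)
  idx <- data.table::rowid(key)
  keep <- idx <= cap
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(tags = out,
       cap = list(cap = cap, retained = sum(keep), total = total))
}

# smallest D with sum(pmin(m, D)) >= retention * total, via one sorted scan
duplicate_cap <- function(mult, retention) {
  total <- sum(mult)
  target <- retention * total
  m <- sort(mult)
  n <- length(m)
  # retained(D) = sum(m[m <= D]) + D * #{m > D}; evaluate at candidate D values
  csum <- cumsum(as.numeric(m))
  for (D in seq_len(max(m))) {
    k <- findInterval(D, m)            # number of groups with m <= D
    retained <- (if (k > 0) csum[k] else 0) + D * (n - k)
    if (retained >= target) return(as.integer(D))
  }
  as.integer(max(m))
}
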