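# Shared fixture builders: everything is generated in code at test time.

toy_genome <- function(...) {
  sizes <- c(...)
  if (length(sizes) == 0) sizes <- c(chr1 = 100000L, chr2 = 50000L)
  genome_index(sizes)
}

toy_tags <- function(pos, chrom = "chr1", strand = "+") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             strand = rep_len(strand, length(pos)), stringsAsFactors = FALSE)
}

toy_genes <- function(tss, strand = "+", chrom = "chr1", span = 2000L) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss, tss - span)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             chrom = rep_len(chrom, n), strand = strand,
             tss = as.integer(tss),
             tts = as.integer(ifelse(strand == "+", tss + span, tss - span)),
             start = as.integer(start), end = as.integer(start + span),
             stringsAsFactors = FALSE)
}

toy_intervals <- function(start, end, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(start)),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# write a minimal single-end SAM file (1-based positions)
write_toy_sam <- function(path, chrom_sizes, recs) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  body <- vapply(recs, function(r) {
    seq <- paste(rep("A", r$len), collapse = "")
    sprintf("%s\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t%s",
            r$name, if (r$strand == "-") 16L else 0L, r$chrom, r$pos1,
            r$len, seq, paste(rep("I", r$len), collapse = ""))
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# independent brute-force oracle for the greedy exclusion-zone peak caller:
# signal recomputed by direct summation; candidates are strict local maxima;
# all exclusion-respecting candidate subsets are enumerated and the one with
# the highest total signal (ties: lexicographically earliest dyad vector)
# is returned
oracle_peaks <- function(pos, sigma = 20, exclusion = 147L) {
  lo <- min(pos) - 4L * ceiling(sigma)
  hi <- max(pos) + 4L * ceiling(sigma)
  grid <- lo:hi
  sig <- vapply(grid, function(x) {
    d <- abs(x - pos)
    sum(stats::dnorm(d[d <= 4 * sigma], sd = sigma))
  }, numeric(1))
  n <- length(sig)
  is_max <- sig > 1e-8 &
    sig >= c(-Inf, sig[-n]) & sig > c(sig[-1], -Inf)
  cand <- grid[is_max]
  w <- sig[is_max]
  k <- length(cand)
  stopifnot(k <= 15)  # keep enumeration tractable
  best <- NULL; best_w <- -Inf
  for (code in 0:(2^k - 1)) {
    sel <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
    if (length(sel) > 1 && min(diff(cand[sel])) < exclusion) next
    tw <- sum(w[sel])
    if (tw > best_w + 1e-12) { best_w <- tw; best <- cand[sel] }
  }
  sort(best)
}

# toy tag sets whose cluster geometry avoids chained conflicts, so the
# greedy caller and the max-total-signal oracle provably coincide
random_peak_toy <- function() {
  n_clu <- sample(1:4, 1)
  centers <- numeric(0)
  x <- 500
  for (i in seq_len(n_clu)) {
    gap <- if (i == 1) 0
           else if (length(centers) >= 1 && stats::runif(1) < 0.3 &&
                    (i == 1 || last_gap >= 300)) sample(60:120, 1)
           else sample(300:500, 1)
    x <- x + gap
    centers <- c(centers, x)
    last_gap <- if (i == 1) 1000 else gap
  }
  pos <- unlist(lapply(centers, function(cc)
    round(stats::rnorm(sample(10:40, 1), cc, 8))))
  pos[pos > 0]
}
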