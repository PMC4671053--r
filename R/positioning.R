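# Nucleosome position calling from dyad tags, per-nucleosome fuzziness,
# common-nucleosome matching between conditions, and paired fuzziness
# comparison.

#' Call nucleosome positions with a Gaussian-kernel peak caller
#'
#' Per chromosome, a per-bp signal is built as the sum of Gaussian kernels
#' (SD `sigma`) centred at each tag position. Candidate dyads are taken
#' greedily by descending signal (ties broken toward the lower coordinate);
#' an accepted dyad suppresses all candidates strictly closer than
#' `exclusion` bp, so accepted dyads on one chromosome are at least
#' `exclusion` bp apart. Tags are then assigned to the nearest accepted
#' dyad within 73 bp, fuzziness is the RMS deviation of assigned tags about
#' the dyad, and calls with fewer than `min_tags` tags are dropped.
#'
#' @param tags Tag data.frame (chrom, pos, strand).
#' @param sigma Kernel SD in bp.
#' @param exclusion Minimum distance between accepted dyads in bp (one
#'   nucleosome footprint).
#' @param min_tags Minimum tags per reported call.
#' @param footprint_half Half-footprint for the reported interval and for
#'   tag assignment (73 bp).
#' @return data.frame with chrom, dyad, n_tags, fuzziness, start, end
#'   (footprint dyad +/- footprint_half), sorted by chrom then dyad.
#' @export
call_nucleosomes <- function(tags, sigma = 20, exclusion = 147L,
                             min_tags = 3L, footprint_half = 73L) {
  if (sigma <= 0) stop("sigma must be > 0")
  res <- lapply(split(tags$pos, tags$chrom), call_chromosome,
                sigma = sigma, exclusion = exclusion, min_tags = min_tags,
                footprint_half = footprint_half)
  chroms <- rep(names(res), vapply(res, nrow, integer(1)))
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(chrom = character(), dyad = integer(),
                      n_tags = integer(), fuzziness = numeric(),
                      start = integer(), end = integer()))
  out <- cbind(data.frame(chrom = chroms, stringsAsFactors = FALSE), out)
  o <- order(out$chrom, out$dyad)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

call_chromosome <- function(pos, sigma, exclusion, min_tags, footprint_half) {
  empty <- data.frame(dyad = integer(), n_tags = integer(),
                      fuzziness = numeric(), start = integer(),
                      end = integer())
  if (length(pos) == 0) return(empty)
  lo <- min(pos) - 4L * ceiling(sigma)
  hi <- max(pos) + 4L * ceiling(sigma)
  signal <- kernel_signal(pos, lo, hi, sigma)
  dyads <- greedy_peaks(signal, exclusion) + lo
  if (length(dyads) == 0) return(empty)
  # assign each tag to the nearest accepted dyad within the half footprint
  sd_ord <- sort(dyads)
  nearest <- findInterval(pos, sd_ord)
  left <- pmax(nearest, 1L)
  right <- pmin(nearest + 1L, length(sd_ord))
  pick <- ifelse(abs(pos - sd_ord[left]) <= abs(pos - sd_ord[right]),
                 left, right)
  dist <- abs(pos - sd_ord[pick])
  keep <- dist <= footprint_half
  assigned <- split(pos[keep],
                    factor(pick[keep], levels = seq_along(sd_ord)))
  n_tags <- lengths(assigned)
  ok <- which(n_tags >= min_tags)
  if (length(ok) == 0) return(empty)
  fuzz <- vapply(ok, function(i) fuzziness(assigned[[i]], sd_ord[i]),
                 numeric(1))
  data.frame(dyad = sd_ord[ok], n_tags = as.integer(n_tags[ok]),
             fuzziness = fuzz,
             start = sd_ord[ok] - footprint_half,
             end = sd_ord[ok] + footprint_half + 1L)
}

# per-bp kernel density-style signal over [lo, hi]; kernel truncated at 4 sigma
kernel_signal <- function(pos, lo, hi, sigma) {
  n <- hi - lo + 1L
  counts <- tabulate(pos - lo + 1L, nbins = n)
  half <- as.integer(ceiling(4 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  padded <- c(numeric(half), counts, numeric(half))
  sig <- stats::filter(padded, kern, sides = 2)
  as.numeric(sig[(half + 1L):(half + n)])
}

# greedy peak selection with a hard exclusion distance; candidates are
# strict local maxima of the smoothed signal (leftmost point of a plateau),
# taken by descending signal with lower-coordinate tie-break; a candidate
# strictly closer than `exclusion` to an accepted peak is suppressed.
# Returns 0-based offsets into the signal vector.
greedy_peaks <- function(signal, exclusion) {
  n <- length(signal)
  if (n == 0) return(integer(0))
  left <- c(-Inf, signal[-n])
  right <- c(signal[-1], -Inf)
  cand <- which(signal > 1e-8 & signal >= left & signal > right)
  ord <- cand[order(-signal[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0 || min(abs(accepted - i)) >= exclusion)
      accepted <- c(accepted, i)
  }
  sort(accepted) - 1L
}

#' Nucleosome fuzziness: RMS deviation of tag positions about the dyad
#'
#' @param positions Tag positions assigned to one nucleosome.
#' @param dyad The called dyad position.
#' @return Fuzziness in bp.
#' @export
fuzziness <- function(positions, dyad) {
  if (length(positions) == 0) stop("fuzziness undefined for zero tags")
  sqrt(mean((positions - dyad)^2))
}

#' Match common nucleosomes between two call sets
#'
#' Greedy one-to-one matching by ascending dyad distance, per chromosome.
#' Pairs at distance >= `max_dist` are excluded (strict "less than half a
#' nucleosome"); each call enters at most one pair.
#'
#' @param calls_a,calls_b Call tables from [call_nucleosomes()].
#' @param max_dist Maximum dyad distance in bp (exclusive).
#' @return data.frame with chrom, dyad_a, dyad_b, distance, fuzziness_a,
#'   fuzziness_b, n_tags_a, n_tags_b.
#' @export
match_common <- function(calls_a, calls_b, max_dist = 73L) {
  out <- list()
  for (chrom in intersect(unique(calls_a$chrom), unique(calls_b$chrom))) {
    a <- calls_a[calls_a$chrom == chrom, , drop = FALSE]
    b <- calls_b[calls_b$chrom == chrom, , drop = FALSE]
    cand <- which(abs(outer(a$dyad, b$dyad, "-")) < max_dist, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    d <- abs(a$dyad[cand[, 1]] - b$dyad[cand[, 2]])
    o <- order(d, a$dyad[cand[, 1]])
    used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
    rows <- list()
    for (k in o) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, dyad_a = a$dyad[i], dyad_b = b$dyad[j],
        distance = abs(a$dyad[i] - b$dyad[j]),
        fuzziness_a = a$fuzziness[i], fuzziness_b = b$fuzziness[j],
        n_tags_a = a$n_tags[i], n_tags_b = b$n_tags[j],
        stringsAsFactors = FALSE)
    }
    out[[chrom]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), dyad_a = integer(),
                      dyad_b = integer(), distance = integer(),
                      fuzziness_a = numeric(), fuzziness_b = numeric(),
                      n_tags_a = integer(), n_tags_b = integer())
  rownames(res) <- NULL
  res
}

#' Compare fuzziness of common nucleosomes between two samples
#'
#' Means are taken over paired calls only; the difference is assessed by a
#' two-tailed paired t-test on per-pair fuzziness differences.
#'
#' @param pairs Pair table from [match_common()].
#' @return List with mean_a, mean_b, mean_difference, t, df, p_value, n.
#' @export
compare_fuzziness <- function(pairs) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  diffs <- pairs$fuzziness_b - pairs$fuzziness_a
  if (stats::sd(diffs) == 0) {
    # degenerate paired test: a constant difference is either null (t = 0)
    # or detected with certainty
    tt <- list(statistic = c(t = if (mean(diffs) == 0) 0
                                 else Inf * sign(mean(diffs))),
               parameter = c(df = nrow(pairs) - 1),
               p.value = if (mean(diffs) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(pairs$fuzziness_b, pairs$fuzziness_a, paired = TRUE)
  }
  list(mean_a = mean(pairs$fuzziness_a), mean_b = mean(pairs$fuzziness_b),
       mean_difference = mean(diffs),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = nrow(pairs))
}
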