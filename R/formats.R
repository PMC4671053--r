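# I/O for the external formats the pipeline touches, plus the shared
# in-memory data model. Coordinates are 0-based half-open everywhere inside
# the package; 1-based formats (SAM/BAM, GTF) are converted on read.

#' Construct a genome index
#'
#' A genome index maps chromosome names to their lengths in bp. It is the
#' reference against which all reads, tags and intervals are validated.
#'
#' @param chrom_sizes Named integer/numeric vector: chromosome name -> length.
#' @return A named integer vector of class `genome_index`.
#' @export
genome_index <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be a named vector")
  if (anyDuplicated(names(chrom_sizes)))
    stop("chromosome names must be unique")
  sizes <- as.integer(round(chrom_sizes))
  if (any(sizes <= 0)) stop("all chromosome lengths must be > 0")
  names(sizes) <- names(chrom_sizes)
  structure(sizes, class = c("genome_index", "integer"))
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (name, length), no header.
#'
#' @param path Path to the chrom-sizes file.
#' @return A `genome_index`.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"))
  genome_index(stats::setNames(dt$size, dt$chrom))
}

new_reads <- function(chrom, start, end, strand) {
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

validate_reads <- function(reads, genome) {
  known <- reads$chrom %in% names(genome)
  n_unknown <- sum(!known)
  reads <- reads[known, , drop = FALSE]
  len <- unclass(genome)[reads$chrom]
  ok <- reads$start >= 0L & reads$start < reads$end & reads$end <= len
  n_oob <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  rownames(reads) <- NULL
  if (n_unknown + n_oob > 0)
    message(sprintf("dropped %d reads on unknown chromosomes, %d out of bounds",
                    n_unknown, n_oob))
  attr(reads, "n_dropped") <- c(unknown_chrom = n_unknown, out_of_bounds = n_oob)
  reads
}

#' Read aligned single-end reads
#'
#' Accepts BED6 (0-based half-open) or SAM/BAM (converted from 1-based on
#' read; strand from flag bit 0x10; aligned width from the CIGAR reference
#' span). Reads on chromosomes absent from `genome`, or extending beyond the
#' chromosome end, are dropped with a message; the counts are attached as the
#' `n_dropped` attribute.
#'
#' @param path Input file.
#' @param genome A `genome_index`.
#' @param format One of "auto", "bed", "sam", "bam". "auto" uses the file
#'   extension.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
read_alignments <- function(path, genome, format = c("auto", "bed", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot infer format from extension: ", ext))
  }
  if (format == "bed") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6) stop("BED6 requires 6 columns, found ", ncol(dt),
                           " in ", path)
    reads <- new_reads(dt[[1]], dt[[2]], dt[[3]], dt[[6]])
    if (!all(reads$strand %in% c("+", "-")))
      stop("invalid strand field in ", path)
  } else {
    bam <- path
    if (format == "sam") bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "cigar"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    rec <- Rsamtools::scanBam(bam, param = p)[[1]]
    width <- GenomicAlignments_width(rec$cigar)
    reads <- new_reads(as.character(rec$rname), rec$pos - 1L,
                       rec$pos - 1L + width, as.character(rec$strand))
  }
  validate_reads(reads, genome)
}

# reference span of a CIGAR string (M/D/N/=/X consume the reference)
GenomicAlignments_width <- function(cigar) {
  as.integer(vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE))
}

#' Read a gene annotation
#'
#' BED12 or GTF. Emits one gene model per transcript; for minus-strand
#' entries the TSS is the interval end. Duplicated gene_ids keep the first
#' record with a warning.
#'
#' @param path Annotation file.
#' @param format "auto" (by extension), "bed12" or "gtf".
#' @return data.frame with gene_id, chrom, strand, tss, tts, start, end
#'   (0-based half-open genic span).
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed12", gtf = "gtf",
                     stop("cannot infer annotation format: ", ext))
  }
  if (format == "bed12") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    g <- data.frame(gene_id = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
                    strand = as.character(dt[[6]]),
                    start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    tx <- gr[gr$type == "transcript"]
    if (length(tx) == 0) { # exon-only GTFs: aggregate per transcript_id
      ex <- gr[gr$type == "exon"]
      sp <- split(ex, ex$transcript_id)
      rng <- unlist(range(sp))
      tx <- rng
      tx$transcript_id <- names(rng)
    }
    ids <- if (!is.null(tx$transcript_id)) tx$transcript_id else tx$gene_id
    g <- data.frame(gene_id = as.character(ids),
                    chrom = as.character(GenomicRanges::seqnames(tx)),
                    strand = as.character(GenomicRanges::strand(tx)),
                    start = GenomicRanges::start(tx) - 1L,
                    end = GenomicRanges::end(tx),
                    stringsAsFactors = FALSE)
  }
  if (anyDuplicated(g$gene_id)) {
    warning("duplicate gene_id entries; keeping first occurrence")
    g <- g[!duplicated(g$gene_id), , drop = FALSE]
  }
  minus <- g$strand == "-"
  g$tss <- ifelse(minus, g$end, g$start)
  g$tts <- ifelse(minus, g$start, g$end)
  rownames(g) <- NULL
  g[, c("gene_id", "chrom", "strand", "tss", "tts", "start", "end")]
}

#' Write genes as BED12
#' @param genes Gene table from [read_gene_annotation()] or the simulator.
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  n <- nrow(genes)
  dt <- data.table::data.table(
    genes$chrom, genes$start, genes$end, genes$gene_id, 0L, genes$strand,
    genes$start, genes$end, "0,0,0", 1L,
    genes$end - genes$start, 0L)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write BED6 interval files
#'
#' `read_intervals` reads the first three (plus optional name/score/strand)
#' BED columns; `write_intervals` writes BED6 with placeholder name/score
#' columns when missing.
#'
#' @param path File path.
#' @return data.frame with chrom, start, end and any extra columns present.
#' @export
read_intervals <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  out <- data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) out$score <- dt[[5]]
  if (ncol(dt) >= 6) out$strand <- as.character(dt[[6]])
  if (any(out$start >= out$end)) stop("invalid interval (start >= end) in ", path)
  out
}

#' @rdname read_intervals
#' @param x Interval data.frame (chrom, start, end, optional name/score/strand).
#' @export
write_intervals <- function(x, path) {
  dt <- data.table::data.table(
    x$chrom, x$start, x$end,
    if (!is.null(x$name)) x$name else ".",
    if (!is.null(x$score)) x$score else 0L,
    if (!is.null(x$strand)) x$strand else "+")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write dyad tags as BED6 (1-bp intervals)
#' @param tags Tag data.frame (chrom, pos, strand).
#' @param path Output path.
#' @export
write_tags <- function(tags, path) {
  write_intervals(data.frame(chrom = tags$chrom, start = tags$pos,
                             end = tags$pos + 1L, name = ".", score = 0L,
                             strand = tags$strand), path)
}

#' Read dyad tags from BED6
#' @param path BED6 file of 1-bp tag intervals.
#' @return data.frame with chrom, pos, strand.
#' @export
read_tags <- function(path) {
  iv <- read_intervals(path)
  data.frame(chrom = iv$chrom, pos = iv$start, strand = iv$strand,
             stringsAsFactors = FALSE)
}

#' Write a binned track as bedGraph
#'
#' Lines are sorted by chromosome then start; values are printed at fixed
#' precision (`digits` significant digits) so that a write/read round trip is
#' bit-exact at that precision.
#'
#' @param track data.frame with chrom, start, end, value.
#' @param path Output path.
#' @param digits Significant digits for values.
#' @export
write_track <- function(track, path, digits = 10) {
  o <- order(track$chrom, track$start)
  track <- track[o, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   formatC(track$value, digits = digits, format = "g"))
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]), value = as.numeric(dt[[4]]),
             stringsAsFactors = FALSE)
}

# GRanges view of an interval data.frame (0-based half-open -> 1-based closed)
as_granges0 <- function(x, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (!is.null(strand)) strand else "*")
}
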