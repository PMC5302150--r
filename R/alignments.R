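#' Aligned-read input
#'
#' Genome-aligned reads come in as BED (3+ columns) or BAM. Both are reduced
#' to the same in-memory representation: an `AlignmentSet` holding one
#' sample's reads as 0-based half-open intervals, sorted by
#' `(chrom, start, end)` with a per-chromosome offset index for fast region
#' lookup. `total_reads` is the number of retained records and is the
#' normalization denominator downstream.
#'
#' @name alignments
NULL

new_alignment_set <- function(sample_id, reads, total_reads, sorted = FALSE) {
  reads <- data.table::as.data.table(reads)
  x <- structure(
    list(sample_id = sample_id, reads = reads,
         total_reads = as.integer(total_reads), index = NULL),
    class = "AlignmentSet"
  )
  if (sorted) x$index <- build_chrom_index(reads) else x <- sort_alignments(x)
  x
}

# chrom -> [from, to] row slice in the sorted read table
build_chrom_index <- function(reads) {
  if (!nrow(reads)) return(list())
  r <- rle(reads$chrom)
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1L
  stats::setNames(Map(c, from, to), r$values)
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat(sprintf("AlignmentSet '%s': %d reads on %d chromosome(s)\n",
              x$sample_id, x$total_reads, length(x$index)))
  invisible(x)
}

#' Sort an alignment set
#'
#' Orders reads by `(chrom, start, end)` using C-locale string comparison for
#' chromosome names; the sort is stable and idempotent. Also (re)builds the
#' per-chromosome offset index.
#'
#' @param x an `AlignmentSet`.
#' @return the sorted `AlignmentSet`.
#' @export
sort_alignments <- function(x) {
  stopifnot(inherits(x, "AlignmentSet"))
  o <- c_order(x$reads$chrom, x$reads$start, x$reads$end)
  x$reads <- x$reads[o]
  x$index <- build_chrom_index(x$reads)
  x
}

#' Read alignments from a BED file
#'
#' Accepts BED3+ (`chrom start end [name score strand]`); `#`, `track` and
#' `browser` lines are skipped. Records with an unknown strand symbol are
#' kept with strand `"+"` and a warning; `start >= end` is a parse error
#' naming the line. `total_reads` equals the number of data lines.
#'
#' @param path path to a BED or BED.gz file.
#' @param sample_id sample name; defaults to the file name without extension.
#' @return an `AlignmentSet` sorted by `(chrom, start, end)`.
#' @export
read_alignments_bed <- function(path, sample_id = NULL) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  if (is.null(sample_id)) sample_id <- strip_input_ext(basename(path))
  if (file.size(path) == 0) return(read_alignments_bed_empty(sample_id))
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                      blank.lines.skip = TRUE),
    error = function(e) parse_error(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e)))
  )
  if (!nrow(dt))
    return(new_alignment_set(sample_id,
                             data.table::data.table(chrom = character(),
                                                    start = integer(),
                                                    end = integer(),
                                                    strand = character()),
                             0L, sorted = TRUE))
  chrom1 <- as.character(dt[[1L]])
  skip <- grepl("^\\s*#", chrom1) | grepl("^(track|browser)\\b", chrom1)
  dt <- dt[!skip]
  if (!nrow(dt))
    return(read_alignments_bed_empty(sample_id))
  if (ncol(dt) < 3L) parse_error(sprintf("%s: BED needs >= 3 columns", path))
  start <- suppressWarnings(as.integer(dt[[2L]]))
  end <- suppressWarnings(as.integer(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    lineno <- which(!skip)[bad[1]]
    parse_error(sprintf("%s line %d: invalid interval (start must be 0 <= start < end)",
                        path, lineno))
  }
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else rep("+", nrow(dt))
  unknown <- !strand %in% c("+", "-")
  if (any(unknown)) {
    mp_warning("strand_warning", sprintf(
      "%s: %d record(s) with unknown strand symbol treated as '+'",
      path, sum(unknown)))
    strand[unknown] <- "+"
  }
  reads <- data.table::data.table(chrom = as.character(dt[[1L]]),
                                  start = start, end = end, strand = strand)
  new_alignment_set(sample_id, reads, nrow(reads))
}

read_alignments_bed_empty <- function(sample_id) {
  new_alignment_set(sample_id,
                    data.table::data.table(chrom = character(), start = integer(),
                                           end = integer(), strand = character()),
                    0L, sorted = TRUE)
}

#' Read alignments from a BAM file
#'
#' Unmapped, secondary and supplementary records are excluded and do not
#' count toward `total_reads`; duplicates are kept and paired-end mates are
#' treated as independent reads. Each retained record becomes the 0-based
#' half-open interval of its reference-consumed span (CIGAR-aware).
#'
#' @inheritParams read_alignments_bed
#' @return an `AlignmentSet` sorted by `(chrom, start, end)`.
#' @export
read_alignments_bam <- function(path, sample_id = NULL) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  if (is.null(sample_id)) sample_id <- strip_input_ext(basename(path))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  ga <- tryCatch(
    GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(flag = flag)),
    error = function(e) input_error(sprintf("cannot read BAM %s: %s", path,
                                            conditionMessage(e)))
  )
  df <- as.data.frame(ga)
  reads <- data.table::data.table(
    chrom = as.character(df$seqnames),
    start = df$start - 1L,  # 1-based closed -> 0-based half-open
    end = df$end,
    strand = as.character(df$strand)
  )
  reads$strand[!reads$strand %in% c("+", "-")] <- "+"
  new_alignment_set(sample_id, reads, nrow(reads))
}

#' Write an alignment set as BED6
#' @param x an `AlignmentSet`.
#' @param path output path.
#' @export
write_alignments_bed <- function(x, path) {
  stopifnot(inherits(x, "AlignmentSet"))
  r <- x$reads
  lines <- sprintf("%s\t%d\t%d\tr%d\t0\t%s", r$chrom, r$start, r$end,
                   seq_len(nrow(r)), r$strand)
  write_lines_atomic(lines, path)
}

#' Read alignments, inferring the format from the file extension
#'
#' `.bam` dispatches to [read_alignments_bam()], `.bed`/`.bed.gz` to
#' [read_alignments_bed()]; `format` overrides the inference.
#'
#' @inheritParams read_alignments_bed
#' @param format `"auto"`, `"bed"` or `"bam"`.
#' @export
read_alignments <- function(path, sample_id = NULL, format = c("auto", "bed", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  switch(format,
         bam = read_alignments_bam(path, sample_id),
         bed = read_alignments_bed(path, sample_id))
}

strip_input_ext <- function(x) sub("\\.(bed|bam|tsv|txt)(\\.gz)?$", "", x,
                                   ignore.case = TRUE)

# Warn when annotation and alignment chromosome names are disjoint --
# the classic silent-zero-counts failure mode.
check_chrom_overlap <- function(aln, annot_chroms) {
  if (length(aln$index) && length(annot_chroms) &&
      !any(names(aln$index) %in% annot_chroms)) {
    mp_warning("chrom_mismatch", sprintf(
      "sample '%s': no chromosome name shared between alignments (%s...) and annotation (%s...)",
      aln$sample_id, names(aln$index)[1], annot_chroms[1]))
  }
  invisible(NULL)
}
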