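#' Promoter and transcript annotation
#'
#' The quantification targets of every pipeline are defined by three small
#' user-supplied tables: a promoter BED file, a transcript exon table and a
#' transcript-to-promoter association table. All genomic coordinates are
#' 0-based half-open (BED convention). A promoter's `anchor` is the floor of
#' the midpoint of its BED interval and is the point around which ChIP-seq
#' counting windows are centered.
#'
#' @name annotation
NULL

new_promoter_set <- function(promoter_id, chrom, anchor, strand, assembly) {
  check_assembly(assembly)
  if (anyDuplicated(promoter_id))
    validation_error(sprintf(
      "duplicate promoter_id: %s",
      paste(unique(promoter_id[duplicated(promoter_id)]), collapse = ", ")
    ))
  if (length(anchor) && any(anchor < 0)) validation_error("promoter anchor must be >= 0")
  if (length(chrom) && any(!nzchar(chrom))) validation_error("empty chromosome name")
  if (length(strand) && !all(strand %in% c("+", "-")))
    validation_error("promoter strand must be '+' or '-'")
  structure(
    data.frame(
      promoter_id = as.character(promoter_id),
      chrom = as.character(chrom),
      anchor = as.integer(anchor),
      strand = as.character(strand),
      stringsAsFactors = FALSE
    ),
    assembly = assembly,
    class = c("PromoterSet", "data.frame")
  )
}

#' Read a promoter set from a BED-like file
#'
#' Expects at least 4 tab-separated columns per data line
#' (`chrom start end name [score] [strand]`); `#`-comment and blank lines are
#' skipped. The promoter anchor is `floor((start+end)/2)`; strand defaults to
#' `"+"` when the file has fewer than 6 columns. Input row order is preserved
#' and defines the row order of every downstream matrix.
#'
#' @param path path to the BED(.gz) file.
#' @param assembly genome assembly label, one of `"hg18"`, `"hg19"`, `"mm9"`.
#' @return a `PromoterSet`: a data.frame with columns `promoter_id`, `chrom`,
#'   `anchor`, `strand` and an `assembly` attribute.
#' @export
read_promoters <- function(path, assembly = "hg19") {
  check_assembly(assembly)
  lines <- read_text_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^(track|browser)\\b", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(new_promoter_set(character(), character(), integer(), character(), assembly))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    parse_error(sprintf("line %d: expected >= 4 tab-separated columns, got %d",
                        lineno[which(nf < 4L)[1]], nf[which(nf < 4L)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    parse_error(sprintf("line %d: non-numeric start/end", lineno[bad[1]]))
  bad <- which(start < 0 | end <= start)
  if (length(bad))
    parse_error(sprintf("line %d: invalid interval [%s, %s)",
                        lineno[bad[1]], start[bad[1]], end[bad[1]]))
  strand <- rep("+", length(fields))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  unknown <- which(!strand %in% c("+", "-"))
  if (length(unknown)) {
    mp_warning("strand_warning", sprintf(
      "%d promoter line(s) with unknown strand symbol treated as '+' (first: line %d)",
      length(unknown), lineno[unknown[1]]
    ))
    strand[unknown] <- "+"
  }
  anchor <- floor((start + end) / 2)
  new_promoter_set(name, chrom, anchor, strand, assembly)
}

#' Write a promoter set as BED6
#'
#' Inverse of [read_promoters()]: writes each promoter as a width-1 interval
#' `[anchor, anchor+1)` so that re-reading recovers the identical anchor.
#'
#' @param promoters a `PromoterSet`.
#' @param path output path.
#' @export
write_promoters <- function(promoters, path) {
  stopifnot(inherits(promoters, "PromoterSet"))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   promoters$chrom, promoters$anchor, promoters$anchor + 1L,
                   promoters$promoter_id, promoters$strand)
  write_lines_atomic(lines, path)
}

#' Read transcript models from an exon table
#'
#' The file is a TSV with header `transcript_id chrom start end strand`, one
#' exon per row, 0-based half-open coordinates. Exons of one transcript must
#' lie on a single chromosome and strand; they are sorted, abutting exons are
#' merged, and overlapping exons are rejected (overlap would double-count
#' transcript length). Transcript length is the sum of exon widths.
#'
#' @param path path to the exon TSV(.gz).
#' @return a `TranscriptSet`: list with `exons` (data.table of merged exons)
#'   and `transcripts` (data.table `transcript_id`, `chrom`, `strand`,
#'   `length`, `n_exons`).
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("transcript_id", "chrom", "strand"), integer = c("start", "end")
  ))
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(dt)))
    parse_error(sprintf("transcript table must have columns: %s", paste(need, collapse = ", ")))
  dt <- dt[, need, with = FALSE]
  bad <- which(dt$start >= dt$end | dt$start < 0)
  if (length(bad))
    parse_error(sprintf("exon row %d: invalid interval [%d, %d)",
                        bad[1], dt$start[bad[1]], dt$end[bad[1]]))
  if (!all(dt$strand %in% c("+", "-")))
    parse_error("transcript strand must be '+' or '-'")
  build_transcript_set(dt)
}

# Shared constructor: group exons, sort, merge abutting, reject overlap.
build_transcript_set <- function(exons) {
  exons <- data.table::as.data.table(exons)
  start <- end <- transcript_id <- chrom <- strand <- NULL # NSE note for R CMD check
  multi <- exons[, list(nc = data.table::uniqueN(chrom), ns = data.table::uniqueN(strand)),
                 by = transcript_id]
  bad <- multi[multi$nc > 1L | multi$ns > 1L]
  if (nrow(bad))
    validation_error(sprintf("transcript %s spans multiple chromosomes or strands",
                             bad$transcript_id[1]))
  data.table::setorderv(exons, c("transcript_id", "start", "end"))
  # overlap check then merge abutting (end == next start) runs per transcript
  merged <- exons[, {
    s <- start; e <- end
    if (.N > 1L && any(s[-1L] < e[-.N]))
      validation_error(sprintf("overlapping exons in transcript %s", .BY[[1L]]))
    keep_s <- s; keep_e <- e
    if (.N > 1L) {
      grp <- cumsum(c(TRUE, s[-1L] > e[-.N]))
      keep_s <- tapply(s, grp, min)
      keep_e <- tapply(e, grp, max)
    }
    list(chrom = chrom[1L], start = as.integer(keep_s),
         end = as.integer(keep_e), strand = strand[1L])
  }, by = transcript_id]
  transcripts <- merged[, list(
    chrom = chrom[1L], strand = strand[1L],
    length = sum(end - start), n_exons = .N
  ), by = transcript_id]
  structure(list(exons = merged[], transcripts = transcripts[]),
            class = "TranscriptSet")
}

#' Write a transcript exon table
#' @param transcripts a `TranscriptSet`.
#' @param path output path.
#' @export
write_transcripts <- function(transcripts, path) {
  stopifnot(inherits(transcripts, "TranscriptSet"))
  ex <- transcripts$exons
  lines <- c("transcript_id\tchrom\tstart\tend\tstrand",
             sprintf("%s\t%s\t%d\t%d\t%s", ex$transcript_id, ex$chrom,
                     ex$start, ex$end, ex$strand))
  write_lines_atomic(lines, path)
}

#' Read transcript-to-promoter associations
#'
#' TSV with header `transcript_id promoter_id`. Many transcripts may map to
#' one promoter; a transcript may map to only one promoter (a transcript
#' listed twice is a validation error). When `promoters` and/or
#' `transcripts` are supplied, every referenced id is checked against them.
#'
#' @param path path to the association TSV(.gz).
#' @param promoters optional `PromoterSet` to validate `promoter_id` against.
#' @param transcripts optional `TranscriptSet` to validate `transcript_id`
#'   against.
#' @return an `AssociationTable`: data.frame `transcript_id`, `promoter_id`.
#' @export
read_associations <- function(path, promoters = NULL, transcripts = NULL) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("transcript_id", "promoter_id")
  if (!all(need %in% names(dt)))
    parse_error("association table must have columns: transcript_id, promoter_id")
  assoc <- as.data.frame(dt[, need, with = FALSE])
  new_association_table(assoc, promoters, transcripts)
}

new_association_table <- function(assoc, promoters = NULL, transcripts = NULL) {
  dup <- assoc$transcript_id[duplicated(assoc$transcript_id)]
  if (length(dup))
    validation_error(sprintf("transcript %s associated with more than one promoter",
                             dup[1]))
  if (!is.null(promoters)) {
    missing <- setdiff(assoc$promoter_id, promoters$promoter_id)
    if (length(missing))
      validation_error(sprintf("association references unknown promoter(s): %s",
                               paste(utils::head(missing, 3), collapse = ", ")))
  }
  if (!is.null(transcripts)) {
    missing <- setdiff(assoc$transcript_id, transcripts$transcripts$transcript_id)
    if (length(missing))
      validation_error(sprintf("association references unknown transcript(s): %s",
                               paste(utils::head(missing, 3), collapse = ", ")))
  }
  structure(assoc, class = c("AssociationTable", "data.frame"))
}

#' Write a transcript-to-promoter association table
#' @param assoc an `AssociationTable`.
#' @param path output path.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "AssociationTable"))
  lines <- c("transcript_id\tpromoter_id",
             sprintf("%s\t%s", assoc$transcript_id, assoc$promoter_id))
  write_lines_atomic(lines, path)
}
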