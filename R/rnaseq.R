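#' RNA-seq chain: transcript assignment and promoter expression
#'
#' Genome-aligned RNA-seq reads are assigned to the transcript set by exon
#' overlap: a read is compatible with a transcript when it overlaps any of
#' its exons by at least 1 bp on the same chromosome. A read compatible with
#' `k >= 1` transcripts contributes `1/k` to each (deterministic,
#' mass-conserving; no EM rescue). Transcript counts are then length- and
#' depth-normalized (RPKM by default), summed over each promoter's
#' transcripts, and log2-transformed.
#'
#' @name rnaseq
NULL

#' Assign reads to transcripts by exon overlap
#'
#' @param reads an `AlignmentSet`.
#' @param transcripts a `TranscriptSet`.
#' @param stranded `"none"` (default: ignore strand), `"forward"` (read
#'   strand must match the transcript) or `"reverse"` (must be opposite).
#' @return a `TranscriptCounts`: named numeric vector of fractional counts
#'   over all transcripts (zeros included), with attributes `library_size`
#'   (total retained reads) and `n_assigned` (reads compatible with >= 1
#'   transcript).
#' @export
assign_reads <- function(reads, transcripts,
                         stranded = c("none", "forward", "reverse")) {
  stopifnot(inherits(reads, "AlignmentSet"), inherits(transcripts, "TranscriptSet"))
  stranded <- match.arg(stranded)
  ex <- transcripts$exons
  tx_ids <- transcripts$transcripts$transcript_id
  check_chrom_overlap(reads, unique(ex$chrom))
  r <- reads$reads
  counts <- stats::setNames(numeric(length(tx_ids)), tx_ids)
  n_assigned <- 0L
  if (nrow(r) && nrow(ex)) {
    rd_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
    ex_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
    hits <- GenomicRanges::findOverlaps(rd_gr, ex_gr, minoverlap = 1L,
                                        ignore.strand = TRUE)
    pair <- data.table::data.table(
      read = S4Vectors::queryHits(hits),
      tx = ex$transcript_id[S4Vectors::subjectHits(hits)]
    )
    if (stranded != "none" && nrow(pair)) {
      tx_strand <- stats::setNames(transcripts$transcripts$strand, tx_ids)
      same <- r$strand[pair$read] == tx_strand[pair$tx]
      pair <- pair[if (stranded == "forward") same else !same]
    }
    pair <- unique(pair)                       # one vote per (read, transcript)
    if (nrow(pair)) {
      read <- tx <- w <- NULL
      pair[, w := 1 / .N, by = read]
      agg <- pair[, list(count = sum(w)), by = tx]
      counts[agg$tx] <- agg$count
      n_assigned <- length(unique(pair$read))
    }
  }
  structure(counts, library_size = reads$total_reads,
            n_assigned = as.integer(n_assigned),
            class = c("TranscriptCounts", "numeric"))
}

#' Promoter expression from transcript counts
#'
#' Per transcript `t`: `rpkm_t = count_t * 1e9 / (length_t * library_size)`
#' (or TPM when `norm = "tpm"`). Per promoter `p`, expression is the sum of
#' the normalized values of its associated transcripts, and the reported
#' value is `log2(E_p + pseudocount)`. Promoters with no counted transcript
#' report `log2(pseudocount)`. Counted transcripts absent from the
#' association table are dropped with a warning.
#'
#' @param counts a `TranscriptCounts` from [assign_reads()].
#' @param assoc an `AssociationTable`.
#' @param transcripts a `TranscriptSet` (provides transcript lengths).
#' @param promoters a `PromoterSet` (defines output order).
#' @param pseudocount added inside the log; default 0.5.
#' @param norm `"rpkm"` (default) or `"tpm"`.
#' @return named numeric vector of log2 expression, one value per promoter,
#'   in promoter-set order.
#' @export
promoter_expression <- function(counts, assoc, transcripts, promoters,
                                pseudocount = 0.5, norm = c("rpkm", "tpm")) {
  norm <- match.arg(norm)
  lib <- attr(counts, "library_size")
  if (is.null(lib) || lib == 0L)
    processing_error("library size is zero; cannot normalize expression")
  len <- stats::setNames(transcripts$transcripts$length,
                         transcripts$transcripts$transcript_id)
  cn <- names(counts)
  unknown_len <- setdiff(cn, names(len))
  if (length(unknown_len))
    validation_error(sprintf("no transcript length for: %s",
                             paste(utils::head(unknown_len, 3), collapse = ", ")))
  orphan <- setdiff(cn[counts > 0], assoc$transcript_id)
  if (length(orphan))
    mp_warning("orphan_transcripts", sprintf(
      "%d counted transcript(s) have no promoter association and were dropped (first: %s)",
      length(orphan), orphan[1]))
  rate <- counts / len[cn]                      # reads per bp
  expr_t <- switch(norm,
    rpkm = counts * 1e9 / (len[cn] * lib),
    tpm = if (sum(rate) > 0) rate * 1e6 / sum(rate) else rate
  )
  p2t <- stats::setNames(assoc$promoter_id, assoc$transcript_id)
  keep <- cn %in% assoc$transcript_id
  e_p <- tapply(expr_t[keep], p2t[cn[keep]], sum)
  out <- stats::setNames(numeric(nrow(promoters)), promoters$promoter_id)
  hit <- intersect(names(e_p), names(out))
  out[hit] <- e_p[hit]
  log2(out + pseudocount)
}

#' Run the full RNA-seq chain on a set of alignment files
#'
#' @param inputs character vector of BED/BAM paths (one sample each).
#' @param promoters a `PromoterSet`.
#' @param transcripts a `TranscriptSet`.
#' @param assoc an `AssociationTable`.
#' @param pseudocount pseudocount inside the log (default 0.5).
#' @param norm `"rpkm"` or `"tpm"`.
#' @param stranded strandedness of read assignment, see [assign_reads()].
#' @param workers number of parallel workers (default 1).
#' @return a `SummaryMatrix` of promoter log2 expression.
#' @export
process_rnaseq <- function(inputs, promoters, transcripts, assoc,
                           pseudocount = 0.5, norm = "rpkm",
                           stranded = "none", workers = 1L) {
  new_association_table(assoc, promoters, transcripts)  # validate consistency
  cols <- run_parallel(inputs, workers, function(path) {
    aln <- read_alignments(path)
    if (aln$total_reads == 0L) {
      mp_warning("empty_sample", sprintf("sample '%s' has no reads", aln$sample_id))
      col <- stats::setNames(rep(log2(pseudocount), nrow(promoters)),
                             promoters$promoter_id)
      return(list(id = aln$sample_id, col = col))
    }
    tc <- assign_reads(aln, transcripts, stranded = stranded)
    list(id = aln$sample_id,
         col = promoter_expression(tc, assoc, transcripts, promoters,
                                   pseudocount = pseudocount, norm = norm))
  })
  m <- do.call(cbind, lapply(cols, `[[`, "col"))
  colnames(m) <- vapply(cols, `[[`, "", "id")
  if (anyDuplicated(colnames(m))) validation_error("duplicate sample_id among inputs")
  summary_matrix(m, meta = list(
    data_type = "rnaseq", assembly = attr(promoters, "assembly"),
    pseudocount = pseudocount, normalization = paste0("log2-", norm),
    stranded = stranded))
}
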