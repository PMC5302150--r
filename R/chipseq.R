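#' ChIP-seq chain: promoter-window counting
#'
#' ChIP-seq samples are summarized by counting, for every promoter, the reads
#' overlapping a fixed-width window (default 2 kb) centered on the promoter
#' anchor, then converting counts to log2 counts-per-million with a
#' pseudocount. Strand is ignored: ChIP fragments are strand-symmetric
#' around binding sites.
#'
#' @name chipseq
NULL

#' Build promoter-centered counting windows
#'
#' For anchor `a` and even width `w`, the window is
#' `[max(0, a - w/2), a + w/2)` on the promoter's chromosome, clamped at the
#' chromosome start; one window per promoter, in promoter-set order.
#'
#' @param promoters a `PromoterSet`.
#' @param width window width in bp; must be even and >= 2. Default 2000.
#' @return data.frame `chrom`, `start`, `end`, `promoter_id`.
#' @export
make_windows <- function(promoters, width = 2000L) {
  stopifnot(inherits(promoters, "PromoterSet"))
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 2L || width %% 2L != 0L)
    config_error(sprintf("window width must be an even integer >= 2 (got %s)", width))
  half <- width %/% 2L
  data.frame(
    chrom = promoters$chrom,
    start = pmax(0L, promoters$anchor - half),
    end = promoters$anchor + half,
    promoter_id = promoters$promoter_id,
    stringsAsFactors = FALSE
  )
}

#' Count reads in promoter windows
#'
#' Counting modes:
#' * `"overlap"` (default): a read increments every window it overlaps by at
#'   least 1 bp, so one read may count toward several overlapping windows.
#' * `"midpoint"`: a read counts for the windows containing its midpoint
#'   `floor((start+end)/2)`.
#' * `"five_prime"`: a read counts for the windows containing its 5' end
#'   (`start` on `+`, `end - 1` on `-`).
#'
#' @param reads an `AlignmentSet`.
#' @param windows windows from [make_windows()] (may overlap each other).
#' @param mode overlap rule, see Details.
#' @return integer vector of counts, one per window, named by `promoter_id`.
#' @export
count_in_windows <- function(reads, windows,
                             mode = c("overlap", "midpoint", "five_prime")) {
  stopifnot(inherits(reads, "AlignmentSet"))
  mode <- match.arg(mode)
  check_chrom_overlap(reads, unique(windows$chrom))
  r <- reads$reads
  if (nrow(r)) {
    pos <- switch(mode,
      overlap = NULL,
      midpoint = as.integer(floor((r$start + r$end) / 2)),
      five_prime = ifelse(r$strand == "-", r$end - 1L, r$start)
    )
    if (!is.null(pos)) {
      rd_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(pos + 1L, width = 1L))
    } else {
      rd_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
    }
  } else {
    rd_gr <- GenomicRanges::GRanges()
  }
  win_gr <- GenomicRanges::GRanges(windows$chrom,
                                   IRanges::IRanges(windows$start + 1L, windows$end))
  n <- GenomicRanges::countOverlaps(win_gr, rd_gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  stats::setNames(as.integer(n), windows$promoter_id)
}

#' Assemble a promoter-by-sample count matrix
#'
#' @param samples list of `AlignmentSet`, one per sample; column order
#'   follows the list order.
#' @param windows windows from [make_windows()].
#' @param mode passed to [count_in_windows()].
#' @return a `CountMatrix`: integer matrix (promoters x samples) with a
#'   `library_size` attribute (per-sample `total_reads`).
#' @export
count_matrix <- function(samples, windows, mode = "overlap") {
  stopifnot(length(samples) > 0L)
  cols <- lapply(samples, count_in_windows, windows = windows, mode = mode)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(samples, function(s) s$sample_id, "")
  if (anyDuplicated(colnames(m)))
    validation_error("duplicate sample_id among inputs")
  structure(m,
            library_size = stats::setNames(
              vapply(samples, function(s) s$total_reads, 0L), colnames(m)),
            class = c("CountMatrix", class(m)))
}

#' Normalize counts to log2 counts-per-million
#'
#' Each entry becomes `log2(count * 1e6 / library_size + pseudocount)` where
#' `library_size` is the sample's total retained reads. A zero count maps to
#' `log2(pseudocount)` exactly; scaling counts and library size together
#' leaves the output unchanged.
#'
#' @param counts a `CountMatrix` from [count_matrix()].
#' @param pseudocount added inside the log; default 0.5.
#' @param meta optional named list merged into the summary metadata.
#' @return a `SummaryMatrix` (see [summary_matrix()]).
#' @export
normalize_log <- function(counts, pseudocount = 0.5, meta = list()) {
  lib <- attr(counts, "library_size")
  if (is.null(lib)) validation_error("counts must carry a library_size attribute")
  zero <- names(lib)[lib == 0L]
  if (length(zero))
    processing_error(sprintf("library size is zero for sample(s): %s",
                             paste(zero, collapse = ", ")))
  if (any(counts < 0)) validation_error("negative counts")
  m <- unclass(counts)
  attr(m, "library_size") <- NULL
  cpm <- sweep(m, 2L, lib / 1e6, "/")
  vals <- log2(cpm + pseudocount)
  summary_matrix(vals, meta = utils::modifyList(
    list(data_type = "chipseq", pseudocount = pseudocount,
         normalization = "log2-cpm"), meta))
}

#' Run the full ChIP-seq chain on a set of alignment files
#'
#' Reads each input (BED/BAM), counts reads in promoter windows, and returns
#' the normalized log2-CPM summary matrix. Input files are processed
#' independently, optionally in parallel; the result is identical for any
#' worker count.
#'
#' @param inputs character vector of BED/BAM paths.
#' @param promoters a `PromoterSet`.
#' @param window window width in bp (default 2000).
#' @param pseudocount pseudocount for [normalize_log()].
#' @param mode counting mode, see [count_in_windows()].
#' @param workers number of parallel workers (forked; default 1).
#' @return a `SummaryMatrix`.
#' @export
process_chipseq <- function(inputs, promoters, window = 2000L, pseudocount = 0.5,
                            mode = "overlap", workers = 1L) {
  windows <- make_windows(promoters, window)
  samples <- run_parallel(inputs, workers, function(path) {
    read_alignments(path)
  })
  counts <- count_matrix(samples, windows, mode = mode)
  # an empty sample cannot be CPM-normalized; its column is the pseudocount
  # floor and the run carries on with a warning
  lib <- attr(counts, "library_size")
  empty <- names(lib)[lib == 0L]
  if (length(empty)) {
    mp_warning("empty_sample", sprintf("sample(s) with no reads: %s",
                                       paste(empty, collapse = ", ")))
    attr(counts, "library_size")[empty] <- 1L
  }
  sm <- normalize_log(counts, pseudocount,
                      meta = list(assembly = attr(promoters, "assembly"),
                                  window = as.integer(window), count_mode = mode))
  sm$values[, empty] <- log2(pseudocount)
  sm
}

# mclapply with deterministic ordering and error propagation; falls back to
# lapply for a single worker (and on Windows, where forking is unavailable).
run_parallel <- function(xs, workers, fn) {
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || .Platform$OS.type == "windows" || length(xs) <= 1L) {
    res <- lapply(xs, fn)
  } else {
    res <- parallel::mclapply(xs, fn, mc.cores = workers, mc.preschedule = TRUE)
    err <- vapply(res, inherits, TRUE, what = "try-error")
    if (any(err)) stop(attr(res[[which(err)[1]]], "condition"))
  }
  res
}
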