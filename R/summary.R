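#' The summary matrix: the upload payload
#'
#' Every pipeline ends in a `SummaryMatrix`: a small promoter- (or probe-)
#' by-sample matrix of normalized log2 expression, serialized as a
#' tab-delimited text file a few MB in size regardless of the raw input
#' size. The on-disk dialect is fixed so that reruns are byte-identical:
#' leading `#key=value` metadata lines (keys sorted), a header line
#' `id<TAB>sample...`, then one row per id with values printed to 6
#' significant digits with `.` as the decimal separator and `\n` endings.
#'
#' @name summary-format
NULL

#' Construct a summary matrix
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); all entries must be finite.
#' @param meta named list of metadata (`data_type`, `assembly`, pipeline
#'   parameters); written as `#key=value` header lines.
#' @return a `SummaryMatrix`.
#' @export
summary_matrix <- function(values, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    validation_error("summary values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    validation_error("summary matrix needs row and column names")
  if (anyDuplicated(rownames(values))) validation_error("duplicate row ids")
  if (anyDuplicated(colnames(values))) validation_error("duplicate sample ids")
  if (any(!is.finite(values)))
    validation_error("summary matrix contains non-finite values")
  structure(list(values = values, meta = meta), class = "SummaryMatrix")
}

#' @export
print.SummaryMatrix <- function(x, ...) {
  cat(sprintf("SummaryMatrix: %d feature(s) x %d sample(s)%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$meta$data_type)) paste0(" [", x$meta$data_type, "]") else ""))
  invisible(x)
}

#' @export
dim.SummaryMatrix <- function(x) dim(x$values)

#' Write a summary matrix to a tab-delimited file
#'
#' Byte-deterministic: equal matrices produce byte-identical files. Values
#' are formatted with 6 significant digits (trailing zeros kept).
#'
#' @param m a `SummaryMatrix`.
#' @param path output path; written atomically.
#' @param gzip compress the output with gzip.
#' @return the path, invisibly.
#' @export
write_summary <- function(m, path, gzip = FALSE) {
  stopifnot(inherits(m, "SummaryMatrix"))
  meta <- m$meta
  meta_lines <- character()
  if (length(meta)) {
    keys <- sort(names(meta))
    meta_lines <- sprintf("#%s=%s", keys,
                          vapply(meta[keys], function(v) paste(format(v, scientific = FALSE), collapse = ","), ""))
  }
  header <- paste(c("id", colnames(m$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(m$values)), function(i) {
    paste(c(rownames(m$values)[i], format_sig6(m$values[i, ])), collapse = "\t")
  }, "")
  write_lines_atomic(c(meta_lines, header, body), path, gzip = gzip)
  invisible(path)
}

#' Read a summary matrix written by [write_summary()]
#'
#' Inverse of [write_summary()] up to the 6-significant-digit formatting.
#' Ragged rows, duplicate ids and non-numeric cells are parse errors naming
#' the offending line.
#'
#' @param path path to a summary TSV (optionally gzipped).
#' @return a `SummaryMatrix`.
#' @export
read_summary <- function(path) {
  lines <- read_text_lines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  if (any(is_meta)) {
    kv <- sub("^#", "", lines[is_meta])
    eq <- regexpr("=", kv, fixed = TRUE)
    keys <- substr(kv, 1L, eq - 1L)
    vals <- substring(kv, eq + 1L)
    meta <- stats::setNames(as.list(vals), keys)
    num <- suppressWarnings(as.numeric(vals))
    meta[!is.na(num)] <- as.list(num[!is.na(num)])
  }
  data_lines <- lines[!is_meta]
  data_idx <- which(!is_meta)
  if (!length(data_lines)) parse_error(sprintf("%s: no header line", path))
  header <- strsplit(data_lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "id")
    parse_error(sprintf("%s line %d: header must start with 'id'", path, data_idx[1L]))
  samples <- header[-1L]
  rows <- strsplit(data_lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != length(header))
  if (length(bad))
    parse_error(sprintf("%s line %d: expected %d fields, got %d",
                        path, data_idx[-1L][bad[1L]], length(header), nf[bad[1L]]))
  ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(ids))
    parse_error(sprintf("%s: duplicate row id '%s'", path, ids[duplicated(ids)][1L]))
  vals <- suppressWarnings(
    vapply(rows, function(f) as.numeric(f[-1L]), numeric(length(samples)))
  )
  vals <- matrix(vals, ncol = length(samples), byrow = TRUE,
                 dimnames = list(ids, samples))
  nabad <- which(apply(is.na(vals), 1L, any))
  if (length(nabad))
    parse_error(sprintf("%s line %d: non-numeric value", path, data_idx[-1L][nabad[1L]]))
  summary_matrix(vals, meta = meta)
}
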