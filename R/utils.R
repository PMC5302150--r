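# Internal helpers: classed conditions, deterministic formatting, atomic IO.

mp_error <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("maraprep_", class), "maraprep_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  ))
}

mp_warning <- function(class, msg) {
  warning(structure(
    class = c(paste0("maraprep_", class), "maraprep_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' @noRd
parse_error <- function(msg) mp_error("parse_error", msg)
validation_error <- function(msg) mp_error("validation_error", msg)
config_error <- function(msg) mp_error("config_error", msg)
processing_error <- function(msg) mp_error("processing_error", msg)
submission_error <- function(msg) mp_error("submission_error", msg)
input_error <- function(msg) mp_error("input_error", msg)

SUPPORTED_ASSEMBLIES <- c("hg18", "hg19", "mm9")

check_assembly <- function(assembly) {
  if (length(assembly) != 1L || !assembly %in% SUPPORTED_ASSEMBLIES)
    config_error(sprintf(
      "assembly must be one of %s (got '%s')",
      paste(SUPPORTED_ASSEMBLIES, collapse = ", "), paste(assembly, collapse = ",")
    ))
  assembly
}

# 6 significant digits, trailing zeros kept, '.' decimal separator --
# the fixed on-disk number dialect of summary files.
format_sig6 <- function(x) sprintf("%#.6g", x)

# Write lines with '\n' endings regardless of platform, atomically:
# write to a temp file in the same directory, then rename.
write_lines_atomic <- function(lines, path, gzip = FALSE) {
  dir <- dirname(path)
  if (!dir.exists(dir)) input_error(sprintf("directory does not exist: %s", dir))
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- if (gzip) gzfile(tmp, "wb") else file(tmp, "wb")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con = con, sep = "\n")
    close(con)
    ok <- TRUE
  }, error = function(e) {
    try(close(con), silent = TRUE)
    unlink(tmp)
    mp_error("io_error", sprintf("cannot write %s: %s", path, conditionMessage(e)))
  })
  if (ok && !file.rename(tmp, path)) {
    unlink(tmp)
    mp_error("io_error", sprintf("cannot move temporary file onto %s", path))
  }
  invisible(path)
}

# C-locale lexicographic string order, stable; used everywhere chromosome
# names are compared so sorting is deterministic across locales.
c_order <- function(...) order(..., method = "radix")

is_gz <- function(path) grepl("\\.gz$", path)

read_text_lines <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  con <- if (is_gz(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
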