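#' Job lifecycle and submission
#'
#' Processing and submission requests are tracked as jobs with states
#' `created -> processing -> processed -> uploading -> submitted`; any state
#' may fall to `failed`, and a failed submission may be retried
#' (`failed -> uploading`) as long as the processed summary file exists.
#' `download_url` is non-empty exactly when a job is `submitted`. The store
#' is a single local TSV, one record per line, rewritten atomically
#' (write-temp-then-rename) on every transition so a crash never leaves a
#' partial record. Every stage transition and warning is appended to the
#' job's log file.
#'
#' @name client
NULL

JOB_STATES <- c("created", "processing", "processed", "uploading",
                "submitted", "failed")

# allowed edges; "failed -> uploading" is the documented retry edge,
# permitted only when the job already has a summary file
JOB_EDGES <- list(
  created = "processing",
  processing = c("processed", "failed"),
  processed = c("uploading", "failed"),
  uploading = c("submitted", "failed"),
  failed = "uploading",
  submitted = character()
)

#' Open (or create) a job store
#'
#' @param path path of the store TSV; created on first use.
#' @param scratch directory for summaries, logs and temporaries; defaults to
#'   a `scratch` directory next to the store (relocatable to an external
#'   drive).
#' @return a `JobStore`.
#' @export
job_store <- function(path, scratch = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (is.null(scratch)) scratch <- file.path(dirname(path), "scratch")
  dir.create(scratch, showWarnings = FALSE, recursive = TRUE)
  structure(list(path = path, scratch = scratch), class = "JobStore")
}

JOB_FIELDS <- c("job_id", "project", "email", "data_type", "assembly",
                "state", "download_url", "created_at", "updated_at",
                "log_path", "summary_path", "input_paths", "annotation")

store_read <- function(store) {
  if (!file.exists(store$path)) return(list())
  lines <- read_text_lines(store$path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  lines <- lines[lines != paste(JOB_FIELDS, collapse = "\t")]
  recs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(JOB_FIELDS)) return(NULL)  # ignore torn lines
    r <- stats::setNames(as.list(f), JOB_FIELDS)
    r$created_at <- as.numeric(r$created_at)
    r$updated_at <- as.numeric(r$updated_at)
    r$input_paths <- if (nzchar(r$input_paths))
      strsplit(r$input_paths, ";", fixed = TRUE)[[1L]] else character()
    r$annotation <- if (nzchar(r$annotation))
      stats::setNames(as.list(sub("^[^=]*=", "", strsplit(r$annotation, ";", fixed = TRUE)[[1L]])),
                      sub("=.*$", "", strsplit(r$annotation, ";", fixed = TRUE)[[1L]]))
    else list()
    class(r) <- "JobRecord"
    r
  })
  recs <- Filter(Negate(is.null), recs)
  stats::setNames(recs, vapply(recs, `[[`, "", "job_id"))
}

store_write <- function(store, recs) {
  lines <- vapply(recs, function(r) {
    paste(c(r$job_id, r$project, r$email, r$data_type, r$assembly, r$state,
            r$download_url, sprintf("%.6f", r$created_at),
            sprintf("%.6f", r$updated_at), r$log_path, r$summary_path,
            paste(r$input_paths, collapse = ";"),
            if (length(r$annotation))
              paste(sprintf("%s=%s", names(r$annotation),
                            unlist(r$annotation)), collapse = ";")
            else ""),
          collapse = "\t")
  }, "")
  write_lines_atomic(c(paste(JOB_FIELDS, collapse = "\t"), lines), store$path)
}

store_get <- function(store, job_id) {
  recs <- store_read(store)
  if (!job_id %in% names(recs))
    mp_error("lookup_error", sprintf("unknown job_id: %s", job_id))
  recs[[job_id]]
}

store_put <- function(store, rec) {
  recs <- store_read(store)
  recs[[rec$job_id]] <- rec
  store_write(store, recs)
  rec
}

job_transition <- function(store, rec, new_state) {
  allowed <- JOB_EDGES[[rec$state]]
  if (!new_state %in% allowed)
    mp_error("state_error", sprintf("illegal transition %s -> %s for job %s",
                                    rec$state, new_state, rec$job_id))
  if (rec$state == "failed" && new_state == "uploading" &&
      (!nzchar(rec$summary_path) || !file.exists(rec$summary_path)))
    mp_error("state_error", sprintf(
      "job %s cannot be resubmitted: no summary file", rec$job_id))
  rec$state <- new_state
  rec$updated_at <- as.numeric(Sys.time())
  if (new_state != "submitted") rec$download_url <- ""
  job_log_line(rec, sprintf("state -> %s", new_state))
  store_put(store, rec)
}

job_log_line <- function(rec, msg) {
  if (nzchar(rec$log_path)) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
        file = rec$log_path, append = TRUE)
  }
  invisible(NULL)
}

uuid4 <- function() {
  b <- sample.int(256L, 16L, replace = TRUE) - 1L
  b[7] <- bitwOr(bitwAnd(b[7], 0x0F), 0x40)  # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 0x3F), 0x80)  # variant
  h <- sprintf("%02x", b)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

#' Create a job
#'
#' Validates the configuration and persists a new record in state
#' `created`. An assembly is required for `rnaseq`/`chipseq` and ignored
#' for `microarray`; the email, when present, must contain `@`.
#'
#' @param store a [job_store()].
#' @param data_type `"microarray"`, `"rnaseq"` or `"chipseq"`.
#' @param inputs character vector of existing input files.
#' @param assembly `"hg18"`, `"hg19"` or `"mm9"` (sequencing data types).
#' @param project free-text project name (optional).
#' @param email notification address (optional; must contain `@` if given).
#' @param promoters,transcripts,assoc annotation file paths as required by
#'   the data type.
#' @param params named list of pipeline parameters (e.g. `window`,
#'   `pseudocount`) merged into the job's annotation record.
#' @return the persisted `JobRecord`.
#' @export
create_job <- function(store, data_type, inputs, assembly = NULL,
                       project = "", email = "", promoters = NULL,
                       transcripts = NULL, assoc = NULL, params = list()) {
  stopifnot(inherits(store, "JobStore"))
  if (length(data_type) != 1L || !data_type %in% c("microarray", "rnaseq", "chipseq"))
    config_error(sprintf("unknown data_type: %s", paste(data_type, collapse = ",")))
  if (data_type %in% c("rnaseq", "chipseq")) {
    if (is.null(assembly)) config_error(sprintf("%s requires an assembly", data_type))
    check_assembly(assembly)
    if (is.null(promoters)) config_error(sprintf("%s requires a promoter file", data_type))
  }
  if (data_type == "rnaseq" && (is.null(transcripts) || is.null(assoc)))
    config_error("rnaseq requires transcript and association files")
  if (is.null(assembly)) assembly <- ""
  if (!length(inputs)) config_error("no input files given")
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    config_error(sprintf("input file not found: %s", missing[1]))
  if (nzchar(email) && !grepl("@", email, fixed = TRUE))
    config_error(sprintf("invalid email: %s", email))
  ann <- c(
    if (!is.null(promoters)) list(promoters = promoters),
    if (!is.null(transcripts)) list(transcripts = transcripts),
    if (!is.null(assoc)) list(assoc = assoc),
    params
  )
  for (p in c("promoters", "transcripts", "assoc")) {
    if (!is.null(ann[[p]]) && !file.exists(ann[[p]]))
      config_error(sprintf("%s file not found: %s", p, ann[[p]]))
  }
  id <- uuid4()
  now <- as.numeric(Sys.time())
  rec <- structure(list(
    job_id = id, project = project, email = email, data_type = data_type,
    assembly = assembly, state = "created", download_url = "",
    created_at = now, updated_at = now,
    log_path = file.path(store$scratch, paste0(id, ".log")),
    summary_path = "", input_paths = inputs,
    annotation = if (length(ann)) ann else list()
  ), class = "JobRecord")
  file.create(rec$log_path)
  job_log_line(rec, sprintf("job created: type=%s assembly=%s inputs=%d",
                            data_type, assembly, length(inputs)))
  store_put(store, rec)
}

#' Run a job's processing stage
#'
#' Moves the job `created -> processing`, dispatches the inputs to the
#' pipeline for the job's data type (input files processed independently,
#' optionally on several cores), writes the summary file under the store's
#' scratch directory and moves to `processed`. The summary is
#' byte-identical for any worker count. On any stage error the job moves to
#' `failed` with the error text in the log, and the error is re-signalled.
#'
#' @param store a [job_store()].
#' @param job_id id of a job in state `created`.
#' @param workers number of parallel workers.
#' @return the updated `JobRecord` (with `summary_path` set).
#' @export
run_job <- function(store, job_id, workers = 1L) {
  rec <- store_get(store, job_id)
  rec <- job_transition(store, rec, "processing")
  ok <- tryCatch({
    withCallingHandlers({
      sm <- dispatch_pipeline(rec, workers)
    }, warning = function(w) {
      job_log_line(rec, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    rec$summary_path <- file.path(store$scratch, paste0(rec$job_id, ".summary.tsv"))
    job_log_line(rec, sprintf("writing summary: %s", rec$summary_path))
    write_summary(sm, rec$summary_path)
    TRUE
  }, error = function(e) {
    job_log_line(rec, paste("error:", conditionMessage(e)))
    rec$state <- "failed"; rec$updated_at <- as.numeric(Sys.time())
    store_put(store, rec)
    stop(e)
  })
  job_transition(store, rec, "processed")
}

dispatch_pipeline <- function(rec, workers) {
  ann <- rec$annotation
  job_log_line(rec, sprintf("processing %d input(s) with %d worker(s)",
                            length(rec$input_paths), workers))
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  chr <- function(x, d) if (is.null(x)) d else as.character(x)
  switch(rec$data_type,
    chipseq = process_chipseq(
      rec$input_paths, read_promoters(ann$promoters, rec$assembly),
      window = num(ann$window, 2000L),
      pseudocount = num(ann$pseudocount, 0.5),
      mode = chr(ann$count_mode, "overlap"), workers = workers),
    rnaseq = process_rnaseq(
      rec$input_paths, read_promoters(ann$promoters, rec$assembly),
      read_transcripts(ann$transcripts), read_associations(ann$assoc),
      pseudocount = num(ann$pseudocount, 0.5),
      norm = chr(ann$rna_norm, "rpkm"),
      stranded = chr(ann$stranded, "none"), workers = workers),
    microarray = process_microarray(
      rec$input_paths[1L], q = num(ann$nsb_quantile, 0.05),
      eps = num(ann$nsb_clamp, 1.0), k = num(ann$expression_sd, 2))
  )
}

#' Submit a processed job to an analysis server
#'
#' Performs a multipart POST of the summary file plus the fields
#' `data_type`, `assembly`, `project` and `email` to `<server>/submit`. A
#' 200 response whose body contains a result URL moves the job to
#' `submitted` and stores the URL as `download_url`; anything else moves it
#' to `failed`, from which submission may be retried.
#'
#' `server` is either a base URL string (real HTTP via the curl package) or
#' a [mock_mara_server()] object, which implements the same contract
#' in-process for offline use.
#'
#' @param store a [job_store()].
#' @param job_id id of a job in state `processed` (or `failed` after an
#'   earlier submission attempt).
#' @param server base URL string or a `mara_mock_server`.
#' @return the updated `JobRecord`.
#' @export
submit_job <- function(store, job_id, server) {
  rec <- store_get(store, job_id)
  if (!nzchar(rec$summary_path) || !file.exists(rec$summary_path))
    submission_error(sprintf("job %s has no summary file to submit", rec$job_id))
  rec <- job_transition(store, rec, "uploading")
  fields <- list(data_type = rec$data_type, assembly = rec$assembly,
                 project = rec$project, email = rec$email)
  resp <- tryCatch(
    post_summary(server, rec$summary_path, fields),
    error = function(e) list(status = NA_integer_, body = conditionMessage(e))
  )
  if (identical(resp$status, 200L) && nzchar(url <- extract_result_url(resp$body))) {
    rec$download_url <- url
    job_log_line(rec, sprintf("submitted; download URL: %s", url))
    rec$state <- "submitted"; rec$updated_at <- as.numeric(Sys.time())
    store_put(store, rec)
  } else {
    job_log_line(rec, sprintf("submission failed (status %s): %s",
                              resp$status, substr(resp$body, 1, 200)))
    rec <- job_transition(store, rec, "failed")
    submission_error(sprintf("submission of job %s failed (status %s)",
                             rec$job_id, resp$status))
  }
  rec
}

extract_result_url <- function(body) {
  m <- regmatches(body, regexpr("https?://\\S+", body))
  if (length(m)) m[[1]] else ""
}

post_summary <- function(server, summary_path, fields) {
  if (inherits(server, "mara_mock_server")) {
    return(server$handle(list(path = "/submit", fields = fields,
                              file = summary_path)))
  }
  if (!is.character(server) || length(server) != 1L)
    submission_error("server must be a URL or a mara_mock_server")
  if (!requireNamespace("curl", quietly = TRUE))
    submission_error("the 'curl' package is required to submit over HTTP")
  h <- curl::new_handle()
  curl::handle_setform(h, .list = c(
    fields, list(summary = curl::form_file(summary_path, type = "text/tab-separated-values"))
  ))
  res <- curl::curl_fetch_memory(paste0(sub("/$", "", server), "/submit"), handle = h)
  list(status = as.integer(res$status_code), body = rawToChar(res$content))
}

#' An in-process mock analysis server
#'
#' Implements the documented submission contract without any network:
#' `POST /submit` with multipart fields `data_type`, `assembly`, `project`,
#' `email` and the summary file returns status 200 and a plain-text body
#' containing the result URL. Set `$status` to a non-200 value to simulate
#' server failure; every request received is recorded in `$received` for
#' inspection.
#'
#' @param base_url base of the result URLs the mock hands out.
#' @return a `mara_mock_server` environment with fields `status`,
#'   `received` and function `handle(req)`.
#' @export
mock_mara_server <- function(base_url = "http://mock.invalid/results") {
  srv <- new.env(parent = emptyenv())
  srv$status <- 200L
  srv$received <- list()
  srv$n <- 0L
  srv$handle <- function(req) {
    srv$n <- srv$n + 1L
    srv$received[[srv$n]] <- req
    if (!identical(req$path, "/submit"))
      return(list(status = 404L, body = "not found"))
    if (srv$status != 200L)
      return(list(status = srv$status, body = "server error"))
    need <- c("data_type", "assembly", "project", "email")
    if (!all(need %in% names(req$fields)) || !file.exists(req$file))
      return(list(status = 400L, body = "bad request"))
    list(status = 200L,
         body = sprintf("OK %s/%s", base_url,
                        tools::md5sum(req$file)[[1]]))
  }
  class(srv) <- "mara_mock_server"
  srv
}

#' List jobs in creation order
#'
#' @param store a [job_store()].
#' @return data.frame with one row per job, ordered by `created_at`.
#' @export
list_jobs <- function(store) {
  recs <- store_read(store)
  df <- data.frame(
    job_id = vapply(recs, `[[`, "", "job_id"),
    project = vapply(recs, `[[`, "", "project"),
    data_type = vapply(recs, `[[`, "", "data_type"),
    assembly = vapply(recs, `[[`, "", "assembly"),
    state = vapply(recs, `[[`, "", "state"),
    download_url = vapply(recs, `[[`, "", "download_url"),
    created_at = vapply(recs, `[[`, 0, "created_at"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df[order(df$created_at, seq_len(nrow(df))), , drop = FALSE]
}

#' Return a job's log verbatim
#'
#' @param store a [job_store()].
#' @param job_id job id.
#' @return character vector of log lines.
#' @export
job_log <- function(store, job_id) {
  rec <- store_get(store, job_id)
  if (!file.exists(rec$log_path)) return(character())
  readLines(rec$log_path, warn = FALSE)
}
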