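# One shared fixture: a tiny annotation plus two small ChIP-seq samples.
client_fixture <- function(dir, n_reads = 2000, seed = 71) {
  spec <- sim_spec(n_promoters = 10, n_reads = n_reads, seed = seed)
  ann <- gen_annotation(spec, dir)
  beds <- vapply(1:2, function(i) {
    p <- file.path(dir, sprintf("chip%d.bed", i))
    gen_reads(spec, ann, "chipseq", p, i)
    p
  }, "")
  list(spec = spec, ann = ann, beds = beds,
       store = job_store(file.path(dir, "jobs.tsv")))
}

test_that("job creation validates configuration and persists a created record", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  j <- create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
                  promoters = fx$ann$paths$promoters, project = "demo")
  expect_identical(j$state, "created")
  expect_true(file.exists(j$log_path))
  j2 <- create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
                   promoters = fx$ann$paths$promoters)
  expect_false(identical(j$job_id, j2$job_id))
  expect_error(create_job(fx$store, "rnaseq", fx$beds,
                          promoters = fx$ann$paths$promoters),
               "assembly", class = "maraprep_config_error")
  expect_error(create_job(fx$store, "proteomics", fx$beds),
               class = "maraprep_config_error")
  expect_error(create_job(fx$store, "chipseq", c(fx$beds, "no_such.bed"),
                          assembly = "mm9", promoters = fx$ann$paths$promoters),
               "no_such.bed", class = "maraprep_config_error")
  expect_error(create_job(fx$store, "microarray", fx$beds[1], email = "not-an-email"),
               class = "maraprep_config_error")
})

test_that("run_job processes to a summary and logs every stage", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  j <- create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
                  promoters = fx$ann$paths$promoters)
  j <- run_job(fx$store, j$job_id)
  expect_identical(j$state, "processed")
  expect_true(file.exists(j$summary_path))
  sm <- read_summary(j$summary_path)
  expect_identical(dim(sm), c(10L, 2L))
  log <- job_log(fx$store, j$job_id)
  for (stage in c("job created", "state -> processing", "processing 2 input",
                  "writing summary", "state -> processed")) {
    expect_identical(sum(grepl(stage, log, fixed = TRUE)), 1L)
  }
})

test_that("worker count does not change the summary bytes", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  mk <- function(workers) {
    j <- create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
                    promoters = fx$ann$paths$promoters)
    j <- run_job(fx$store, j$job_id, workers = workers)
    readBin(j$summary_path, "raw", file.size(j$summary_path))
  }
  expect_identical(mk(1), mk(4))
})

test_that("a vanished input fails the job with the path in the log", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  doomed <- file.path(d, "soon_gone.bed")
  file.copy(fx$beds[1], doomed)
  j <- create_job(fx$store, "chipseq", doomed, assembly = "mm9",
                  promoters = fx$ann$paths$promoters)
  unlink(doomed)
  expect_error(run_job(fx$store, j$job_id), class = "maraprep_error")
  rec <- maraprep:::store_get(fx$store, j$job_id)
  expect_identical(rec$state, "failed")
  expect_true(any(grepl("soon_gone.bed", job_log(fx$store, j$job_id), fixed = TRUE)))
})

test_that("an empty sample yields a pseudocount column and a logged warning", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  empty <- file.path(d, "empty.bed")
  file.create(empty)
  j <- create_job(fx$store, "chipseq", c(fx$beds[1], empty), assembly = "mm9",
                  promoters = fx$ann$paths$promoters)
  j <- run_job(fx$store, j$job_id)
  expect_identical(j$state, "processed")
  sm <- read_summary(j$summary_path)
  expect_true(all(sm$values[, "empty"] == log2(0.5)))
  expect_true(any(grepl("no reads", job_log(fx$store, j$job_id))))
})

test_that("submission stores a download URL exactly on a 200 response", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  j <- create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
                  promoters = fx$ann$paths$promoters, project = "p", email = "a@b.c")
  j <- run_job(fx$store, j$job_id)
  srv <- mock_mara_server()
  srv$status <- 500L
  expect_error(submit_job(fx$store, j$job_id, srv),
               class = "maraprep_submission_error")
  rec <- maraprep:::store_get(fx$store, j$job_id)
  expect_identical(rec$state, "failed")
  expect_identical(rec$download_url, "")
  # failed submissions are resubmittable
  srv$status <- 200L
  rec <- submit_job(fx$store, j$job_id, srv)
  expect_identical(rec$state, "submitted")
  expect_match(rec$download_url, "^http://")
  req <- srv$received[[length(srv$received)]]
  expect_identical(req$fields$data_type, "chipseq")
  expect_identical(req$fields$email, "a@b.c")
  # submitting an already-submitted job is a state error
  expect_error(submit_job(fx$store, j$job_id, srv), class = "maraprep_state_error")
})

test_that("jobs are listed in creation order and logs are returned verbatim", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  expect_identical(nrow(list_jobs(fx$store)), 0L)
  ids <- vapply(1:3, function(i) {
    create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
               promoters = fx$ann$paths$promoters,
               project = sprintf("p%d", i))$job_id
  }, "")
  df <- list_jobs(fx$store)
  expect_identical(df$job_id, ids)
  expect_true(all(df$state == "created"))
  expect_error(job_log(fx$store, "nope"), class = "maraprep_lookup_error")
})

test_that("no operation sequence can leave the allowed state graph", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  srv <- mock_mara_server()
  withr::local_seed(72)
  edges <- list(created = "processing", processing = c("processed", "failed"),
                processed = c("uploading", "failed"),
                uploading = c("submitted", "failed"),
                failed = "uploading", submitted = character())
  # one client call may pass through several states (run: created ->
  # processing -> processed), so poll-observed pairs are checked against
  # reachability over the allowed edges
  reachable <- function(from) {
    seen <- from
    repeat {
      nxt <- setdiff(unlist(edges[seen]), seen)
      if (!length(nxt)) return(setdiff(seen, from))
      seen <- c(seen, nxt)
    }
  }
  seen <- list()
  ids <- character()
  for (step in 1:40) {
    op <- sample(c("create", "run", "submit_ok", "submit_fail"), 1)
    if (op == "create" || !length(ids)) {
      j <- create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
                      promoters = fx$ann$paths$promoters)
      ids <- c(ids, j$job_id)
      seen[[j$job_id]] <- "created"
    } else {
      id <- sample(ids, 1)
      srv$status <- if (op == "submit_fail") 500L else 200L
      try(if (op == "run") run_job(fx$store, id) else
            submit_job(fx$store, id, srv), silent = TRUE)
    }
    recs <- maraprep:::store_read(fx$store)
    for (id in names(recs)) {
      st <- recs[[id]]$state
      expect_true(st %in% names(edges))
      prev <- seen[[id]]
      if (!is.null(prev) && !identical(prev, st)) {
        expect_true(st %in% reachable(prev),
                    label = sprintf("transition %s -> %s", prev, st))
      }
      seen[[id]] <- st
      # download_url non-empty exactly when submitted
      expect_identical(nzchar(recs[[id]]$download_url), st == "submitted")
    }
  }
})

test_that("a torn trailing line in the store does not corrupt earlier records", {
  d <- withr::local_tempdir()
  fx <- client_fixture(d)
  j <- create_job(fx$store, "chipseq", fx$beds, assembly = "mm9",
                  promoters = fx$ann$paths$promoters)
  cat("half\twritten\trecord", file = fx$store$path, append = TRUE)
  recs <- maraprep:::store_read(fx$store)
  expect_identical(names(recs), j$job_id)
  expect_identical(recs[[j$job_id]]$state, "created")
})
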