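#' Deterministic synthetic-data generators
#'
#' Every pipeline is testable offline: these generators produce promoter /
#' transcript / association annotations on a synthetic chromosome
#' (`chrS1`, deliberately not a real chromosome name), read files with
#' known per-promoter rates, and probe-intensity tables drawn from the
#' microarray background model. All generators are pure functions of
#' `(spec, seed)`: the same spec produces byte-identical files.
#'
#' @name synthetic
NULL

#' Build a simulation spec
#'
#' Defaults describe a small but realistic study: promoters every 10 kb on
#' one synthetic chromosome, 1-3 transcripts per promoter with total span
#' under 8 kb, lognormal(0, 1) promoter rates, 50 bp reads; ChIP-seq read
#' starts spread Normal(anchor, 200 bp); microarray intensities from
#' X = Exp(theta = 200) + N(mu = 100, sigma = 15) with 20% pure-background
#' probes.
#'
#' @param n_promoters number of promoters.
#' @param n_transcripts_per_promoter transcripts per promoter.
#' @param n_reads total reads per generated sample.
#' @param promoter_rates positive weights, length `n_promoters`; `NULL`
#'   draws them from lognormal(0, 1).
#' @param assembly assembly label stamped on the annotation.
#' @param seed integer RNG seed; every generator derives its stream from it.
#' @param read_length generated read length in bp.
#' @param chip_spread standard deviation (bp) of ChIP-seq read starts
#'   around the promoter anchor.
#' @param n_probes,n_samples,mu,sigma,theta,frac_background microarray
#'   generator parameters.
#' @return a `SimSpec` list.
#' @export
sim_spec <- function(n_promoters = 100L, n_transcripts_per_promoter = 2L,
                     n_reads = 100000L, promoter_rates = NULL,
                     assembly = "mm9", seed = 1L,
                     read_length = 50L, chip_spread = 200,
                     n_probes = 10000L, n_samples = 4L,
                     mu = 100, sigma = 15, theta = 200,
                     frac_background = 0.2) {
  stopifnot(n_promoters >= 1L, n_transcripts_per_promoter >= 1L, n_reads >= 0L,
            n_probes >= 1L, n_samples >= 1L, sigma > 0, theta > 0,
            frac_background >= 0, frac_background <= 1)
  check_assembly(assembly)
  if (!is.null(promoter_rates)) {
    if (length(promoter_rates) != n_promoters || any(promoter_rates <= 0))
      config_error("promoter_rates must be positive and of length n_promoters")
  }
  structure(list(
    n_promoters = as.integer(n_promoters),
    n_transcripts_per_promoter = as.integer(n_transcripts_per_promoter),
    n_reads = as.integer(n_reads), promoter_rates = promoter_rates,
    assembly = assembly, seed = as.integer(seed),
    read_length = as.integer(read_length), chip_spread = chip_spread,
    n_probes = as.integer(n_probes), n_samples = as.integer(n_samples),
    mu = mu, sigma = sigma, theta = theta, frac_background = frac_background,
    spacing = 10000L, chrom = "chrS1"
  ), class = "SimSpec")
}

sim_chrom_len <- function(spec) (spec$n_promoters + 1L) * spec$spacing

sim_rates <- function(spec) {
  if (!is.null(spec$promoter_rates)) return(spec$promoter_rates)
  withr::with_seed(spec$seed + 1000L, stats::rlnorm(spec$n_promoters, 0, 1))
}

#' Generate a synthetic annotation
#'
#' Promoters sit every 10 kb on `chrS1` with anchors at 5000, 15000, ...;
#' each promoter's transcripts start at its anchor and run downstream as
#' 1-3 exons with total genomic span <= 8 kb, so neighboring promoters'
#' windows and transcripts never overlap. The three files parse through
#' [read_promoters()], [read_transcripts()] and [read_associations()] with
#' no warnings.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if missing).
#' @return list with elements `promoters`, `transcripts`, `assoc` (parsed
#'   objects) and `paths` (the three written files).
#' @export
gen_annotation <- function(spec, dir) {
  stopifnot(inherits(spec, "SimSpec"))
  if (spec$spacing < 10000L) mp_error("spec_error", "promoter spacing below 10 kb")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_promoters
  anchors <- spec$spacing %/% 2L + (seq_len(n) - 1L) * spec$spacing
  pid <- sprintf("P%05d", seq_len(n))
  withr::with_seed(spec$seed + 2000L, {
    pstrand <- sample(c("+", "-"), n, replace = TRUE)
    exon_rows <- vector("list", n * spec$n_transcripts_per_promoter)
    assoc_tx <- character(0); assoc_p <- character(0)
    k <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(spec$n_transcripts_per_promoter)) {
        k <- k + 1L
        tid <- sprintf("%s.T%d", pid[i], j)
        n_ex <- sample(1:3, 1L)
        # exon lengths and intron gaps chosen so total span stays <= 8 kb
        ex_len <- sample(200:1500, n_ex, replace = TRUE)
        gaps <- if (n_ex > 1L) sample(100:1000, n_ex - 1L, replace = TRUE) else integer()
        starts <- anchors[i] + cumsum(c(0L, ex_len[-n_ex] + gaps))
        exon_rows[[k]] <- data.frame(
          transcript_id = tid, chrom = spec$chrom,
          start = as.integer(starts), end = as.integer(starts + ex_len),
          strand = pstrand[i], stringsAsFactors = FALSE)
        assoc_tx <- c(assoc_tx, tid); assoc_p <- c(assoc_p, pid[i])
      }
    }
  })
  promoters <- new_promoter_set(pid, spec$chrom, anchors, pstrand, spec$assembly)
  transcripts <- build_transcript_set(do.call(rbind, exon_rows))
  assoc <- new_association_table(
    data.frame(transcript_id = assoc_tx, promoter_id = assoc_p,
               stringsAsFactors = FALSE), promoters, transcripts)
  paths <- list(promoters = file.path(dir, "promoters.bed"),
                transcripts = file.path(dir, "transcripts.tsv"),
                assoc = file.path(dir, "associations.tsv"))
  write_promoters(promoters, paths$promoters)
  write_transcripts(transcripts, paths$transcripts)
  write_associations(assoc, paths$assoc)
  list(promoters = promoters, transcripts = transcripts, assoc = assoc,
       paths = paths)
}

#' Generate synthetic reads with known promoter rates
#'
#' RNA-seq mode: transcript `t` of promoter `p` receives
#' `Poisson(lambda_t)` reads with `lambda_t` proportional to
#' `rate_p * length_t` (scaled so the expected total is `n_reads`); each
#' read starts uniformly within the transcript's exons. ChIP-seq mode: each
#' promoter receives `Poisson(rate_p * n_reads / sum(rates))` reads whose
#' start positions are Normal(anchor, `chip_spread`) truncated to the
#' chromosome. All reads have length `read_length` and a random strand.
#'
#' @param spec a [sim_spec()].
#' @param annotation result of [gen_annotation()] for the same spec.
#' @param mode `"rnaseq"` or `"chipseq"`.
#' @param path output BED path.
#' @param sample_index integer >= 1; each sample index derives an
#'   independent (but seed-deterministic) read sample.
#' @return `path`, invisibly; attribute `rates` carries the per-promoter
#'   rates used.
#' @export
gen_reads <- function(spec, annotation, mode = c("rnaseq", "chipseq"),
                      path, sample_index = 1L) {
  stopifnot(inherits(spec, "SimSpec"))
  mode <- match.arg(mode)
  rates <- sim_rates(spec)
  chrom_len <- sim_chrom_len(spec)
  rl <- spec$read_length
  seed <- spec$seed + 3000L + 17L * as.integer(sample_index) +
    1L * (mode == "chipseq")
  reads <- withr::with_seed(seed, {
    if (mode == "rnaseq") {
      tx <- annotation$transcripts$transcripts
      p_of_t <- stats::setNames(annotation$assoc$promoter_id,
                                annotation$assoc$transcript_id)
      rate_t <- rates[match(p_of_t[tx$transcript_id],
                            annotation$promoters$promoter_id)] * tx$length
      lambda <- if (sum(rate_t) > 0) rate_t / sum(rate_t) * spec$n_reads else rate_t
      n_t <- stats::rpois(length(lambda), lambda)
      ex <- annotation$transcripts$exons
      pieces <- lapply(which(n_t > 0L), function(i) {
        e <- ex[ex$transcript_id == tx$transcript_id[i]]
        w <- e$end - e$start
        ej <- sample.int(nrow(e), n_t[i], replace = TRUE, prob = w)
        s <- e$start[ej] + floor(stats::runif(n_t[i]) * w[ej])
        s
      })
      starts <- if (length(pieces)) unlist(pieces) else integer()
    } else {
      n_p <- stats::rpois(spec$n_promoters, rates / sum(rates) * spec$n_reads)
      anchors <- annotation$promoters$anchor
      starts <- unlist(lapply(which(n_p > 0L), function(i) {
        round(stats::rnorm(n_p[i], anchors[i], spec$chip_spread))
      }))
      if (is.null(starts)) starts <- integer()
    }
    starts <- pmin(pmax(as.integer(starts), 0L), chrom_len - rl)
    strand <- if (length(starts)) sample(c("+", "-"), length(starts),
                                         replace = TRUE) else character()
    list(starts = starts, strand = strand)
  })
  lines <- if (length(reads$starts)) {
    sprintf("%s\t%d\t%d\tread%07d\t0\t%s", spec$chrom, reads$starts,
            reads$starts + rl, seq_along(reads$starts), reads$strand)
  } else character()
  write_lines_atomic(lines, path)
  invisible(structure(path, rates = rates))
}

#' Generate a synthetic probe-intensity table
#'
#' A fraction `frac_background` of probes is pure background
#' B ~ N(mu, sigma^2) (clamped > 0) in every sample; the remainder are
#' X = S + B with S ~ Exp(mean theta) drawn independently per sample. The
#' planted labels are written beside the table for filter testing.
#'
#' @param spec a [sim_spec()].
#' @param path output TSV path; labels go to `<path>.labels.tsv`.
#' @return list `path`, `labels_path`, `is_background` (logical per probe).
#' @export
gen_intensities <- function(spec, path) {
  stopifnot(inherits(spec, "SimSpec"))
  n <- spec$n_probes; ns <- spec$n_samples
  out <- withr::with_seed(spec$seed + 4000L, {
    n_bg <- round(spec$frac_background * n)
    is_bg <- rep(FALSE, n)
    if (n_bg > 0) is_bg[sample.int(n, n_bg)] <- TRUE
    bg <- matrix(stats::rnorm(n * ns, spec$mu, spec$sigma), n, ns)
    sig <- matrix(stats::rexp(n * ns, rate = 1 / spec$theta), n, ns)
    sig[is_bg, ] <- 0
    list(m = pmax(bg + sig, 1e-3), is_bg = is_bg)
  })
  ids <- sprintf("probe%06d", seq_len(n))
  header <- paste(c("probe_id", sprintf("S%02d", seq_len(ns))), collapse = "\t")
  body <- vapply(seq_len(n), function(i) {
    paste(c(ids[i], sprintf("%.4f", out$m[i, ])), collapse = "\t")
  }, "")
  write_lines_atomic(c(header, body), path)
  labels_path <- paste0(path, ".labels.tsv")
  write_lines_atomic(c("probe_id\tis_background",
                       sprintf("%s\t%d", ids, as.integer(out$is_bg))),
                     labels_path)
  list(path = path, labels_path = labels_path, is_background = out$is_bg)
}
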