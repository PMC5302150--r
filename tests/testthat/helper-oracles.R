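# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (all-pairs loops, direct arithmetic) and
# share no code with the implementation they check.

# O(n*m) all-pairs interval-overlap counter (half-open intervals)
brute_count_overlaps <- function(reads, windows) {
  vapply(seq_len(nrow(windows)), function(j) {
    sum(reads$chrom == windows$chrom[j] &
          reads$start < windows$end[j] &
          reads$end > windows$start[j])
  }, 0L)
}

# all-pairs exon-overlap read assignment with 1/k splitting
brute_assign_reads <- function(reads, exons, tx_ids) {
  counts <- setNames(numeric(length(tx_ids)), tx_ids)
  n_assigned <- 0L
  for (i in seq_len(nrow(reads))) {
    hit <- unique(exons$transcript_id[
      exons$chrom == reads$chrom[i] &
        exons$start < reads$end[i] &
        exons$end > reads$start[i]])
    if (length(hit)) {
      counts[hit] <- counts[hit] + 1 / length(hit)
      n_assigned <- n_assigned + 1L
    }
  }
  attr(counts, "n_assigned") <- n_assigned
  counts
}

# quadrature oracle for the posterior mean E[S | X = x] under
# S ~ Exp(theta), B ~ N(mu, sigma^2)
quadrature_posterior_mean <- function(x, mu, sigma, theta) {
  vapply(x, function(xi) {
    num <- stats::integrate(function(s) s * stats::dexp(s, 1 / theta) *
                              stats::dnorm(xi - s, mu, sigma),
                            0, Inf, rel.tol = 1e-12)$value
    den <- stats::integrate(function(s) stats::dexp(s, 1 / theta) *
                              stats::dnorm(xi - s, mu, sigma),
                            0, Inf, rel.tol = 1e-12)$value
    num / den
  }, 0)
}

# random fixture builders -------------------------------------------------

random_promoter_set <- function(n, chroms = c("chr1", "chr2"), assembly = "hg19") {
  start <- sample.int(1e6, n)
  maraprep:::new_promoter_set(
    sprintf("P%04d", seq_len(n)), sample(chroms, n, replace = TRUE),
    start, sample(c("+", "-"), n, replace = TRUE), assembly)
}

random_alignments <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                              sample_id = "s1", read_len = 50L) {
  s <- sample.int(max_pos, n, replace = TRUE)
  maraprep:::new_alignment_set(
    sample_id,
    data.table::data.table(chrom = sample(chroms, n, replace = TRUE),
                           start = s, end = s + read_len,
                           strand = sample(c("+", "-"), n, replace = TRUE)),
    n)
}

write_bed <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d\tr%d\t0\t%s", df$chrom, df$start, df$end,
                     seq_len(nrow(df)), df$strand), path)
  path
}

background_params <- function(mu, sigma, theta) {
  structure(list(mu = mu, sigma = sigma, theta = theta),
            class = "BackgroundParams")
}

# minimal one-chromosome annotation used by several client/pipeline tests
tiny_annotation <- function(dir, n_promoters = 20, seed = 99) {
  spec <- sim_spec(n_promoters = n_promoters, n_reads = 5000, seed = seed)
  list(spec = spec, ann = gen_annotation(spec, dir))
}
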