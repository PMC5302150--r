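test_that("background estimation recovers known simulation parameters", {
  withr::local_seed(51)
  # 20% pure-background probes, the rest signal+background
  sig <- stats::rexp(50000, 1 / 200)
  sig[sample.int(50000, 10000)] <- 0
  x <- pmax(sig + stats::rnorm(50000, 100, 15), 1e-3)
  p <- estimate_background(x)
  expect_lt(abs(p$mu - 100) / 100, 0.10)
  expect_lt(abs(p$sigma - 15) / 15, 0.10)
  expect_lt(abs(p$theta - 200) / 200, 0.10)
})

test_that("near-pure background yields a tiny theta and mu near the sample mean", {
  withr::local_seed(52)
  x <- stats::rnorm(50000, 100, 15) + stats::rexp(50000, 1 / (1e-3 * 100))
  p <- estimate_background(x)
  expect_lt(abs(p$mu - mean(x)) / mean(x), 0.05)
  expect_lt(p$theta, 0.2 * p$mu)
})

test_that("degenerate intensity vectors are estimation errors", {
  expect_error(estimate_background(rep(5, 1000)), class = "maraprep_estimation_error")
  expect_error(estimate_background(stats::rnorm(50)), class = "maraprep_estimation_error")
})

test_that("background correction matches the quadrature posterior mean", {
  p <- background_params(100, 15, 200)
  grid <- seq(100 - 3 * 15, 100 + 10 * 15, length.out = 60)
  got <- background_correct(grid, p)
  want <- quadrature_posterior_mean(grid, 100, 15, 200)
  expect_lt(max(abs(got - want) / want), 1e-6)
})

test_that("background correction agrees with an independent normexp implementation", {
  skip_if_not_installed("limma")
  p <- background_params(80, 20, 150)
  grid <- seq(0, 500, length.out = 101)
  lim <- limma::normexp.signal(c(80, log(20), log(150)), grid)
  expect_equal(background_correct(grid, p), lim, tolerance = 1e-10)
})

test_that("background correction is positive, increasing, and has the noiseless limit", {
  p <- background_params(100, 1e-6, 200)
  expect_equal(background_correct(150, p), 50, tolerance = 1e-3)
  withr::local_seed(53)
  for (i in 1:20) {
    pp <- background_params(stats::runif(1, 10, 500), stats::runif(1, 1, 60),
                            stats::runif(1, 10, 500))
    x <- sort(stats::runif(50, pp$mu - 5 * pp$sigma, pp$mu + 10 * pp$sigma))
    y <- background_correct(x, pp)
    expect_true(all(y > 0))
    expect_true(all(diff(y) > 0))
  }
})

test_that("NSB adjustment subtracts the per-sample quantile floor and clamps", {
  m <- matrix(5, 4, 2, dimnames = list(paste0("p", 1:4), c("a", "b")))
  adj <- adjust_nonspecific(m, q = 0.05, eps = 1.0)
  expect_true(all(adj == 1.0))
  withr::local_seed(54)
  m <- matrix(stats::rexp(600, 1 / 50), 200, 3,
              dimnames = list(sprintf("p%03d", 1:200), c("a", "b", "c")))
  adj <- adjust_nonspecific(m, q = 0.1, eps = 1.0)
  nu <- attr(adj, "nsb_floor")
  for (j in 1:3) {
    expect_equal(unname(nu[j]), unname(stats::quantile(m[, j], 0.1)))
    expect_identical(order(adj[, j][adj[, j] > 1]), order(m[, j][adj[, j] > 1]))
  }
})

test_that("probes expressed in at least one sample survive the filter", {
  params <- replicate(4, background_params(100, 10, 200), simplify = FALSE)
  # threshold is mu + 2*sigma = 120
  corrected <- rbind(high_one = c(125, 50, 50, 50),
                     low_all = c(119, 80, 30, 10),
                     high_all = c(300, 250, 260, 280))
  colnames(corrected) <- paste0("s", 1:4)
  adjusted <- corrected
  kept <- filter_nonexpressed(adjusted, corrected, params)
  expect_identical(rownames(kept), c("high_one", "high_all"))
  expect_error(
    filter_nonexpressed(adjusted[2, , drop = FALSE],
                        corrected[2, , drop = FALSE], params),
    class = "maraprep_processing_error")
})

test_that("the filter removes planted background probes but spares signal probes", {
  spec <- sim_spec(seed = 1)   # 10000 probes, 4 samples, 20% background
  gi <- gen_intensities(spec, withr::local_tempfile())
  raw <- read_intensities(gi$path)
  params <- lapply(seq_len(ncol(raw)), function(j) estimate_background(raw[, j]))
  corrected <- vapply(seq_len(ncol(raw)),
                      function(j) background_correct(raw[, j], params[[j]]),
                      numeric(nrow(raw)))
  dimnames(corrected) <- dimnames(raw)
  kept <- filter_nonexpressed(adjust_nonspecific(corrected), corrected, params)
  keep <- rownames(raw) %in% rownames(kept)
  expect_gte(mean(!keep[gi$is_background]), 0.90)
  expect_lte(mean(!keep[!gi$is_background]), 0.10)
})

test_that("quantile normalization reproduces the hand-computed rank means", {
  m <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
  # identical columns are a fixed point
  m2 <- matrix(c(5, 1, 9, 5, 1, 9), 3, 2,
               dimnames = list(paste0("p", 1:3), c("a", "b")))
  expect_equal(quantile_normalize(m2), m2)
})

test_that("ties receive the mean of their tied rank-means", {
  m <- matrix(c(2, 2, 8, 1, 5, 9), 3, 2,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  ref <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 2]), unname(ref))
  expect_equal(unname(qn[1:2, 1]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(qn[3, 1]), unname(ref[3]))
})

test_that("quantile normalization equalizes columns, is idempotent and permutes cleanly", {
  withr::local_seed(55)
  m <- matrix(stats::rlnorm(3000), 500, 6,
              dimnames = list(sprintf("p%03d", 1:500), sprintf("s%d", 1:6)))
  qn <- quantile_normalize(m)
  sorted_cols <- apply(qn, 2, sort)
  expect_true(all(abs(sorted_cols - sorted_cols[, 1]) < 1e-12))
  expect_true(max(abs(colMeans(qn) - mean(colMeans(qn)))) < 1e-12)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(quantile_normalize(m[, perm]), qn[, perm])
})

test_that("quantile normalization agrees with an independent implementation", {
  skip_if_not_installed("limma")
  withr::local_seed(56)
  m <- matrix(stats::rlnorm(1200), 300, 4,
              dimnames = list(sprintf("p%03d", 1:300), sprintf("s%d", 1:4)))
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m, ties = TRUE)),
               tolerance = 1e-12)
})

test_that("log transform is exact on powers of two and strictly monotone", {
  m <- matrix(c(1024, 1), 2, 1, dimnames = list(c("p1", "p2"), "s"))
  sm <- log_transform(m)
  expect_identical(unname(sm$values[, 1]), c(10, 0))
  expect_error(log_transform(matrix(c(1, -1), 2, 1,
                                    dimnames = list(c("a", "b"), "s"))),
               class = "maraprep_invariant_violation")
  withr::local_seed(57)
  x <- sort(stats::runif(100, 0.01, 1000))
  expect_true(all(diff(log2(x)) > 0))
})

test_that("the full microarray chain is deterministic and survives a round trip", {
  spec <- sim_spec(n_probes = 2000, seed = 2)
  gi <- gen_intensities(spec, withr::local_tempfile())
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_summary(process_microarray(gi$path), f1)
  write_summary(process_microarray(gi$path), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  sm <- read_summary(f1)
  expect_identical(sm$meta$data_type, "microarray")
  expect_true(all(is.finite(sm$values)))
})
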