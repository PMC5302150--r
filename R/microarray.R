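#' Microarray chain
#'
#' Raw probe intensities are modeled per sample as X = S + B with true
#' signal S ~ Exponential(mean theta) and additive background
#' B ~ Normal(mu, sigma^2) (the classic normal+exponential convolution).
#' The chain estimates (mu, sigma, theta) per sample, replaces each
#' intensity with the posterior mean E[S | X = x], subtracts a per-sample
#' non-specific-binding floor, removes probes that are non-expressed in
#' every sample, quantile-normalizes across samples and log2-transforms.
#' Input is an open tab-delimited probe-intensity table (probe_id plus one
#' column per sample), not a binary vendor format.
#'
#' @name microarray
NULL

#' Read a probe-intensity table
#'
#' TSV with header `probe_id <sample1> <sample2> ...` and strictly positive
#' intensities.
#'
#' @param path path to the intensity TSV(.gz).
#' @return numeric matrix, rownames = probe ids, colnames = sample ids.
#' @export
read_intensities <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1L] != "probe_id" || ncol(dt) < 2L)
    parse_error("intensity table must have header: probe_id <sample> ...")
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) validation_error("duplicate probe_id")
  m <- as.matrix(dt[, -1L, with = FALSE])
  if (!is.numeric(m)) parse_error("non-numeric intensity values")
  if (any(!is.finite(m)) || any(m <= 0))
    validation_error("intensities must be finite and > 0")
  rownames(m) <- ids
  m
}

#' Estimate background-model parameters for one sample
#'
#' Under X = S + B, S ~ Exp(theta), B ~ N(mu, sigma^2): `mu` is estimated as
#' the mode of a kernel-smoothed density of the intensities, `sigma` as the
#' root-mean-square deviation of the intensities below the mode (the left
#' tail is essentially pure background), and `theta` as the mean excess of
#' the intensities above the mode. The mode is located in two passes: a
#' first density over all intensities, then a second over the sub-mode
#' portion only, whose bandwidth is set by the background spread rather
#' than by the long signal tail (a single pass oversmooths the background
#' peak and drags the mode estimate into the signal).
#'
#' @param x numeric vector of raw intensities for one sample (>= 100 values).
#' @return a `BackgroundParams` list: `mu`, `sigma`, `theta`.
#' @export
estimate_background <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 100L)
    mp_error("estimation_error", "need at least 100 probes to estimate background")
  if (!all(is.finite(x)) || stats::sd(x) == 0)
    mp_error("estimation_error", "degenerate (constant or non-finite) intensities")
  d1 <- stats::density(x, n = 512L)
  m0 <- d1$x[which.max(d1$y)]
  xl <- x[x < m0]
  mu <- if (length(xl) >= 10L && stats::sd(xl) > 0) {
    d2 <- stats::density(xl, n = 512L)
    d2$x[which.max(d2$y)]
  } else m0
  left <- x[x < mu]
  right <- x[x > mu]
  if (!length(left) || !length(right))
    mp_error("estimation_error", "cannot separate background from signal")
  sigma <- sqrt(mean((left - mu)^2))
  theta <- mean(right - mu)
  if (sigma <= 0 || theta <= 0)
    mp_error("estimation_error", "background estimation produced non-positive scale")
  structure(list(mu = mu, sigma = sigma, theta = theta),
            class = "BackgroundParams")
}

#' Posterior-mean background correction
#'
#' Replaces an observed intensity x with E[S | X = x] under the
#' normal+exponential model: with `a = x - mu - sigma^2/theta`, the
#' corrected value is `a + sigma * phi(a/sigma) / Phi(a/sigma)`, evaluated
#' on the log scale so the Gaussian tail ratio stays numerically stable far
#' below the background mean. The result is strictly positive and strictly
#' increasing in x.
#'
#' @param x numeric vector of intensities.
#' @param params a `BackgroundParams`.
#' @return corrected intensities, same length as `x`.
#' @export
background_correct <- function(x, params) {
  stopifnot(inherits(params, "BackgroundParams"))
  a <- x - params$mu - params$sigma^2 / params$theta
  z <- a / params$sigma
  # phi(z)/Phi(z) via logs: exact where Phi underflows
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  out <- a + params$sigma * mills
  pmax(out, .Machine$double.xmin)
}

#' Subtract the non-specific-binding floor
#'
#' Per sample, the floor `nu` is the `q`-quantile of the background-corrected
#' intensities; each value becomes `max(x - nu, eps)`. The shift is monotone
#' (order-preserving up to clamping at `eps`), and `eps = 1` guarantees that
#' the later log2 transform is non-negative and defined.
#'
#' @param m corrected intensity matrix (probes x samples).
#' @param q floor quantile, default 0.05.
#' @param eps lower clamp, default 1.0.
#' @return adjusted matrix with attribute `nsb_floor` (per-sample `nu`).
#' @export
adjust_nonspecific <- function(m, q = 0.05, eps = 1.0) {
  stopifnot(is.matrix(m))
  nu <- apply(m, 2L, stats::quantile, probs = q, names = FALSE)
  adj <- pmax(sweep(m, 2L, nu, "-"), eps)
  attr(adj, "nsb_floor") <- stats::setNames(nu, colnames(m))
  adj
}

#' Remove consistently non-expressed probes
#'
#' A probe is expressed in a sample when its background-corrected (but not
#' yet NSB-adjusted) intensity exceeds `mu + k*sigma` of that sample's
#' background model; probes expressed in zero samples are removed. A probe
#' expressed in even a single sample is kept. Row order of survivors is
#' preserved.
#'
#' @param adjusted NSB-adjusted matrix (rows to subset).
#' @param corrected background-corrected matrix (the expression evidence).
#' @param params list of `BackgroundParams`, one per sample, in column order.
#' @param k threshold in background standard deviations, default 2.
#' @return row subset of `adjusted`, with attribute `expressed` (logical
#'   matrix of per-sample calls on the input rows).
#' @export
filter_nonexpressed <- function(adjusted, corrected, params, k = 2) {
  stopifnot(is.matrix(adjusted), is.matrix(corrected),
            ncol(adjusted) == length(params))
  thr <- vapply(params, function(p) p$mu + k * p$sigma, 0)
  expressed <- sweep(corrected, 2L, thr, ">")
  keep <- rowSums(expressed) > 0L
  if (!any(keep)) processing_error("no expressed probes after filtering")
  out <- adjusted[keep, , drop = FALSE]
  attr(out, "expressed") <- expressed
  out
}

#' Rank-mean quantile normalization
#'
#' The classic procedure: sort each column, average across columns at each
#' rank, and map every entry to the mean of its rank. Ties within a column
#' receive the mean of their tied rank-means, so after normalization every
#' column carries the identical multiset of values and a second application
#' is a no-op.
#'
#' @param m numeric matrix (probes x samples).
#' @return normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (!nrow(m) || !ncol(m)) return(m)
  sorted <- apply(m, 2L, sort, method = "radix")
  if (is.null(dim(sorted))) dim(sorted) <- dim(m)  # single-row input
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j], method = "radix")
    col <- numeric(nrow(m))
    col[o] <- ref
    # tie groups share the mean of the rank-means they span
    col <- stats::ave(col, match(m[, j], m[, j]), FUN = mean)
    out[, j] <- col
  }
  out
}

#' Log2-transform a positive matrix into a summary
#'
#' @param m numeric matrix with all entries > 0.
#' @param meta metadata list for the resulting [summary_matrix()].
#' @return a `SummaryMatrix`.
#' @export
log_transform <- function(m, meta = list()) {
  if (any(m <= 0))
    mp_error("invariant_violation", "log_transform received non-positive values")
  summary_matrix(log2(m), meta = meta)
}

#' Run the full microarray chain
#'
#' @param input path to a probe-intensity TSV, or a numeric matrix as
#'   returned by [read_intensities()].
#' @param q NSB floor quantile (default 0.05).
#' @param eps NSB lower clamp (default 1.0).
#' @param k expression threshold in background standard deviations
#'   (default 2).
#' @return a `SummaryMatrix` of log2 normalized intensities over the
#'   expressed probes.
#' @export
process_microarray <- function(input, q = 0.05, eps = 1.0, k = 2) {
  raw <- if (is.character(input)) read_intensities(input) else input
  stopifnot(is.matrix(raw))
  params <- lapply(seq_len(ncol(raw)), function(j) estimate_background(raw[, j]))
  corrected <- vapply(seq_len(ncol(raw)),
                      function(j) background_correct(raw[, j], params[[j]]),
                      numeric(nrow(raw)))
  dimnames(corrected) <- dimnames(raw)
  adjusted <- adjust_nonspecific(corrected, q = q, eps = eps)
  kept <- filter_nonexpressed(adjusted, corrected, params, k = k)
  normed <- quantile_normalize(kept)
  log_transform(normed, meta = list(
    data_type = "microarray", background = "normexp-posterior-mean",
    nsb_quantile = q, nsb_clamp = eps, expression_sd = k,
    normalization = "quantile-log2"))
}
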