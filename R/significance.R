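# Distance-stratified negative binomial significance model.
#
# Contact counts are grouped by 1D genomic distance (one stratum per bin-width
# interval, per chromosome, up to a maximum distance). Each stratum gets its
# own NB(mu, size) fit; a count is significant when its lower-tail CDF under
# the stratum model reaches the probability threshold. Calls sitting in
# contact deserts (sparse matrix neighborhoods) are then removed.

#' Stratify contact counts by 1D genomic distance
#'
#' Groups counts by `start2 - start1`. The diagonal (distance 0) and pairs
#' beyond `max_distance` are excluded. By default only the stored (non-zero)
#' counts enter the strata, mirroring sparse dump input; with
#' `include_zeros = TRUE` the implicit zero bin pairs of each stratum are
#' appended, which removes the zero-truncation bias of the stratum mean at
#' sparsely covered distances (see the package vignette).
#'
#' @param records canonical contact data.frame for one chromosome.
#' @param resolution bin width in bp.
#' @param max_distance largest 1D distance considered (bp; default 2 Mb).
#' @param include_zeros append implicit zero pairs to each stratum.
#' @param n_bins number of bins on the chromosome (required when
#'   `include_zeros = TRUE`; defaults to the largest observed bin index + 1).
#' @return named list mapping distance (bp, as names) to an integer vector of
#'   counts.
#' @export
stratify_by_distance <- function(records, resolution, max_distance = 2e6,
                                 include_zeros = FALSE, n_bins = NULL) {
  d <- records$start2 - records$start1
  keep <- d > 0 & d <= max_distance
  d <- d[keep]
  cnt <- records$count[keep]
  strata <- split(cnt, d)
  if (include_zeros) {
    if (is.null(n_bins)) n_bins <- max(records$start2) / resolution + 1
    for (nm in names(strata)) {
      k <- as.numeric(nm) / resolution
      n_zero <- max(0, (n_bins - k) - length(strata[[nm]]))
      strata[[nm]] <- c(strata[[nm]], rep(0L, n_zero))
    }
  }
  strata
}

#' Fit a negative binomial to one stratum of counts
#'
#' Maximum-likelihood fit of NB(mu, size) in (log mu, log size), started from
#' method-of-moments (`size0 = mean^2 / (var - mean)`). Under- or
#' equi-dispersed strata (sample variance <= mean) fall back to a Poisson
#' model, encoded as `size = Inf`.
#'
#' @param counts non-negative integer vector.
#' @return list with `mu`, `size`, `n_obs`, `method` ("nb" or "poisson") and,
#'   for NB fits, `loglik` and `converged`.
#' @export
fit_negative_binomial <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || all(counts == 0))
    stop("degenerate stratum: no informative counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m <- mean(counts)
  v <- stats::var(counts)
  n <- length(counts)
  if (!is.finite(v) || v <= m)
    return(list(mu = m, size = Inf, n_obs = n, method = "poisson"))
  size0 <- min(max(m^2 / (v - m), 1e-3), 1e6)
  # exact likelihood over tabulated counts: strata hold few distinct values
  tab <- table(counts)
  vals <- as.numeric(names(tab))
  wts <- as.numeric(tab)
  nll <- function(p) {
    -sum(wts * stats::dnbinom(vals, size = exp(p[2L]), mu = exp(p[1L]),
                              log = TRUE))
  }
  opt <- stats::optim(c(log(m), log(size0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-12))
  list(mu = exp(opt$par[1L]), size = exp(opt$par[2L]), n_obs = n,
       method = "nb", loglik = -opt$value, converged = opt$convergence == 0L)
}

#' Fit all distance strata of a chromosome
#'
#' Applies [fit_negative_binomial()] to every stratum with at least `min_obs`
#' counts; smaller or degenerate (all-zero) strata are skipped, so no calls
#' are made at those distances.
#'
#' @param strata output of [stratify_by_distance()].
#' @param min_obs minimum counts per stratum (default 30).
#' @return data.frame with `distance` (bp), `mu`, `size`, `n_obs`, `method`.
#' @export
fit_strata <- function(strata, min_obs = 30L) {
  rows <- lapply(names(strata), function(nm) {
    cnt <- strata[[nm]]
    if (length(cnt) < min_obs || all(cnt == 0)) return(NULL)
    f <- fit_negative_binomial(cnt)
    data.frame(distance = as.numeric(nm), mu = f$mu, size = f$size,
               n_obs = f$n_obs, method = f$method)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(distance = numeric(), mu = numeric(), size = numeric(),
                      n_obs = integer(), method = character())
  out[order(out$distance), , drop = FALSE]
}

#' Lower-tail contact probability under a stratum model
#'
#' Returns `P(X <= count)` under NB(mu, size), or Poisson(mu) for the
#' `size = Inf` fallback. Vectorized over all arguments.
#'
#' @param count observed contact count(s), non-negative.
#' @param mu stratum mean(s).
#' @param size stratum NB size(s); `Inf` selects the Poisson model.
#' @return probabilities in `[0, 1]`, monotone non-decreasing in `count`.
#' @export
contact_probability <- function(count, mu, size) {
  if (any(count < 0)) stop("count must be non-negative")
  n <- max(length(count), length(mu), length(size))
  count <- rep_len(count, n)
  mu <- rep_len(mu, n)
  size <- rep_len(size, n)
  pois <- is.infinite(size)
  out <- numeric(n)
  if (any(pois)) out[pois] <- stats::ppois(count[pois], lambda = mu[pois])
  if (any(!pois))
    out[!pois] <- stats::pnbinom(count[!pois], size = size[!pois],
                                 mu = mu[!pois])
  out
}

#' Call significant contacts against fitted strata
#'
#' A stored contact is retained when its lower-tail probability under its
#' distance stratum's fit reaches `prob_threshold` (inclusive). Records in
#' distances without a fit (skipped strata, the diagonal, beyond the fitted
#' range) are dropped.
#'
#' @param records canonical contact data.frame.
#' @param fits stratum fit table from [fit_strata()].
#' @param prob_threshold significance threshold on the CDF (default 0.975).
#' @return the retained records with added `distance`, `probability` and
#'   `expected` (stratum mean) columns.
#' @export
call_significant <- function(records, fits, prob_threshold = 0.975) {
  d <- records$start2 - records$start1
  idx <- match(d, fits$distance)
  ok <- !is.na(idx)
  rec <- records[ok, , drop = FALSE]
  idx <- idx[ok]
  prob <- contact_probability(rec$count, fits$mu[idx], fits$size[idx])
  keep <- prob >= prob_threshold
  out <- rec[keep, , drop = FALSE]
  out$distance <- d[ok][keep]
  out$probability <- prob[keep]
  out$expected <- fits$mu[idx][keep]
  rownames(out) <- NULL
  out
}

#' Remove significant calls located in contact deserts
#'
#' For each significant contact at matrix pixel (i, j), the mean raw count
#' over the `(2 * padding + 1)^2` window centered on the pixel is computed on
#' the full symmetric contact matrix, counting absent sparse entries as zero
#' and clipping the window at the matrix boundary (the mean is over in-bounds
#' pixels only). Calls with a window mean below `min_mean` are discarded as
#' noise.
#'
#' @param significant significant contacts (subset of `all_records`).
#' @param all_records all stored contacts of the chromosome.
#' @param resolution bin width in bp.
#' @param padding window half-width in pixels (default 5).
#' @param min_mean minimum mean raw count in the window (default 1).
#' @param n_bins matrix dimension; defaults to the largest observed bin
#'   index + 1.
#' @return the surviving subset of `significant`.
#' @export
desert_filter <- function(significant, all_records, resolution, padding = 5L,
                          min_mean = 1, n_bins = NULL) {
  if (nrow(significant) == 0L) return(significant)
  i_all <- all_records$start1 / resolution + 1
  j_all <- all_records$start2 / resolution + 1
  if (is.null(n_bins)) n_bins <- max(j_all)
  off <- i_all != j_all
  M <- Matrix::sparseMatrix(i = c(i_all, j_all[off]),
                            j = c(j_all, i_all[off]),
                            x = c(all_records$count, all_records$count[off]),
                            dims = c(n_bins, n_bins))
  si <- significant$start1 / resolution + 1
  sj <- significant$start2 / resolution + 1
  wmean <- vapply(seq_along(si), function(t) {
    rows <- max(1, si[t] - padding):min(n_bins, si[t] + padding)
    cols <- max(1, sj[t] - padding):min(n_bins, sj[t] + padding)
    sum(M[rows, cols, drop = FALSE]) / (length(rows) * length(cols))
  }, numeric(1))
  out <- significant[wmean >= min_mean, , drop = FALSE]
  rownames(out) <- NULL
  out
}
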