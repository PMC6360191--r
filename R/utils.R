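#' Weighted delete-one-block jackknife for a (ratio) statistic
#'
#' Core resampling engine shared by all f-statistics. The estimate is a
#' ratio of block-summable quantities, `sum(num) / sum(den)`; plain means
#' are the special case `den = 1` per observation. Standard errors use the
#' weighted jackknife with block weights equal to the number of
#' observations (SNPs) per block, which is appropriate when missingness
#' leaves blocks of unequal size.
#'
#' @param num numeric vector of per-SNP numerator contributions.
#' @param den per-SNP denominator contributions, or `NULL` for a mean
#'   (denominator 1 per SNP).
#' @param blocks integer/factor block id per SNP, contiguous in the genome.
#' @return list with `est`, `se`, `z`, `n_blocks`, `n_snps`, and the
#'   delete-one-block estimates `loo`.
#' @keywords internal
block_jackknife <- function(num, den = NULL, blocks) {
  keep <- is.finite(num)
  if (!is.null(den)) keep <- keep & is.finite(den)
  num <- num[keep]
  blocks <- blocks[keep]
  if (is.null(den)) den <- rep(1, length(num)) else den <- den[keep]
  n <- length(num)
  if (n == 0L) stop("no usable SNPs for jackknife")
  bl <- factor(blocks)
  g <- nlevels(bl)
  if (g < 2L) stop("fewer than 2 usable blocks; cannot jackknife")
  s_num <- rowsum(num, bl)[, 1L]
  s_den <- rowsum(den, bl)[, 1L]
  m <- as.vector(table(bl))
  S <- sum(s_num); TT <- sum(s_den)
  if (TT == 0) stop("zero denominator across all SNPs")
  est <- S / TT
  loo <- (S - s_num) / (TT - s_den)
  h <- n / m
  theta_jack <- g * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  v <- mean((tau - theta_jack)^2 / (h - 1))
  se <- sqrt(v)
  list(est = est, se = se, z = if (se > 0) est / se else NA_real_,
       n_blocks = g, n_snps = n, loo = loo)
}

#' Weighted jackknife covariance of a vector statistic
#'
#' Given per-block sums and counts for each component of a vector of mean
#' statistics, returns the full-data estimate, delete-one-block estimates
#' and the weighted-jackknife covariance matrix.
#'
#' @param bsum g x k matrix of per-block numerator sums.
#' @param bcnt g x k matrix of per-block SNP counts (denominators).
#' @return list with `est` (length k), `loo` (g x k), `cov` (k x k),
#'   `n_blocks`.
#' @keywords internal
jackknife_cov <- function(bsum, bcnt) {
  g <- nrow(bsum)
  if (g < 2L) stop("fewer than 2 blocks")
  S <- colSums(bsum)
  N <- colSums(bcnt)
  if (any(N == 0)) stop("statistic component with zero usable SNPs")
  est <- S / N
  loo <- sweep(-bsum, 2L, S, "+") / sweep(-bcnt, 2L, N, "+")
  # block weights from total usable SNPs across components
  m <- rowSums(bcnt)
  n <- sum(m)
  h <- n / m
  theta_jack <- g * est - colSums((1 - m / n) * loo)
  tau <- h * matrix(est, g, length(est), byrow = TRUE) - (h - 1) * loo
  dev <- sweep(tau, 2L, theta_jack, "-") / sqrt(h - 1)
  cov <- crossprod(dev) / g
  list(est = est, loo = loo, cov = cov, n_blocks = g)
}

#' Derive a stream-specific 32-bit seed from a master seed
#' @keywords internal
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
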