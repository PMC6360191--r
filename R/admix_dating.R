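#' Weighted admixture-LD decay curve
#'
#' For every SNP pair within a maximum genetic distance, computes the
#' haplotype covariance of the admixed sample weighted by the allele
#' frequency difference between the two reference (source proxy)
#' populations at both loci, and averages the weighted products within
#' distance bins. Admixture generates positive weighted LD that decays
#' as exp(-g d) with distance d (Morgans) for a pulse g generations ago.
#' Pairs are formed within chromosomes only.
#'
#' @param hs a `haplotype_set` (see [simulate_admixture_ld()]) or a list
#'   with `haps` (haplotype x SNP 0/1 matrix) and `map` (`chrom`,
#'   `gpos`).
#' @param freq1,freq2 reference allele frequencies per SNP.
#' @param bin_width_cm bin width in cM (default 0.1).
#' @param max_dist_cm maximum pair distance in cM (default 10).
#' @return data.frame of class `weighted_ld_curve`: `bin_left_cm`,
#'   `bin_mid_cm`, `wld`, `n_pairs`.
#' @export
weighted_ld_curve <- function(hs, freq1, freq2, bin_width_cm = 0.1,
                              max_dist_cm = 10) {
  haps <- hs$haps; map <- hs$map
  ns <- ncol(haps)
  stopifnot(length(freq1) == ns, length(freq2) == ns)
  if (all(abs(freq1 - freq2) < 1e-12))
    stop("reference populations are identical; weights vanish")
  w <- freq1 - freq2
  nh <- nrow(haps)
  n_bins <- as.integer(ceiling(max_dist_cm / bin_width_cm))
  acc <- numeric(n_bins); cnt <- numeric(n_bins)
  max_d <- max_dist_cm / 100
  for (chr in unique(map$chrom)) {
    sidx <- which(map$chrom == chr)
    H <- haps[, sidx, drop = FALSE]
    gp <- map$gpos[sidx]
    o <- order(gp)
    H <- H[, o, drop = FALSE]; gp <- gp[o]
    wc <- w[sidx][o]
    mu <- colMeans(H)
    Hc <- sweep(H, 2L, mu)
    m <- length(gp)
    chunk <- 512L
    for (s0 in seq(1L, m, by = chunk)) {
      s1 <- min(s0 + chunk - 1L, m)
      # pairs (s, t) with s in chunk, t > s, within max distance
      t_hi <- findInterval(gp[s0:s1] + max_d, gp)
      t_max <- max(t_hi)
      if (t_max <= s0) next
      cols <- s0:t_max
      CP <- crossprod(Hc[, s0:s1, drop = FALSE], Hc[, cols, drop = FALSE]) / nh
      D <- outer(-gp[s0:s1], gp[cols], "+")     # distance t minus s
      valid <- D > 0 & D <= max_d
      if (!any(valid)) next
      W <- outer(wc[s0:s1], wc[cols])
      b <- pmin(ceiling(D[valid] * 100 / bin_width_cm), n_bins)
      vals <- (CP * W)[valid]
      acc_b <- rowsum(vals, b)
      ids <- as.integer(rownames(acc_b))
      acc[ids] <- acc[ids] + acc_b[, 1L]
      cnt_b <- rowsum(rep(1, length(b)), b)
      cnt[ids] <- cnt[ids] + cnt_b[, 1L]
    }
  }
  if (all(cnt == 0)) stop("no SNP pairs fall in any distance bin")
  out <- data.frame(bin_left_cm = (seq_len(n_bins) - 1L) * bin_width_cm,
                    bin_mid_cm = (seq_len(n_bins) - 0.5) * bin_width_cm,
                    wld = ifelse(cnt > 0, acc / cnt, NA_real_),
                    n_pairs = cnt)
  class(out) <- c("weighted_ld_curve", "data.frame")
  out
}

#' Date an admixture pulse from weighted LD decay
#'
#' Fits A exp(-g d) + c to the weighted LD curve beyond a minimum
#' distance cutoff (which excludes background LD) by least squares
#' weighted by pair counts, with d in Morgans so that g is in
#' generations. The date in years applies the standard human generation
#' time of 28 years. With several chromosomes, a delete-one-chromosome
#' jackknife on the curve gives the SE of g.
#'
#' @param curve a [weighted_ld_curve()] (or any data.frame with
#'   `bin_mid_cm`, `wld`, `n_pairs`).
#' @param min_dist_cm lower distance cutoff in cM (default 0.5).
#' @param generation_time years per generation (default 28).
#' @return list of class `exp_fit`: `amplitude`, `g`, `affine`,
#'   `years`, `se_g` (NA without chromosome replicates), `failed`.
#' @export
fit_exponential_decay <- function(curve, min_dist_cm = 0.5,
                                  generation_time = 28) {
  use <- curve$bin_mid_cm >= min_dist_cm & is.finite(curve$wld) &
    curve$n_pairs > 0
  if (sum(use) < 5L) stop("fewer than 5 usable bins beyond the cutoff")
  d <- curve$bin_mid_cm[use] / 100
  y <- curve$wld[use]
  wt <- curve$n_pairs[use]
  # log-linear start on positive, above-baseline values
  c0 <- min(y)
  pos <- y - c0 + 1e-12
  lf <- stats::lm(log(pos) ~ d, weights = wt)
  g0 <- max(1, -stats::coef(lf)[[2L]])
  A0 <- exp(stats::coef(lf)[[1L]])
  obj <- function(par) {
    A <- par[1L]; g <- par[2L]; cc <- par[3L]
    sum(wt * (y - (A * exp(-g * d) + cc))^2)
  }
  opt <- stats::optim(c(A0, g0, c0), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  A <- opt$par[1L]; g <- opt$par[2L]; cc <- opt$par[3L]
  failed <- !(g > 0) || A <= 0
  structure(list(amplitude = A, g = g, affine = cc,
                 years = g * generation_time, se_g = NA_real_,
                 generation_time = generation_time, failed = failed),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("admixture date: g = %.1f generations (%.0f years at %g y/gen)%s\n",
              x$g, x$years, x$generation_time,
              if (x$failed) " [FAILED FIT]" else ""))
  invisible(x)
}

#' Date admixture from haplotypes and two reference populations
#'
#' Convenience wrapper: computes the weighted LD curve and fits the
#' exponential decay, optionally jackknifing over chromosomes for the SE
#' of g.
#'
#' @inheritParams weighted_ld_curve
#' @inheritParams fit_exponential_decay
#' @return an `exp_fit`, with `se_g` filled in when the map has more
#'   than one chromosome.
#' @export
date_admixture <- function(hs, freq1, freq2, bin_width_cm = 0.1,
                           max_dist_cm = 10, min_dist_cm = 0.5,
                           generation_time = 28) {
  curve <- weighted_ld_curve(hs, freq1, freq2, bin_width_cm, max_dist_cm)
  fit <- fit_exponential_decay(curve, min_dist_cm, generation_time)
  chrs <- unique(hs$map$chrom)
  if (length(chrs) > 1L) {
    gs <- vapply(chrs, function(ch) {
      keep <- hs$map$chrom != ch
      sub <- list(haps = hs$haps[, keep, drop = FALSE],
                  map = hs$map[keep, , drop = FALSE])
      cv <- weighted_ld_curve(sub, freq1[keep], freq2[keep],
                              bin_width_cm, max_dist_cm)
      fit_exponential_decay(cv, min_dist_cm, generation_time)$g
    }, 0)
    nch <- length(chrs)
    fit$se_g <- sqrt((nch - 1) / nch * sum((gs - mean(gs))^2))
  }
  fit$curve <- curve
  fit
}
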