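#' Default outgroup (right) population set
#'
#' The 14-population outgroup list used for the published qpWave/qpAdm
#' analyses of the Caucasus/steppe cohort.
#'
#' @return character vector of population labels.
#' @export
default_outgroups <- function() {
  c("Mbuti.DG", "Ust_Ishim.DG", "Kostenki14", "MA1", "Han.DG", "Papuan.DG",
    "Onge.DG", "Villabruna", "Vestonice16", "ElMiron", "Ethiopia_4500BP.SG",
    "Karitiana.DG", "Natufian", "Iran_Ganj_Dareh_Neolithic")
}

# f4 matrix X[i,j] = f4(l0, l_i; r0, r_j) with per-block sums for the
# jackknife. allsnps = TRUE uses, for each entry, every SNP where its own
# four populations have data; FALSE restricts to SNPs complete across all
# left and right populations.
f4_block_matrix <- function(left, right, freqs, blocks, allsnps = TRUE) {
  l0 <- left[1L]; r0 <- right[1L]
  li <- left[-1L]; rj <- right[-1L]
  m <- length(li); cc <- length(rj)
  pl0 <- get_freq(freqs, l0)$p
  pr0 <- get_freq(freqs, r0)$p
  complete <- NULL
  if (!allsnps) {
    allp <- c(left, right)
    complete <- rep(TRUE, length(pl0))
    for (p in allp) complete <- complete & !is.na(get_freq(freqs, p)$p)
  }
  bl <- factor(blocks)
  G <- nlevels(bl)
  bsum <- matrix(0, G, m * cc)
  bcnt <- matrix(0, G, m * cc)
  for (j in seq_len(cc)) {
    prj <- get_freq(freqs, rj[j])$p
    right_diff <- pr0 - prj
    for (i in seq_len(m)) {
      pli <- get_freq(freqs, li[i])$p
      num <- (pl0 - pli) * right_diff
      if (!allsnps) num[!complete] <- NA_real_
      use <- is.finite(num)
      idx <- i + (j - 1L) * m
      bsum[, idx] <- rowsum(ifelse(use, num, 0), bl)[, 1L]
      bcnt[, idx] <- rowsum(as.numeric(use), bl)[, 1L]
    }
  }
  nonempty <- rowSums(bcnt) > 0
  bsum <- bsum[nonempty, , drop = FALSE]
  bcnt <- bcnt[nonempty, , drop = FALSE]
  jk <- jackknife_cov(bsum, bcnt)
  list(X = matrix(jk$est, m, cc), cov = jk$cov, loo = jk$loo,
       bcnt = bcnt, m = m, c = cc, left = left, right = right,
       n_blocks = nrow(bsum))
}

regularized_inverse <- function(Q, ridge = 1e-8) {
  d <- nrow(Q)
  Qr <- Q + diag(ridge * sum(diag(Q)) / d, d)
  out <- tryCatch(solve(Qr), error = function(e) NULL)
  if (is.null(out))
    stop("singular f4 covariance; use fewer right populations or more blocks")
  out
}

# chi-square of the best weighted rank-r approximation to X (vectorized
# column-major as x with inverse covariance Qi), by alternating GLS.
rank_fit_chisq <- function(X, Qi, r, max_iter = 60, tol = 1e-10) {
  m <- nrow(X); cc <- ncol(X)
  x <- as.vector(X)
  if (r == 0L) return(drop(t(x) %*% Qi %*% x))
  if (r >= min(m, cc)) return(0)
  perm <- as.vector(t(matrix(seq_len(m * cc), m, cc)))
  xT <- x[perm]; QiT <- Qi[perm, perm]
  sv <- svd(X)
  B <- sv$v[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  A <- sv$u[, seq_len(r), drop = FALSE]
  chi_old <- Inf
  for (it in seq_len(max_iter)) {
    DA <- kronecker(B, diag(m))                       # vec(E) = DA %*% vec(A)
    a <- solve(t(DA) %*% Qi %*% DA, t(DA) %*% Qi %*% x)
    A <- matrix(a, m, r)
    DB <- kronecker(A, diag(cc))                      # vec(E^T) = DB %*% vec(B)
    b <- solve(t(DB) %*% QiT %*% DB, t(DB) %*% QiT %*% xT)
    B <- matrix(b, cc, r)
    res <- x - as.vector(A %*% t(B))
    chi <- drop(t(res) %*% Qi %*% res)
    if (abs(chi_old - chi) < tol * (1 + chi)) break
    chi_old <- chi
  }
  chi
}

#' qpWave-style rank test for the number of ancestry streams
#'
#' Builds the matrix of f4(l0, l_i; r0, r_j) statistics between a left
#' (test) and right (outgroup) population set and asks, for each rank r,
#' whether the matrix is consistent with rank r given its block-jackknife
#' covariance. Rank r corresponds to the left populations being related
#' to the outgroups via r + 1 streams of ancestry. The fit statistic is
#' chi-square distributed with (L-1-r)(R-1-r) degrees of freedom.
#'
#' @param left test populations (>= 2).
#' @param right outgroup populations, disjoint from `left`, at least as
#'   many as `left`.
#' @param freqs,blocks as in [f2_stat()].
#' @param allsnps per-statistic SNP selection (default TRUE).
#' @param ridge relative ridge added to the covariance diagonal.
#' @return data.frame with columns rank, chisq, dof, p.
#' @export
qpwave_rank_test <- function(left, right, freqs, blocks, allsnps = TRUE,
                             ridge = 1e-8) {
  stopifnot(length(left) >= 2L, length(right) >= length(left))
  if (length(intersect(left, right)))
    stop("left and right population sets must be disjoint")
  fb <- f4_block_matrix(left, right, freqs, blocks, allsnps)
  Qi <- regularized_inverse(fb$cov, ridge)
  ranks <- 0:(min(fb$m, fb$c) - 1L)
  out <- lapply(ranks, function(r) {
    chi <- rank_fit_chisq(fb$X, Qi, r)
    dof <- (fb$m - r) * (fb$c - r)
    data.frame(rank = r, chisq = chi, dof = dof,
               p = stats::pchisq(chi, dof, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

# weights minimizing w' X M(w)^{-1} X' w with sum(w) = 1, for fixed
# covariance; M is the covariance of X' w assembled from the vec-X
# jackknife covariance Q.
solve_weights <- function(X, Q, w, ridge = 1e-8) {
  k <- nrow(X); cc <- ncol(X)
  idx <- lapply(seq_len(cc), function(j) ((j - 1L) * k + 1L):(j * k))
  M <- matrix(0, cc, cc)
  for (j in seq_len(cc)) for (j2 in j:cc) {
    v <- drop(t(w) %*% Q[idx[[j]], idx[[j2]], drop = FALSE] %*% w)
    M[j, j2] <- v; M[j2, j] <- v
  }
  Mi <- regularized_inverse(M, ridge)
  G <- X %*% Mi %*% t(X)
  Gi <- regularized_inverse(G, ridge)
  ones <- rep(1, k)
  w_new <- drop(Gi %*% ones)
  w_new / sum(w_new)
}

#' qpAdm-style mixture-proportion estimate
#'
#' Models a target population as a mixture of source populations by
#' requiring that the mixture reproduces the target's f4 relationships to
#' a set of outgroups: with X[i,j] = f4(target, source_i; r0, r_j), the
#' weight vector w (summing to 1) should satisfy w' X = 0. Weights are
#' estimated by generalized least squares under the block-jackknife
#' covariance of X, standard errors by delete-one-block jackknife of the
#' whole estimation, and model fit by the rank test at rank
#' n_sources - 1 (p small = model rejected). Weights outside [0,1] are
#' returned as-is with `feasible = FALSE`, never clipped.
#'
#' @param target target population.
#' @param sources source populations (>= 1).
#' @param outgroups outgroup populations (> sources + 1), disjoint from
#'   target and sources.
#' @param freqs,blocks as in [f2_stat()].
#' @param allsnps per-statistic SNP selection (default TRUE, mirroring
#'   the published analyses).
#' @param ridge covariance regularization.
#' @return object of class `mixture_estimate`: list with `target`,
#'   `sources`, `weights`, `se`, `feasible`, `p_rank`, `n_blocks`.
#' @export
qpadm_estimate <- function(target, sources, outgroups, freqs, blocks,
                           allsnps = TRUE, ridge = 1e-8) {
  stopifnot(length(sources) >= 1L, length(outgroups) >= length(sources) + 1L)
  left <- c(target, sources)
  if (anyDuplicated(left)) stop("target duplicated among sources")
  if (length(intersect(left, outgroups)))
    stop("outgroups must be disjoint from target and sources")
  fb <- f4_block_matrix(left, outgroups, freqs, blocks, allsnps)
  k <- fb$m
  w <- rep(1 / k, k)
  for (it in 1:10) {
    w_new <- solve_weights(fb$X, fb$cov, w, ridge)
    if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
    w <- w_new
  }
  # delete-one-block re-estimation with the full-data covariance
  G <- fb$n_blocks
  loo_w <- matrix(NA_real_, G, k)
  for (g in seq_len(G)) {
    Xg <- matrix(fb$loo[g, ], k, fb$c)
    wg <- w
    for (it in 1:3) wg <- solve_weights(Xg, fb$cov, wg, ridge)
    loo_w[g, ] <- wg
  }
  mg <- rowSums(fb$bcnt)
  n <- sum(mg)
  h <- n / mg
  se <- vapply(seq_len(k), function(i) {
    theta_jack <- G * w[i] - sum((1 - mg / n) * loo_w[, i])
    tau <- h * w[i] - (h - 1) * loo_w[, i]
    sqrt(mean((tau - theta_jack)^2 / (h - 1)))
  }, 0)
  Qi <- regularized_inverse(fb$cov, ridge)
  r <- k - 1L
  chi <- rank_fit_chisq(fb$X, Qi, r)
  dof <- (fb$m - r) * (fb$c - r)
  p_rank <- stats::pchisq(chi, dof, lower.tail = FALSE)
  structure(list(target = target, sources = sources,
                 weights = stats::setNames(w, sources),
                 se = stats::setNames(se, sources),
                 feasible = all(w >= 0 & w <= 1),
                 p_rank = p_rank, chisq = chi, dof = dof,
                 n_blocks = G, n_snps = NA_integer_),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("qpAdm-style model:", x$target, "=",
      paste(sprintf("%.1f%% %s", 100 * x$weights, x$sources), collapse = " + "), "\n")
  cat(sprintf("rank-test p = %.3g; feasible: %s\n", x$p_rank, x$feasible))
  invisible(x)
}

#' Two-way model search over candidate source pairs
#'
#' Fits every candidate pair as a two-source mixture model for the target
#' and ranks models by rank-test p-value; a model is accepted when it is
#' feasible (weights in [0,1]) and fits (p above the threshold).
#'
#' @param target target population.
#' @param candidate_pairs list of length-2 character vectors, or a
#'   2-row/2-column matrix of pairs.
#' @param outgroups,freqs,blocks,allsnps as in [qpadm_estimate()].
#' @param p_threshold acceptance threshold on the rank-test p-value.
#' @return data.frame sorted by p descending with weights, SEs,
#'   feasibility and acceptance flags.
#' @export
model_search_two_way <- function(target, candidate_pairs, outgroups, freqs,
                                 blocks, allsnps = TRUE, p_threshold = 0.05) {
  if (is.matrix(candidate_pairs)) {
    if (nrow(candidate_pairs) != 2L) candidate_pairs <- t(candidate_pairs)
    candidate_pairs <- lapply(seq_len(ncol(candidate_pairs)),
                              function(k) candidate_pairs[, k])
  }
  rows <- lapply(candidate_pairs, function(pr) {
    if (length(pr) != 2L || anyDuplicated(pr) || target %in% pr)
      stop("invalid candidate pair: ", paste(pr, collapse = ","))
    fit <- qpadm_estimate(target, pr, outgroups, freqs, blocks, allsnps)
    data.frame(source1 = pr[1L], source2 = pr[2L],
               w1 = fit$weights[1L], w2 = fit$weights[2L],
               se1 = fit$se[1L], se2 = fit$se[2L],
               p = fit$p_rank, feasible = fit$feasible, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$accepted <- out$feasible & out$p > p_threshold
  out[order(-out$p), , drop = FALSE]
}
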