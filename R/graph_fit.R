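# weighted least squares with non-negativity by active-set clamping;
# adequate for drift lengths, which are refit jointly at every proposal
wls_nonneg <- function(M, y, wts) {
  A <- M * wts; b <- y * wts
  p <- ncol(M)
  free <- rep(TRUE, p)
  d <- rep(0, p)
  for (iter in seq_len(p + 1L)) {
    d <- rep(0, p)
    co <- qr.coef(qr(A[, free, drop = FALSE]), b)
    co[is.na(co)] <- 0
    d[free] <- co
    neg <- d < -1e-12
    if (!any(neg)) break
    free <- free & !neg
    if (!any(free)) break
  }
  pmax(d, 0)
}

# squared-mass design matrix: rows = population pairs, cols = drift edges
f2_design <- function(graph, pop1, pop2) {
  m <- path_masses(graph)
  dm <- m[pop1, , drop = FALSE] - m[pop2, , drop = FALSE]
  dm^2
}

set_admix_weights <- function(graph, w) {
  w <- unname(w)
  for (q in seq_along(graph$admix))
    graph$admix[[q]]$weights <- c(w[q], 1 - w[q])
  graph
}

#' Fit an admixture graph to observed f2 statistics
#'
#' Minimizes the weighted residual sum of squares
#' sum(((obs - pred) / se)^2) over non-negative drift lengths and
#' admixture proportions in (0, 1). For fixed proportions the prediction
#' is linear in the edge lengths, so lengths are profiled out by
#' non-negative weighted least squares and only the proportions are
#' searched by multi-start bounded quasi-Newton (seeded, deterministic).
#' f3 and f4 predictions follow from the fitted f2 matrix by the linear
#' identities, guaranteeing internal consistency.
#'
#' @param graph fitting topology (all admixture nodes two-parent).
#' @param f2_obs data.frame (pop1, pop2, est, se) from
#'   [observed_f2_table()]; must cover all graph leaves.
#' @param n_restarts number of random restarts for the proportions.
#' @param seed integer seed for restart initialization.
#' @return object of class `graph_fit`: `graph` (with fitted lengths and
#'   proportions), `score`, `residuals` (f2 table with predictions and
#'   Z), `worst_z`, `converged`, `n_restarts`.
#' @export
fit_graph <- function(graph, f2_obs, n_restarts = 20L, seed = 1L) {
  stopifnot(all(c("pop1", "pop2", "est", "se") %in% names(f2_obs)))
  if (any(f2_obs$se <= 0)) stop("all f2 standard errors must be > 0")
  miss <- setdiff(graph$leaves, unique(c(f2_obs$pop1, f2_obs$pop2)))
  if (length(miss))
    stop("observed f2 table does not cover leaves: ", paste(miss, collapse = ", "))
  if (any(vapply(graph$admix, function(a) length(a$parents), 0L) != 2L))
    stop("fitting requires two-parent admixture nodes")
  keep <- f2_obs$pop1 %in% graph$leaves & f2_obs$pop2 %in% graph$leaves
  f2_obs <- f2_obs[keep, , drop = FALSE]
  wts <- 1 / f2_obs$se
  y <- f2_obs$est
  nq <- length(graph$admix)
  objective <- function(w) {
    g <- set_admix_weights(graph, w)
    M <- f2_design(g, f2_obs$pop1, f2_obs$pop2)
    d <- wls_nonneg(M, y, wts)
    sum(((y - as.vector(M %*% d)) * wts)^2)
  }
  solve_at <- function(w) {
    g <- set_admix_weights(graph, w)
    M <- f2_design(g, f2_obs$pop1, f2_obs$pop2)
    d <- wls_nonneg(M, y, wts)
    list(graph = g, d = d, score = sum(((y - as.vector(M %*% d)) * wts)^2))
  }
  if (nq == 0L) {
    best <- solve_at(numeric(0))
    conv <- TRUE
  } else {
    starts <- with_seed(seed, {
      s0 <- vapply(graph$admix, function(a) a$weights[1L], 0)
      rbind(s0, matrix(stats::runif((n_restarts - 1L) * nq, 0.05, 0.95),
                       ncol = nq))
    })
    best <- NULL; conv <- FALSE
    for (r in seq_len(nrow(starts))) {
      opt <- stats::optim(starts[r, ], objective, method = "L-BFGS-B",
                          lower = rep(1e-3, nq), upper = rep(1 - 1e-3, nq),
                          control = list(maxit = 200))
      cand <- solve_at(opt$par)
      if (is.null(best) || cand$score < best$score - 1e-12 ||
          (abs(cand$score - best$score) <= 1e-12 &&
           isTRUE(all(opt$par < vapply(best$graph$admix,
                                       function(a) a$weights[1L], 0))))) {
        best <- cand
        conv <- opt$convergence == 0L
      }
    }
  }
  g <- best$graph
  g$edges$length <- best$d
  pred <- expected_f2_matrix(g)
  res <- f2_obs
  res$pred <- pred[cbind(res$pop1, res$pop2)]
  res$z <- (res$est - res$pred) / res$se
  structure(list(graph = g, score = best$score, residuals = res,
                 worst_z = max(abs(res$z)), converged = conv,
                 n_restarts = n_restarts),
            class = "graph_fit")
}

#' @export
print.graph_fit <- function(x, ...) {
  cat(sprintf("graph_fit: score %.3f, worst |Z| %.3f over %d f2 residuals%s\n",
              x$score, x$worst_z, nrow(x$residuals),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Residuals of a fitted graph over f2, f3 and f4 statistics
#'
#' Computes observed statistics (with jackknife SEs) for the graph's
#' leaves and compares them to the predictions implied by the fitted f2
#' matrix, returning the residual table and the worst |Z|, the quantity
#' on which graph solutions are accepted (|Z| <= 3) or rejected.
#'
#' @param fit a [fit_graph()] result (or an `admixture_graph`).
#' @param freqs,blocks observed data as in [f2_stat()].
#' @param stats which statistic families to evaluate.
#' @return list with `table` and `worst_z`.
#' @export
graph_residuals <- function(fit, freqs, blocks, stats = c("f2", "f3", "f4")) {
  graph <- if (inherits(fit, "graph_fit")) fit$graph else fit
  pred <- predict_fstats(graph)
  pops <- graph$leaves
  rows <- list()
  if ("f2" %in% stats) {
    for (i in seq_len(nrow(pred$f2))) {
      r <- pred$f2[i, ]
      o <- f2_stat(r$pop1, r$pop2, freqs, blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        stat = "f2", pops = paste(r$pop1, r$pop2, sep = ","),
        obs = o$est, se = o$se, pred = r$value)
    }
  }
  if ("f3" %in% stats && !is.null(pred$f3)) {
    for (i in seq_len(nrow(pred$f3))) {
      r <- pred$f3[i, ]
      o <- f3_stat(r$a, r$b, r$target, freqs, blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        stat = "f3", pops = paste(r$target, r$a, r$b, sep = ","),
        obs = o$est, se = o$se, pred = r$value)
    }
  }
  if ("f4" %in% stats && !is.null(pred$f4)) {
    for (i in seq_len(nrow(pred$f4))) {
      r <- pred$f4[i, ]
      o <- f4_stat(r$a, r$b, r$c, r$d, freqs, blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        stat = "f4", pops = paste(r$a, r$b, r$c, r$d, sep = ","),
        obs = o$est, se = o$se, pred = r$value)
    }
  }
  tab <- do.call(rbind, rows)
  tab$z <- (tab$obs - tab$pred) / tab$se
  list(table = tab, worst_z = max(abs(tab$z)))
}

# insert a named node in the middle of drift edge ei
split_edge <- function(graph, ei, new_node) {
  ed <- graph$edges
  half <- ed$length[ei] / 2
  top <- data.frame(parent = ed$parent[ei], child = new_node, length = half)
  bottom <- data.frame(parent = new_node, child = ed$child[ei], length = half)
  list(edges = rbind(ed[-ei, , drop = FALSE], top, bottom), node = new_node)
}

graft_candidates <- function(graph, pop, try_admixture = TRUE) {
  ne <- nrow(graph$edges)
  out <- list()
  for (ei in seq_len(ne)) {
    sp <- split_edge(graph, ei, paste0("gr_", pop))
    edges <- rbind(sp$edges,
                   data.frame(parent = sp$node, child = pop, length = 0.01))
    out[[length(out) + 1L]] <- list(
      graph = admixture_graph(edges, graph$admix),
      attach = sprintf("branch:%s->%s", graph$edges$parent[ei], graph$edges$child[ei]))
  }
  if (try_admixture && ne >= 2L) {
    prs <- utils::combn(ne, 2L)
    for (k in seq_len(ncol(prs))) {
      e1 <- prs[1L, k]; e2 <- prs[2L, k]
      sp1 <- split_edge(graph, e1, paste0("grA_", pop))
      # indices shift after removing e1; recompute e2's row in sp1$edges
      tgt <- which(sp1$edges$parent == graph$edges$parent[e2] &
                     sp1$edges$child == graph$edges$child[e2] &
                     abs(sp1$edges$length - graph$edges$length[e2]) < 1e-12)[1L]
      sp2 <- split_edge(list(edges = sp1$edges), tgt, paste0("grB_", pop))
      edges <- rbind(sp2$edges,
                     data.frame(parent = paste0("grM_", pop), child = pop,
                                length = 0.01))
      admix <- c(graph$admix, list(list(child = paste0("grM_", pop),
                                        parents = c(paste0("grA_", pop),
                                                    paste0("grB_", pop)),
                                        weights = c(0.5, 0.5))))
      g <- tryCatch(admixture_graph(edges, admix), error = function(e) NULL)
      if (!is.null(g))
        out[[length(out) + 1L]] <- list(
          graph = g,
          attach = sprintf("admix:%s->%s|%s->%s",
                           graph$edges$parent[e1], graph$edges$child[e1],
                           graph$edges$parent[e2], graph$edges$child[e2]))
    }
  }
  out
}

#' Consecutive-grafting admixture-graph search
#'
#' Starting from a fitted skeleton, adds populations one at a time,
#' trying every attachment: as a plain branch on each drift edge and
#' (optionally) as a two-parent admixed leaf on each pair of edges. Each
#' candidate is refitted from scratch and only solutions whose worst
#' residual |Z| stays within the threshold survive to seed the next
#' round, mirroring the published search that grew the Caucasus graph
#' from a Mbuti/Loschbour/MA1 skeleton.
#'
#' @param skeleton an [admixture_graph()] whose leaves are already
#'   covered by the data.
#' @param additions ordered character vector of populations to graft.
#' @param freqs,blocks observed data as in [f2_stat()].
#' @param z_threshold survival threshold on the worst residual |Z|.
#' @param try_admixture also propose admixed attachments.
#' @param max_survivors survivors carried into the next round (by score).
#' @param n_restarts,seed passed to [fit_graph()].
#' @param residual_stats statistic families for the acceptance |Z|.
#' @return list with `survivors` (list of `graph_fit` with `attach`
#'   labels and worst |Z|), `failed_round` (NA when all rounds produced
#'   survivors), and a `trace` data.frame of all evaluated candidates.
#' @export
graft_search <- function(skeleton, additions, freqs, blocks, z_threshold = 3,
                         try_admixture = TRUE, max_survivors = 5L,
                         n_restarts = 8L, seed = 1L,
                         residual_stats = c("f2", "f4")) {
  survivors <- list(list(graph = skeleton, attach = "skeleton", score = 0))
  trace <- list()
  failed_round <- NA_integer_
  for (round in seq_along(additions)) {
    pop <- additions[round]
    pops_now <- c(skeleton$leaves, additions[seq_len(round)])
    f2o <- observed_f2_table(pops_now, freqs, blocks)
    next_surv <- list()
    for (s in survivors) {
      cands <- graft_candidates(s$graph, pop, try_admixture)
      for (cd in cands) {
        fit <- fit_graph(cd$graph, f2o, n_restarts = n_restarts,
                         seed = derive_seed(seed, round))
        rz <- graph_residuals(fit, freqs, blocks, residual_stats)
        trace[[length(trace) + 1L]] <- data.frame(
          round = round, pop = pop, from = s$attach, attach = cd$attach,
          score = fit$score, worst_z = rz$worst_z)
        if (rz$worst_z <= z_threshold) {
          fit$attach <- paste(s$attach, cd$attach, sep = " | ")
          fit$worst_z_all <- rz$worst_z
          next_surv[[length(next_surv) + 1L]] <- fit
        }
      }
    }
    if (!length(next_surv)) { failed_round <- round; break }
    ord <- order(vapply(next_surv, function(x) x$worst_z_all, 0))
    survivors <- next_surv[ord[seq_len(min(max_survivors, length(next_surv)))]]
  }
  list(survivors = survivors, failed_round = failed_round,
       trace = do.call(rbind, trace))
}
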