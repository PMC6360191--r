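#' Construct an admixture graph
#'
#' A rooted directed acyclic graph whose drift edges carry non-negative
#' lengths and whose admixture nodes mix two or more parent lineages with
#' weights summing to one. Edge lengths are held internally on the
#' natural (dimensionless drift) scale; the text serialization multiplies
#' them by 1000, the convention used in published graph figures.
#'
#' Graphs used for fitting and topology search must have two-parent
#' admixture nodes only; the frequency simulator accepts any number of
#' parents.
#'
#' @param edges data.frame with columns `parent`, `child`, `length`
#'   (natural drift units, >= 0).
#' @param admix optional list of admixture events, each a list with
#'   `child`, `parents` (character vector), `weights` (same length,
#'   summing to 1).
#' @return object of class `admixture_graph` with components `edges`,
#'   `admix`, `nodes`, `root`, `leaves`, and a topological `order`.
#' @export
admixture_graph <- function(edges, admix = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("parent", "child", "length") %in% names(edges)))
  if (any(edges$length < 0)) stop("drift edge lengths must be >= 0")
  admix <- lapply(admix, function(a) {
    if (abs(sum(a$weights) - 1) > 1e-8)
      stop("model error: admixture weights for ", a$child, " do not sum to 1")
    if (any(a$weights < 0) || any(a$weights > 1))
      stop("model error: admixture weights must lie in [0,1]")
    if (length(a$parents) != length(a$weights) || length(a$parents) < 2L)
      stop("model error: admixture node needs >= 2 parents with matching weights")
    a
  })
  parent_of <- c(edges$parent, unlist(lapply(admix, `[[`, "parents")))
  child_of <- c(edges$child, unlist(lapply(
    admix, function(a) rep(a$child, length(a$parents)))))
  nodes <- unique(c(parent_of, child_of))
  n_in <- table(factor(child_of, levels = nodes))
  adm_children <- vapply(admix, `[[`, "", "child")
  plain_children <- edges$child
  if (anyDuplicated(plain_children))
    stop("model error: node with two drift parents: ",
         plain_children[duplicated(plain_children)][1L])
  if (any(adm_children %in% plain_children))
    stop("model error: node is both drift child and admixture child")
  roots <- nodes[n_in == 0L]
  if (length(roots) != 1L)
    stop("model error: graph must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  # topological sort (parents before children)
  ord <- character(0)
  remaining <- nodes
  indeg <- as.vector(n_in); names(indeg) <- nodes
  queue <- roots
  link <- data.frame(parent = parent_of, child = child_of, stringsAsFactors = FALSE)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    ch <- link$child[link$parent == v]
    for (c in ch) {
      indeg[c] <- indeg[c] - sum(link$parent == v & link$child == c)
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(ord) != length(nodes)) stop("model error: graph contains a cycle")
  has_out <- nodes %in% parent_of
  leaves <- nodes[!has_out]
  structure(list(edges = edges, admix = admix, nodes = nodes, root = roots,
                 leaves = leaves, order = ord),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat("admixture_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "drift edges,", length(x$admix), "admixture events\n")
  cat("root:", x$root, "| leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Lineage path masses of each leaf on each drift edge
#'
#' Tracing a leaf's ancestry towards the root, admixture nodes split the
#' lineage mass among their parents according to the mixing weights. The
#' mass that a leaf places on a drift edge is the probability that its
#' lineage drifts through that edge; these masses are the basis of the
#' f-statistic path algebra.
#'
#' @param graph an [admixture_graph()].
#' @param leaves which populations to trace (default all leaves).
#' @return matrix (length(leaves) x n_edges) of masses in [0,1].
#' @export
path_masses <- function(graph, leaves = graph$leaves) {
  node_masses <- node_path_masses(graph, leaves)
  m <- node_masses[, graph$edges$child, drop = FALSE]
  colnames(m) <- paste(graph$edges$parent, graph$edges$child, sep = "->")
  m
}

# mass of each traced leaf's lineage at every node
node_path_masses <- function(graph, leaves = graph$leaves) {
  nodes <- graph$nodes
  mass <- matrix(0, length(leaves), length(nodes),
                 dimnames = list(leaves, nodes))
  mass[cbind(leaves, leaves)] <- 1
  adm_child <- vapply(graph$admix, `[[`, "", "child")
  for (v in rev(graph$order)) {
    mv <- mass[, v]
    if (all(mv == 0)) next
    ai <- match(v, adm_child)
    if (!is.na(ai)) {
      a <- graph$admix[[ai]]
      for (j in seq_along(a$parents))
        mass[, a$parents[j]] <- mass[, a$parents[j]] + a$weights[j] * mv
    } else {
      p <- graph$edges$parent[graph$edges$child == v]
      if (length(p)) mass[, p] <- mass[, p] + mv
    }
  }
  mass
}

#' Total ancestry contribution of a source node to a leaf
#'
#' The fraction of a leaf's lineage mass that passes through a given
#' ancestor node; for a two-level cascade of two-parent admixtures this
#' reproduces the overall percentages quoted for three-way mixtures.
#'
#' @param graph an [admixture_graph()].
#' @param leaf leaf population label.
#' @param node ancestor node label.
#' @return scalar mass in [0,1].
#' @export
ancestry_contribution <- function(graph, leaf, node) {
  node_path_masses(graph, leaf)[1L, node]
}

#' Expected f2 matrix of an admixture graph (path algebra)
#'
#' Expected f2 between two leaves is the sum over drift edges of edge
#' length times the squared difference in lineage path mass. f3 and f4
#' follow from f2 by the usual linear identities.
#'
#' @param graph an [admixture_graph()].
#' @param pops populations (default all leaves).
#' @return symmetric matrix of expected f2 values.
#' @export
expected_f2_matrix <- function(graph, pops = graph$leaves) {
  m <- path_masses(graph, pops)
  d <- graph$edges$length
  n <- length(pops)
  f2 <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    v <- sum(d * (m[i, ] - m[j, ])^2)
    f2[i, j] <- v; f2[j, i] <- v
  }
  f2
}

#' Predict f2, f3 and f4 statistics from a graph
#'
#' @param graph an [admixture_graph()].
#' @param pops populations to include (default all leaves).
#' @return list of data.frames `f2` (pop1, pop2, value), `f3`
#'   (target; a, b), and `f4` (a, b; c, d over distinct quadruple
#'   partitions), all derived from the expected f2 matrix via
#'   f3(C; A, B) = (f2(C,A) + f2(C,B) - f2(A,B)) / 2 and
#'   f4(A,B;C,D) = (f2(A,D) + f2(B,C) - f2(A,C) - f2(B,D)) / 2.
#' @export
predict_fstats <- function(graph, pops = graph$leaves) {
  F2 <- expected_f2_matrix(graph, pops)
  n <- length(pops)
  f2 <- do.call(rbind, lapply(seq_len(n - 1L), function(i)
    data.frame(pop1 = pops[i], pop2 = pops[(i + 1L):n],
               value = F2[i, (i + 1L):n])))
  f3 <- NULL
  if (n >= 3L) {
    trip <- expand.grid(c = seq_len(n), i = seq_len(n), j = seq_len(n))
    trip <- trip[trip$i < trip$j & trip$c != trip$i & trip$c != trip$j, ]
    f3 <- data.frame(target = pops[trip$c], a = pops[trip$i], b = pops[trip$j],
                     value = (F2[cbind(trip$c, trip$i)] + F2[cbind(trip$c, trip$j)] -
                                F2[cbind(trip$i, trip$j)]) / 2)
  }
  f4 <- NULL
  if (n >= 4L) {
    quads <- utils::combn(n, 4L)
    rows <- lapply(seq_len(ncol(quads)), function(k) {
      q <- quads[, k]
      # the three distinct pairings of a quadruple
      parts <- list(q[c(1, 2, 3, 4)], q[c(1, 3, 2, 4)], q[c(1, 4, 2, 3)])
      do.call(rbind, lapply(parts, function(p)
        data.frame(a = pops[p[1]], b = pops[p[2]], c = pops[p[3]], d = pops[p[4]],
                   value = (F2[p[1], p[4]] + F2[p[2], p[3]] -
                              F2[p[1], p[3]] - F2[p[2], p[4]]) / 2)))
    })
    f4 <- do.call(rbind, rows)
  }
  list(f2 = f2, f3 = f3, f4 = f4)
}

#' Parse an admixture graph from its text format
#'
#' Records are whitespace-separated lines:
#' `edge <parent> <child> <length_x1000>` and
#' `admix <child> <parent1> <parent2> [...] <w1> [w2 ...]` (one weight
#' fewer than parents; the last weight is implied). Lengths are stored
#' divided by 1000. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return an [admixture_graph()].
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  ed <- list(); ad <- list()
  for (tk in toks) {
    if (tk[1L] == "edge") {
      ed[[length(ed) + 1L]] <- data.frame(parent = tk[2L], child = tk[3L],
                                          length = as.numeric(tk[4L]) / 1000)
    } else if (tk[1L] == "admix") {
      rest <- tk[-(1:2)]
      suppressWarnings(num <- as.numeric(rest))
      k <- sum(is.na(num))            # leading parent labels
      parents <- rest[seq_len(k)]
      w <- num[-seq_len(k)]
      if (length(w) == k - 1L) w <- c(w, 1 - sum(w))
      ad[[length(ad) + 1L]] <- list(child = tk[2L], parents = parents, weights = w)
    } else stop("unknown graph record: ", tk[1L])
  }
  admixture_graph(do.call(rbind, ed), ad)
}

#' Serialize an admixture graph to its text format
#'
#' Drift lengths are written multiplied by 1000.
#'
#' @param graph an [admixture_graph()].
#' @param path file path.
#' @export
write_graph <- function(graph, path) {
  ed <- sprintf("edge\t%s\t%s\t%.10g", graph$edges$parent, graph$edges$child,
                graph$edges$length * 1000)
  ad <- vapply(graph$admix, function(a)
    paste(c("admix", a$child, a$parents, sprintf("%.10g", a$weights)),
          collapse = "\t"), "")
  writeLines(c(ed, ad), path)
  invisible(path)
}

#' Exact expected f-statistics under the Balding-Nichols simulation
#'
#' The frequency simulator draws a child frequency with mean equal to the
#' parent's and variance F p (1 - p) per drift edge, and mixes parents
#' linearly at admixture nodes. Because those moment recursions are
#' linear, the exact second-moment table E[p_X p_Y] for all node pairs is
#' computable in closed form given the root frequency's first two
#' moments. This provides the exact expected f2 matrix for the simulated
#' world, which differs from the path-algebra prediction only in units:
#' each edge's effective f2-length is its drift parameter F times the
#' expected heterozygosity at the edge's parent.
#'
#' @param graph graph whose edge lengths are Balding-Nichols F values.
#' @param root_mean,root_m2 first and second moments of the root
#'   frequency distribution (defaults: uniform on [0.05, 0.95]).
#' @return list with `f2` (expected f2 matrix over leaves), and
#'   `f2_graph`: a copy of the graph with edge lengths converted to f2
#'   units, suitable for [predict_fstats()].
#' @export
bn_expected_f2 <- function(graph, root_mean = 0.5,
                           root_m2 = 0.5^2 + 0.9^2 / 12) {
  nodes <- graph$nodes
  nn <- length(nodes)
  C <- matrix(NA_real_, nn, nn, dimnames = list(nodes, nodes))
  adm_child <- vapply(graph$admix, `[[`, "", "child")
  C[graph$root, graph$root] <- root_m2
  f2_len <- graph$edges$length
  for (v in graph$order) {
    if (v == graph$root) next
    ai <- match(v, adm_child)
    prev <- graph$order[seq_len(match(v, graph$order) - 1L)]
    if (!is.na(ai)) {
      a <- graph$admix[[ai]]
      for (y in prev)
        C[v, y] <- C[y, v] <- sum(a$weights * C[cbind(a$parents, rep(y, length(a$parents)))])
      W <- outer(a$weights, a$weights)
      P <- C[a$parents, a$parents, drop = FALSE]
      C[v, v] <- sum(W * P)
    } else {
      ei <- which(graph$edges$child == v)
      p <- graph$edges$parent[ei]
      FF <- graph$edges$length[ei]
      for (y in prev) C[v, y] <- C[y, v] <- C[p, y]
      C[v, v] <- (1 - FF) * C[p, p] + FF * root_mean
      f2_len[ei] <- FF * (root_mean - C[p, p])   # F x parent heterozygosity
    }
  }
  leaves <- graph$leaves
  f2 <- matrix(0, length(leaves), length(leaves), dimnames = list(leaves, leaves))
  for (i in seq_along(leaves)) for (j in seq_along(leaves)) if (i < j) {
    A <- leaves[i]; B <- leaves[j]
    v <- C[A, A] + C[B, B] - 2 * C[A, B]
    f2[i, j] <- v; f2[j, i] <- v
  }
  g2 <- graph
  g2$edges$length <- f2_len
  list(f2 = f2, f2_graph = g2)
}
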