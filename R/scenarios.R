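#' Default Caucasus/steppe admixture-graph scenario
#'
#' The package's stock simulation world: the published joint graph of
#' Mbuti, Loschbour, MA1, EHG, CHG, an Anatolian-farmer lineage,
#' Globular Amphora, Eneolithic steppe, Maykop and Yamnaya_Caucasus, with
#' the printed admixture proportions used as simulation truth: Maykop =
#' 86.4% CHG + 9.6% Anatolian-farmer + 4% EHG ancestry,
#' Yamnaya_Caucasus = 16% Globular-Amphora-related farmer ancestry, the
#' Eneolithic steppe a majority-EHG (65%) mixture with a CHG-related
#' lineage, EHG itself ANE-majority (70%) over WHG, and Globular Amphora
#' an Anatolian-farmer population with 30% WHG ancestry. Drift lengths
#' (x1000 Balding-Nichols F) are fixed package defaults at realistic
#' ancient-DNA scale; only the admixture proportions are published
#' quantities.
#'
#' The Maykop node mixes three parents, which the simulator supports
#' directly; [fig5_fit_topology()] returns the matching two-parent
#' cascade used for fitting.
#'
#' @return an [admixture_graph()].
#' @export
fig5_graph <- function() {
  e <- function(parent, child, len1000)
    data.frame(parent = parent, child = child, length = len1000 / 1000)
  edges <- rbind(
    e("Root", "Mbuti", 120),
    e("Root", "nonAfr", 80),
    e("nonAfr", "Basal", 15),
    e("Basal", "pCHG", 40),
    e("pCHG", "CHG", 40),
    e("Basal", "pAF", 30),
    e("pAF", "Anatolian_farmers", 25),
    e("nonAfr", "WEur", 20),
    e("WEur", "pWHG", 30),
    e("pWHG", "Loschbour", 45),
    e("WEur", "pANE", 25),
    e("pANE", "MA1", 50),
    e("pANE", "pEHG_ANE", 15),
    e("EHG_mix", "EHG", 35),
    e("Ene_mix", "Eneolithic_steppe", 20),
    e("GA_mix", "Globular_Amphora", 30),
    e("May_mix", "Maykop", 25),
    e("Yam_mix", "Yamnaya_Caucasus", 20))
  admix <- list(
    list(child = "EHG_mix", parents = c("pEHG_ANE", "pWHG"),
         weights = c(0.70, 0.30)),
    list(child = "Ene_mix", parents = c("EHG_mix", "pCHG"),
         weights = c(0.65, 0.35)),
    list(child = "GA_mix", parents = c("pAF", "pWHG"),
         weights = c(0.70, 0.30)),
    list(child = "May_mix", parents = c("pCHG", "pAF", "EHG_mix"),
         weights = c(0.864, 0.096, 0.040)),
    list(child = "Yam_mix", parents = c("Ene_mix", "GA_mix"),
         weights = c(0.84, 0.16)))
  admixture_graph(edges, admix)
}

#' Two-parent fitting topology matching [fig5_graph()]
#'
#' Identical to the default scenario graph except that the three-way
#' Maykop admixture is represented as a cascade of two two-parent
#' events: Maykop's non-CHG share first mixes Anatolian-farmer and EHG
#' lineages, then joins CHG. Total ancestry contributions (path masses at
#' `pCHG`, `pAF` and `EHG_mix`) are invariant to this rewriting.
#'
#' @param weights optionally override the cascade start values.
#' @return an [admixture_graph()].
#' @export
fig5_fit_topology <- function(weights = NULL) {
  g <- fig5_graph()
  adm <- g$admix
  adm[[4]] <- NULL
  adm <- c(adm, list(
    list(child = "MayAE", parents = c("pAF", "EHG_mix"),
         weights = c(0.096, 0.040) / 0.136),
    list(child = "May_mix", parents = c("pCHG", "MayAE"),
         weights = c(0.864, 0.136))))
  admixture_graph(g$edges, adm)
}

#' Generic qpAdm parameter-recovery world
#'
#' Builds a graph in which a target population is a k-way mixture of
#' source-related lineages, each source having a private drift leg and a
#' "cousin" outgroup that makes the outgroup set differentially related
#' to the sources (the condition qpAdm needs for power), plus a ladder of
#' deeper generic outgroups.
#'
#' @param weights numeric mixture weights (sum 1); names become source
#'   labels (defaults `S1..Sk`).
#' @param n_outgroups total outgroups, cousins included.
#' @param n_decoys extra unrelated leaves (`X1..Xn`), usable as decoy
#'   sources in model-search experiments; not part of the outgroup set.
#' @return list with `graph`, `target`, `sources`, `outgroups`, `decoys`.
#' @export
build_qpadm_scenario <- function(weights, n_outgroups = 10L, n_decoys = 0L) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, length(weights) >= 2L)
  k <- length(weights)
  src <- names(weights)
  if (is.null(src)) src <- paste0("S", seq_len(k))
  n_deep <- n_outgroups - k
  stopifnot(n_deep >= 1L)
  rows <- list(); nodes_prev <- "Root"
  ogs <- character(0)
  e <- function(p, c, l) data.frame(parent = p, child = c, length = l)
  for (i in seq_len(n_deep)) {
    chain <- if (i < n_deep) paste0("C", i) else "D0"
    og <- paste0("O", i)
    rows[[length(rows) + 1L]] <- e(nodes_prev, og, 0.045)
    rows[[length(rows) + 1L]] <- e(nodes_prev, chain, 0.008)
    nodes_prev <- chain
    ogs <- c(ogs, og)
  }
  prev <- "D0"
  anc <- character(k)
  for (i in seq_len(k)) {
    b <- paste0("B", i)
    a <- paste0("A", i)
    if (i < k) {
      rows[[length(rows) + 1L]] <- e(prev, b, 0.010)
      rows[[length(rows) + 1L]] <- e(b, a, 0.010)
      prev <- b
    } else {
      rows[[length(rows) + 1L]] <- e(prev, a, 0.020)
    }
    co <- paste0("CO", i)
    rows[[length(rows) + 1L]] <- e(a, src[i], 0.025)
    rows[[length(rows) + 1L]] <- e(a, co, 0.040)
    anc[i] <- a
    ogs <- c(ogs, co)
  }
  decoys <- character(0)
  for (i in seq_len(n_decoys)) {
    x <- paste0("X", i)
    rows[[length(rows) + 1L]] <- e("D0", x, 0.035)
    decoys <- c(decoys, x)
  }
  admix <- list(list(child = "T_mix", parents = anc, weights = unname(weights)))
  rows[[length(rows) + 1L]] <- e("T_mix", "Target", 0.010)
  g <- admixture_graph(do.call(rbind, rows), admix)
  list(graph = g, target = "Target", sources = src, outgroups = ogs,
       decoys = decoys)
}

#' Two-way steppe/farmer qpAdm recovery world
#'
#' A Yamnaya-like target mixed from an Eneolithic-steppe-like source and
#' a Globular-Amphora-like farmer source that is itself an
#' Anatolian-farmer population with 30% WHG-related ancestry, matching
#' the surrogate-source structure of the published two-way steppe
#' models.
#'
#' @param alpha farmer-surrogate admixture fraction of the target.
#' @return list with `graph`, `target`, `sources`, `outgroups`.
#' @export
build_two_way_farmer_scenario <- function(alpha) {
  stopifnot(alpha > 0, alpha < 1)
  e <- function(p, c, l) data.frame(parent = p, child = c, length = l)
  rows <- rbind(
    e("Root", "O1", 0.045), e("Root", "C1", 0.008),
    e("C1", "O2", 0.045), e("C1", "C2", 0.008),
    e("C2", "O3", 0.045), e("C2", "C3", 0.008),
    e("C3", "O4", 0.045), e("C3", "D0", 0.008),
    e("D0", "pAF", 0.030), e("pAF", "O_AF", 0.040),
    e("D0", "pWest", 0.010),
    e("pWest", "pWHG", 0.025), e("pWHG", "O_WHG", 0.040),
    e("pWest", "pSteppe", 0.025), e("pSteppe", "O_Steppe", 0.040),
    e("pSteppe", "Eneolithic_steppe_like", 0.025),
    e("GA_mix", "Globular_Amphora_like", 0.020),
    e("T_mix", "Yamnaya_like", 0.010))
  admix <- list(
    list(child = "GA_mix", parents = c("pAF", "pWHG"), weights = c(0.70, 0.30)),
    list(child = "T_mix", parents = c("pSteppe", "GA_mix"),
         weights = c(1 - alpha, alpha)))
  g <- admixture_graph(rows, admix)
  list(graph = g, target = "Yamnaya_like",
       sources = c("Eneolithic_steppe_like", "Globular_Amphora_like"),
       outgroups = c("O1", "O2", "O3", "O4", "O_AF", "O_WHG", "O_Steppe"))
}
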