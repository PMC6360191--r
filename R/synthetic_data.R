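#' Simulation configuration
#'
#' Bundles the pieces of a genotype simulation: the admixture graph whose
#' drift parameters act as simulation truth, the panel size, the root
#' allele-frequency distribution (uniform on [0.05, 0.95] unless stated
#' otherwise), cohort sizes, missingness and ploidy.
#'
#' @param graph an [admixture_graph()]; edge lengths are Balding-Nichols
#'   F values.
#' @param n_snps number of biallelic SNPs (>= 1).
#' @param n_per_pop individuals per population; a single number or a
#'   named vector keyed by population.
#' @param missing_rate per-call missingness fraction in [0, 1).
#' @param ploidy_mode `"pseudo_haploid"` (default, as for low-coverage
#'   ancient cohorts) or `"diploid"`.
#' @param root_freq range of the uniform root frequency distribution.
#' @param n_chr,morgans_per_chr,bp_per_chr layout of the simulated panel
#'   across pseudo-chromosomes.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(graph, n_snps = 50000L, n_per_pop = 10L,
                       missing_rate = 0.05,
                       ploidy_mode = c("pseudo_haploid", "diploid"),
                       root_freq = c(0.05, 0.95), n_chr = 22L,
                       morgans_per_chr = 1, bp_per_chr = 1e8, seed = NULL) {
  stopifnot(n_snps >= 1L, missing_rate >= 0, missing_rate < 1,
            length(root_freq) == 2L, root_freq[1] < root_freq[2])
  structure(list(graph = graph, n_snps = as.integer(n_snps),
                 n_per_pop = n_per_pop, missing_rate = missing_rate,
                 ploidy_mode = match.arg(ploidy_mode), root_freq = root_freq,
                 n_chr = as.integer(n_chr), morgans_per_chr = morgans_per_chr,
                 bp_per_chr = bp_per_chr, seed = seed),
            class = "sim_config")
}

#' SNP metadata for a simulated panel
#'
#' Evenly spaces SNPs across pseudo-chromosomes with linearly increasing
#' genetic and physical positions.
#'
#' @inheritParams sim_config
#' @return SNP table as used by [genotype_matrix()].
#' @export
simulated_snp_table <- function(n_snps, n_chr = 22L, morgans_per_chr = 1,
                                bp_per_chr = 1e8) {
  chrom <- rep(seq_len(n_chr), length.out = n_snps)
  chrom <- sort(chrom)
  idx <- unlist(lapply(table(chrom), seq_len), use.names = FALSE)
  per <- as.vector(table(chrom))[chrom]
  frac <- (idx - 0.5) / per
  data.frame(snp_id = sprintf("snp_%06d", seq_len(n_snps)),
             chrom = as.character(chrom),
             gpos = frac * morgans_per_chr,
             ppos = as.integer(round(frac * bp_per_chr)) + 1L,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

# one Balding-Nichols drift step: child | parent ~ Beta with mean p and
# variance F p (1 - p); F below 1e-9 is treated as no drift.
bn_drift <- function(p, F) {
  if (F < 1e-9) return(p)
  out <- p
  inner <- p > 0 & p < 1
  a <- p[inner] * (1 - F) / F
  b <- (1 - p[inner]) * (1 - F) / F
  out[inner] <- stats::rbeta(sum(inner), a, b)
  pmin(pmax(out, 0), 1)
}

#' Simulate population allele frequencies along an admixture graph
#'
#' Root frequencies are drawn from the configured uniform distribution;
#' each drift edge applies a Balding-Nichols step with F equal to the
#' edge length; admixture nodes take the weighted mean of their parents'
#' frequencies. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return matrix (populations x SNPs) of alternative-allele frequencies
#'   for every node of the graph (leaves and internal).
#' @export
simulate_graph_frequencies <- function(config) {
  g <- config$graph
  with_seed(config$seed, {
    ns <- config$n_snps
    freq <- matrix(NA_real_, length(g$nodes), ns,
                   dimnames = list(g$nodes, NULL))
    freq[g$root, ] <- stats::runif(ns, config$root_freq[1], config$root_freq[2])
    adm_child <- vapply(g$admix, `[[`, "", "child")
    for (v in g$order) {
      if (v == g$root) next
      ai <- match(v, adm_child)
      if (!is.na(ai)) {
        a <- g$admix[[ai]]
        freq[v, ] <- colSums(freq[a$parents, , drop = FALSE] * a$weights)
      } else {
        ei <- which(g$edges$child == v)
        freq[v, ] <- bn_drift(freq[g$edges$parent[ei], ], g$edges$length[ei])
      }
    }
    freq
  })
}

#' Sample a genotype cohort from population allele frequencies
#'
#' Diploid mode draws Binomial(2, p) genotypes; pseudo-haploid mode draws
#' a single allele and doubles it. Missingness is applied independently
#' per call.
#'
#' @param freq matrix (populations x SNPs); rows for the sampled
#'   populations must be present.
#' @param config a [sim_config()]; `n_per_pop` may be a named vector to
#'   sample different cohort sizes per population.
#' @param pops populations to sample (default: graph leaves present in
#'   `freq`).
#' @param seed overrides `config$seed` when given.
#' @return a [genotype_matrix()].
#' @export
sample_genotypes <- function(freq, config, pops = NULL, seed = config$seed) {
  if (is.null(pops)) pops <- intersect(config$graph$leaves, rownames(freq))
  npp <- config$n_per_pop
  if (is.null(names(npp))) npp <- stats::setNames(rep(npp[1L], length(pops)), pops)
  with_seed(seed, {
    ns <- ncol(freq)
    snp <- simulated_snp_table(ns, config$n_chr, config$morgans_per_chr,
                               config$bp_per_chr)
    cols <- list(); labels <- character(0)
    for (p in pops) {
      fp <- freq[p, ]
      for (i in seq_len(npp[[p]])) {
        if (config$ploidy_mode == "pseudo_haploid") {
          gcall <- 2L * stats::rbinom(ns, 1L, fp)
        } else {
          gcall <- stats::rbinom(ns, 2L, fp)
        }
        if (config$missing_rate > 0) {
          gcall[stats::runif(ns) < config$missing_rate] <- NA_integer_
        }
        cols[[length(cols) + 1L]] <- gcall
        labels <- c(labels, p)
      }
    }
    geno <- do.call(cbind, cols)
    ind <- data.frame(sample_id = paste0(labels, "_", stats::ave(seq_along(labels),
                                                                 labels, FUN = seq_along)),
                      sex = "U", population = labels,
                      ploidy = if (config$ploidy_mode == "pseudo_haploid") 1L else 2L,
                      stringsAsFactors = FALSE)
    genotype_matrix(geno, snp, ind, config$ploidy_mode)
  })
}

#' Simulate mosaic haplotypes from a two-source admixture pulse
#'
#' Each haplotype is an ancestry mosaic of two source populations formed
#' g generations after a single admixture pulse: ancestry change points
#' are laid down by a Poisson process of rate g per Morgan and at each
#' change point (and at the chromosome start) the ancestry is drawn
#' afresh with probability `p_admix` for source 1. Within a segment,
#' alleles are Bernoulli draws from that source's frequency. This Markov
#' construction gives weighted LD decaying as exp(-g d).
#'
#' @param p_admix admixture fraction of source 1, in (0, 1).
#' @param g generations since admixture (>= 1).
#' @param map data.frame with `chrom` and `gpos` (Morgans) per SNP.
#' @param n_haplotypes number of haplotypes to simulate.
#' @param freq1,freq2 per-SNP allele frequencies of the two sources.
#' @param seed integer seed.
#' @return list of class `haplotype_set`: `haps` (n_haplotypes x n_snps
#'   0/1 matrix), `ancestry` (matching matrix of source labels 1/2),
#'   `map`, and the simulation parameters.
#' @export
simulate_admixture_ld <- function(p_admix, g, map, n_haplotypes,
                                  freq1, freq2, seed = NULL) {
  stopifnot(p_admix > 0, p_admix < 1, g >= 1)
  if (nrow(map) == 0L) stop("empty genetic map")
  with_seed(seed, {
    ns <- nrow(map)
    haps <- matrix(0L, n_haplotypes, ns)
    anc <- matrix(0L, n_haplotypes, ns)
    for (chr in unique(map$chrom)) {
      sidx <- which(map$chrom == chr)
      gp <- map$gpos[sidx]
      L <- max(gp)
      for (h in seq_len(n_haplotypes)) {
        nsw <- stats::rpois(1L, g * L)
        brk <- sort(stats::runif(nsw, 0, L))
        states <- stats::rbinom(nsw + 1L, 1L, p_admix)  # 1 = source 1
        seg <- findInterval(gp, brk) + 1L
        st <- states[seg]
        p <- ifelse(st == 1L, freq1[sidx], freq2[sidx])
        haps[h, sidx] <- stats::rbinom(length(sidx), 1L, p)
        anc[h, sidx] <- 2L - st
      }
    }
    structure(list(haps = haps, ancestry = anc, map = map,
                   p_admix = p_admix, g = g),
              class = "haplotype_set")
  })
}

#' Simulate chromosome-mapped read counts for sex assignment
#'
#' Autosomal read counts are Poisson with mean `depth` per target site;
#' X and Y counts scale with copy number (males: one X, one Y; females:
#' two X, zero Y) and with relative capture/mapping efficiencies, which
#' default to values that place simulated rate distributions where
#' published 1240K-capture cohorts sit. A small mismapping rate puts a
#' few reads on the Y of females.
#'
#' @param true_sexes character vector of `"M"`/`"F"`.
#' @param depth mean reads per autosomal target site (> 0).
#' @param n_auto,n_x,n_y number of targets per compartment (1240K-like
#'   defaults).
#' @param eff_x,eff_y capture/mapping efficiency of X and Y targets
#'   relative to autosomes.
#' @param mismap fraction of the per-site rate appearing on the Y of
#'   individuals without a Y chromosome.
#' @param seed integer seed.
#' @return data.frame with counts, X-rate and Y-rate per individual
#'   (rates are per-target ratios relative to autosomes).
#' @export
simulate_read_counts_sex <- function(true_sexes, depth, n_auto = 1150000L,
                                     n_x = 49704L, n_y = 32670L,
                                     eff_x = 0.75, eff_y = 0.65,
                                     mismap = 0.005, seed = NULL) {
  stopifnot(depth > 0)
  with_seed(seed, {
    n <- length(true_sexes)
    male <- true_sexes == "M"
    auto <- stats::rpois(n, depth * n_auto)
    x <- stats::rpois(n, depth * n_x * eff_x * ifelse(male, 0.5, 1))
    y <- stats::rpois(n, depth * n_y * ifelse(male, 0.5 * eff_y, mismap))
    data.frame(sample_id = sprintf("ind_%03d", seq_len(n)),
               true_sex = true_sexes, auto_reads = auto,
               x_reads = x, y_reads = y,
               x_rate = (x / n_x) / (auto / n_auto),
               y_rate = (y / n_y) / (auto / n_auto),
               stringsAsFactors = FALSE)
  })
}

#' Write a haplotype set as plain-text matrix plus sidecar map
#'
#' @param hs a `haplotype_set`.
#' @param prefix path prefix; `<prefix>.haps.tsv` and `<prefix>.map.tsv`
#'   are created.
#' @export
write_haplotypes <- function(hs, prefix) {
  utils::write.table(hs$haps, paste0(prefix, ".haps.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(hs$map, paste0(prefix, ".map.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
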