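#' Population allele frequencies from a genotype matrix
#'
#' Alternative-allele frequency and haploid sample size per population and
#' SNP. Pseudo-haploid individuals contribute one allele observation each,
#' diploid individuals two, so the recorded sizes are true counts of
#' independent allele draws and the finite-sample corrections downstream
#' remain valid for mixed cohorts.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping optional named character vector mapping `sample_id` to
#'   population; defaults to the `population` column of the `.ind` table.
#' @return object of class `freq_table`: list with `freq` and `size`
#'   matrices (populations x SNPs), the `snp` table, and `ploidy` flags
#'   per population.
#' @export
allele_frequencies <- function(gm, grouping = NULL) {
  if (is.null(grouping)) {
    pops <- gm$ind$population
  } else {
    pops <- unname(grouping[gm$ind$sample_id])
    if (anyNA(pops)) stop("grouping does not cover every individual")
  }
  upops <- unique(pops)
  ploidy <- gm$ind$ploidy
  if (is.null(ploidy)) ploidy <- if (gm$ploidy_mode == "pseudo_haploid") 1L else 2L
  ploidy <- rep(ploidy, length.out = nrow(gm$ind))
  ns <- nrow(gm$snp)
  freq <- matrix(NA_real_, length(upops), ns, dimnames = list(upops, NULL))
  size <- matrix(0, length(upops), ns, dimnames = list(upops, NULL))
  g <- gm$geno
  # per-individual alt-allele dose and allele count
  alt <- sweep(g, 2L, ifelse(ploidy == 1L, 2, 1), "/")
  cnt <- matrix(rep(ifelse(ploidy == 1L, 1, 2), each = ns), ns)
  cnt[is.na(g)] <- 0
  alt[is.na(g)] <- 0
  for (p in upops) {
    cols <- which(pops == p)
    if (!length(cols)) stop("population with zero individuals: ", p)
    a <- rowSums(alt[, cols, drop = FALSE])
    n <- rowSums(cnt[, cols, drop = FALSE])
    size[p, ] <- n
    freq[p, ] <- ifelse(n > 0, a / n, NA_real_)
  }
  has_ph <- vapply(upops, function(p) any(ploidy[pops == p] == 1L), TRUE)
  structure(list(freq = freq, size = size, snp = gm$snp,
                 pseudo_haploid = has_ph),
            class = "freq_table")
}

#' Assign SNPs to contiguous jackknife blocks
#'
#' Blocks are contiguous runs in (chromosome, position) and never span a
#' chromosome boundary. Genetic positions (Morgans) are used when
#' available and informative, with a default block span of 5 cM; a 5 Mb
#' physical fallback applies when all genetic positions are zero or
#' missing.
#'
#' @param snp SNP table (needs `chrom` and `gpos`/`ppos`).
#' @param block_cm genetic block span in centimorgans.
#' @param block_mb physical fallback span in megabases.
#' @return integer block id per SNP.
#' @export
make_blocks <- function(snp, block_cm = 5, block_mb = 5) {
  use_gen <- !all(is.na(snp$gpos) | snp$gpos == 0)
  pos <- if (use_gen) snp$gpos / (block_cm / 100) else snp$ppos / (block_mb * 1e6)
  key <- paste(snp$chrom, floor(pos), sep = ":")
  as.integer(factor(key, levels = unique(key)))
}

fstat_result <- function(stat, pops, jk) {
  data.frame(stat = stat, pops = paste(pops, collapse = ","),
             est = jk$est, se = jk$se, z = jk$z,
             n_blocks = jk$n_blocks, n_snps = jk$n_snps,
             stringsAsFactors = FALSE, row.names = NULL)
}

get_freq <- function(freqs, pop) {
  if (!pop %in% rownames(freqs$freq)) stop("population not in frequency table: ", pop)
  list(p = freqs$freq[pop, ], n = freqs$size[pop, ])
}

# unbiased estimate of p(1-p)/n_X, i.e. h_X / (2 n_X)
het_correction <- function(p, n) p * (1 - p) / (n - 1)

#' f2 statistic with block-jackknife standard error
#'
#' Mean over SNPs of \eqn{(a-b)^2} minus the finite-sample
#' heterozygosity corrections for both populations. `A == B` returns an
#' exact zero. SNPs lacking data in either population are excluded.
#'
#' @param A,B population labels.
#' @param freqs a `freq_table` from [allele_frequencies()].
#' @param blocks block ids from [make_blocks()].
#' @param correct apply the finite-sample bias correction (default TRUE).
#' @return one-row data.frame (stat, pops, est, se, z, n_blocks, n_snps).
#' @export
f2_stat <- function(A, B, freqs, blocks, correct = TRUE) {
  a <- get_freq(freqs, A); b <- get_freq(freqs, B)
  if (A == B) {
    num <- ifelse(is.na(a$p), NA_real_, 0)
  } else {
    num <- (a$p - b$p)^2
    if (correct) num <- num - het_correction(a$p, a$n) - het_correction(b$p, b$n)
  }
  fstat_result("f2", c(A, B), block_jackknife(num, NULL, blocks))
}

#' f3 statistic (admixture test) with block-jackknife standard error
#'
#' Mean over SNPs of \eqn{(c-a)(c-b)} minus the target's finite-sample
#' correction; significantly negative values indicate that the target C
#' is admixed between A- and B-related sources. The correction term uses
#' the haploid sample sizes recorded in the frequency table, which treats
#' pseudo-haploid individuals as single allele draws (the behaviour the
#' original tooling enables with its inbreed flag). A pseudo-haploid
#' target represented by a single individual has no defined correction
#' and is rejected.
#'
#' @param A,B source population labels.
#' @param C target population label.
#' @inheritParams f2_stat
#' @param inbreed treat the target's individuals as haploid allele draws
#'   (required for pseudo-haploid targets).
#' @export
f3_stat <- function(A, B, C, freqs, blocks, correct = TRUE, inbreed = TRUE) {
  a <- get_freq(freqs, A); b <- get_freq(freqs, B); cc <- get_freq(freqs, C)
  if (!inbreed && isTRUE(freqs$pseudo_haploid[C]))
    warning("inbreed = FALSE but target ", C,
            " is pseudo-haploid; correction still uses haploid sizes")
  num <- (cc$p - a$p) * (cc$p - b$p)
  if (correct) {
    usable <- !is.na(num)
    if (any(cc$n[usable] < 2))
      stop("target ", C, " has singleton coverage at some SNPs; ",
           "its f3 correction is undefined (single pseudo-haploid target?)")
    num <- num - het_correction(cc$p, cc$n)
  }
  fstat_result("f3", c(A, B, C), block_jackknife(num, NULL, blocks))
}

#' f4 statistic with block-jackknife standard error
#'
#' Mean over SNPs of \eqn{(a-b)(c-d)}; zero when (A,B) and (C,D) are
#' unrelated contrasts on a tree, i.e. an allele-sharing treeness test.
#' No finite-sample correction is needed.
#'
#' @param A,B,C,D population labels.
#' @inheritParams f2_stat
#' @export
f4_stat <- function(A, B, C, D, freqs, blocks) {
  a <- get_freq(freqs, A); b <- get_freq(freqs, B)
  cc <- get_freq(freqs, C); d <- get_freq(freqs, D)
  num <- (a$p - b$p) * (cc$p - d$p)
  fstat_result("f4", c(A, B, C, D), block_jackknife(num, NULL, blocks))
}

#' D statistic with block-jackknife standard error
#'
#' The normalized form of f4, the ratio of the summed numerator
#' \eqn{(a-b)(c-d)} to the summed normalizer
#' \eqn{(a+b-2ab)(c+d-2cd)}, bounded in [-1, 1]; the jackknife is taken
#' on the ratio.
#'
#' @inheritParams f4_stat
#' @export
d_stat <- function(A, B, C, D, freqs, blocks) {
  a <- get_freq(freqs, A); b <- get_freq(freqs, B)
  cc <- get_freq(freqs, C); d <- get_freq(freqs, D)
  num <- (a$p - b$p) * (cc$p - d$p)
  den <- (a$p + b$p - 2 * a$p * b$p) * (cc$p + d$p - 2 * cc$p * d$p)
  fstat_result("D", c(A, B, C, D), block_jackknife(num, den, blocks))
}

#' Admixture-f3 scan over all source pairs
#'
#' Evaluates f3(s1, s2; target) for every unordered pair from the source
#' pool; pairs with Z < -3 are flagged as significant evidence that the
#' target is admixed between the pair's related sources. Rows are sorted
#' by ascending Z.
#'
#' @param target target population.
#' @param source_pool candidate source populations (>= 2).
#' @inheritParams f2_stat
#' @param z_threshold significance threshold on Z (default -3).
#' @export
admixture_f3_scan <- function(target, source_pool, freqs, blocks,
                              z_threshold = -3) {
  stopifnot(length(source_pool) >= 2L)
  prs <- utils::combn(source_pool, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(k)
    f3_stat(prs[1L, k], prs[2L, k], target, freqs, blocks))
  out <- do.call(rbind, rows)
  out$significant <- out$z < z_threshold
  out[order(out$z), , drop = FALSE]
}

#' f4 affinity scan over candidate populations
#'
#' Evaluates f4(outgroup, X; pop1, pop2) for every candidate X, the scan
#' used to detect which outside lineages share excess alleles with pop1
#' versus pop2. Candidates with |Z| > 3 are flagged, with the sign
#' indicating the direction of attraction.
#'
#' @param outgroup fixed first population.
#' @param fixed_pair character vector of the two right-hand populations.
#' @param candidates candidate X populations.
#' @inheritParams f2_stat
#' @param z_threshold |Z| flag threshold (default 3).
#' @export
f4_affinity_scan <- function(outgroup, fixed_pair, candidates, freqs, blocks,
                             z_threshold = 3) {
  stopifnot(length(fixed_pair) == 2L)
  rows <- lapply(candidates, function(x)
    f4_stat(outgroup, x, fixed_pair[1L], fixed_pair[2L], freqs, blocks))
  out <- do.call(rbind, rows)
  out$candidate <- candidates
  out$significant <- abs(out$z) > z_threshold
  out[order(-abs(out$z)), , drop = FALSE]
}

#' All-pairs observed f2 table for graph fitting
#'
#' @param pops populations to include.
#' @inheritParams f2_stat
#' @return data.frame (pop1, pop2, est, se).
#' @export
observed_f2_table <- function(pops, freqs, blocks) {
  prs <- utils::combn(pops, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    r <- f2_stat(prs[1L, k], prs[2L, k], freqs, blocks)
    data.frame(pop1 = prs[1L, k], pop2 = prs[2L, k], est = r$est, se = r$se)
  })
  do.call(rbind, rows)
}
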