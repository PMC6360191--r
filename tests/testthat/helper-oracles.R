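# Independent brute-force oracles for the f-statistic engine, written as
# plain loops straight from the per-SNP definitions. These deliberately
# share no code with the package internals.

make_freq_table <- function(freq, size, snp = NULL) {
  if (is.null(snp)) snp <- simulated_snp_table(ncol(freq), n_chr = 2L)
  structure(list(freq = freq, size = size, snp = snp,
                 pseudo_haploid = stats::setNames(rep(FALSE, nrow(freq)),
                                                  rownames(freq))),
            class = "freq_table")
}

# weighted delete-one-block jackknife of a per-SNP mean or ratio, naive
oracle_jackknife <- function(num, den = NULL, blocks) {
  keep <- is.finite(num)
  if (!is.null(den)) keep <- keep & is.finite(den)
  num <- num[keep]; blocks <- blocks[keep]
  den <- if (is.null(den)) rep(1, length(num)) else den[keep]
  ub <- unique(blocks)
  g <- length(ub)
  n <- length(num)
  est <- sum(num) / sum(den)
  loo <- numeric(g); m <- numeric(g)
  for (k in seq_len(g)) {
    inb <- blocks == ub[k]
    m[k] <- sum(inb)
    loo[k] <- sum(num[!inb]) / sum(den[!inb])
  }
  h <- n / m
  theta_jack <- g * est - sum((1 - m / n) * loo)
  v <- 0
  for (k in seq_len(g)) {
    tau <- h[k] * est - (h[k] - 1) * loo[k]
    v <- v + (tau - theta_jack)^2 / (h[k] - 1)
  }
  list(est = est, se = sqrt(v / g))
}

oracle_f2 <- function(A, B, ft, blocks) {
  a <- ft$freq[A, ]; b <- ft$freq[B, ]
  na <- ft$size[A, ]; nb <- ft$size[B, ]
  num <- (a - b)^2 - a * (1 - a) / (na - 1) - b * (1 - b) / (nb - 1)
  oracle_jackknife(num, NULL, blocks)
}

oracle_f3 <- function(A, B, C, ft, blocks) {
  a <- ft$freq[A, ]; b <- ft$freq[B, ]; cc <- ft$freq[C, ]
  nc <- ft$size[C, ]
  num <- (cc - a) * (cc - b) - cc * (1 - cc) / (nc - 1)
  oracle_jackknife(num, NULL, blocks)
}

oracle_f4 <- function(A, B, C, D, ft, blocks) {
  num <- (ft$freq[A, ] - ft$freq[B, ]) * (ft$freq[C, ] - ft$freq[D, ])
  oracle_jackknife(num, NULL, blocks)
}

oracle_d <- function(A, B, C, D, ft, blocks) {
  a <- ft$freq[A, ]; b <- ft$freq[B, ]
  cc <- ft$freq[C, ]; d <- ft$freq[D, ]
  num <- (a - b) * (cc - d)
  den <- (a + b - 2 * a * b) * (cc + d - 2 * cc * d)
  oracle_jackknife(num, den, blocks)
}

# random small frequency fixture: 4 populations x n SNPs, 3 blocks
random_freq_fixture <- function(n = 5L, seed = 42L) {
  set.seed(seed)
  pops <- c("A", "B", "C", "D")
  freq <- matrix(runif(4 * n, 0.1, 0.9), 4, n, dimnames = list(pops, NULL))
  size <- matrix(sample(4:20, 4 * n, replace = TRUE), 4, n,
                 dimnames = list(pops, NULL))
  list(ft = make_freq_table(freq, size),
       blocks = rep_len(1:3, n))
}

# small genotype fixture shared by the I/O tests
small_genotype_fixture <- function() {
  snp <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                    chrom = c("1", "1", "2"),
                    gpos = c(0.01, 0.02, 0.005),
                    ppos = c(100L, 2000L, 500L),
                    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                    stringsAsFactors = FALSE)
  ind <- data.frame(sample_id = c("s1", "s2"), sex = c("M", "F"),
                    population = c("P1", "P2"), stringsAsFactors = FALSE)
  geno <- matrix(c(0L, 2L, 1L, NA, 2L, 0L), nrow = 3, byrow = TRUE)
  genotype_matrix(geno, snp, ind, "diploid")
}
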