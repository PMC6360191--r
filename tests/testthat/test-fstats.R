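test_that("allele frequencies count haploid draws correctly", {
  snp <- simulated_snp_table(2L, n_chr = 1L)
  # one diploid het + two pseudo-haploid individuals with calls (0, 2)
  ind <- data.frame(sample_id = c("d1", "p1", "p2"), sex = "U",
                    population = c("Pd", "Pp", "Pp"),
                    ploidy = c(2L, 1L, 1L))
  geno <- matrix(c(1L, 0L, 2L,
                   2L, 2L, NA), nrow = 2, byrow = TRUE)
  gm <- genotype_matrix(geno, snp, ind, "mixed")
  ft <- allele_frequencies(gm)
  expect_equal(unname(ft$freq["Pd", 1]), 0.5)
  expect_equal(unname(ft$size["Pd", 1]), 2)
  expect_equal(unname(ft$freq["Pp", 1]), 0.5)   # pseudo-haploid calls 0 and 2
  expect_equal(unname(ft$size["Pp", 1]), 2)
  expect_equal(unname(ft$freq["Pp", 2]), 1)     # one missing call drops out
  expect_equal(unname(ft$size["Pp", 2]), 1)
  expect_equal(unname(ft$freq["Pd", 2]), 1)
})

test_that("f-statistics equal the brute-force per-SNP oracle to 1e-12", {
  fx <- random_freq_fixture(n = 5L, seed = 42L)
  ft <- fx$ft; bl <- fx$blocks
  r <- f2_stat("A", "B", ft, bl); o <- oracle_f2("A", "B", ft, bl)
  expect_equal(r$est, o$est, tolerance = 1e-12)
  expect_equal(r$se, o$se, tolerance = 1e-12)
  r <- f3_stat("A", "B", "C", ft, bl); o <- oracle_f3("A", "B", "C", ft, bl)
  expect_equal(r$est, o$est, tolerance = 1e-12)
  expect_equal(r$se, o$se, tolerance = 1e-12)
  r <- f4_stat("A", "B", "C", "D", ft, bl)
  o <- oracle_f4("A", "B", "C", "D", ft, bl)
  expect_equal(r$est, o$est, tolerance = 1e-12)
  expect_equal(r$se, o$se, tolerance = 1e-12)
  r <- d_stat("A", "B", "C", "D", ft, bl)
  o <- oracle_d("A", "B", "C", "D", ft, bl)
  expect_equal(r$est, o$est, tolerance = 1e-12)
  expect_equal(r$se, o$se, tolerance = 1e-12)
})

test_that("f-statistic identities hold exactly on fixtures", {
  fx <- random_freq_fixture(n = 24L, seed = 9L)
  ft <- fx$ft; bl <- fx$blocks
  f4 <- function(...) f4_stat(..., freqs = ft, blocks = bl)$est
  expect_equal(f4("A", "B", "C", "D"), -f4("B", "A", "C", "D"))
  expect_equal(f4("A", "B", "C", "D"), -f4("A", "B", "D", "C"))
  expect_equal(f4("A", "B", "C", "D"), f4("C", "D", "A", "B"))
  expect_identical(f4("A", "B", "C", "C"), 0)           # degenerate quadruple
  expect_identical(f2_stat("A", "A", ft, bl)$est, 0)    # identity case
  expect_equal(f2_stat("A", "B", ft, bl)$est, f2_stat("B", "A", ft, bl)$est)
  # uncorrected f2 is a mean of squares, hence non-negative
  expect_gte(f2_stat("A", "B", ft, bl, correct = FALSE)$est, 0)
  expect_identical(d_stat("A", "A", "C", "D", ft, bl)$est, 0)
})

test_that("D equals 1 for a maximally tree-like configuration", {
  freq <- rbind(A = rep(1, 12), B = rep(0, 12), C = rep(1, 12), D = rep(0, 12))
  size <- matrix(10, 4, 12, dimnames = list(c("A", "B", "C", "D"), NULL))
  ft <- make_freq_table(freq, size)
  expect_equal(d_stat("A", "B", "C", "D", ft, rep_len(1:3, 12))$est, 1)
})

test_that("jackknife SE matches the analytic SE on i.i.d. blocks", {
  set.seed(11)
  n <- 10000L; pops <- c("A", "B", "C", "D")
  freq <- matrix(runif(4 * n, 0.2, 0.8), 4, n, dimnames = list(pops, NULL))
  size <- matrix(50, 4, n, dimnames = list(pops, NULL))
  ft <- make_freq_table(freq, size)
  blocks <- rep(1:100, each = 100)
  r <- f4_stat("A", "B", "C", "D", ft, blocks)
  contrib <- (freq["A", ] - freq["B", ]) * (freq["C", ] - freq["D", ])
  analytic <- sd(contrib) / sqrt(n)
  expect_lt(abs(r$se - analytic) / analytic, 0.20)
})

test_that("singleton pseudo-haploid f3 targets are rejected", {
  pops <- c("A", "B", "C")
  freq <- matrix(runif(30, 0.2, 0.8), 3, 10, dimnames = list(pops, NULL))
  size <- matrix(10, 3, 10, dimnames = list(pops, NULL))
  size["C", ] <- 1
  ft <- make_freq_table(freq, size)
  expect_error(f3_stat("A", "B", "C", ft, rep_len(1:2, 10)), "singleton")
})

test_that("admixture-f3 scan flags a simulated two-way mixture", {
  e <- function(p, c, l) data.frame(parent = p, child = c, length = l)
  edges <- rbind(e("R", "pP1", 0.08), e("pP1", "P1", 0.001),
                 e("R", "pP2", 0.08), e("pP2", "P2", 0.001),
                 e("R", "O", 0.05), e("Tm", "T", 0.001))
  g <- admixture_graph(edges, list(list(child = "Tm", parents = c("pP1", "pP2"),
                                        weights = c(0.5, 0.5))))
  cfg <- sim_config(g, n_snps = 50000L, n_per_pop = 10L, seed = 21L)
  fr <- simulate_graph_frequencies(cfg)
  gm <- sample_genotypes(fr, cfg, seed = 22L)
  ft <- allele_frequencies(gm); bl <- make_blocks(gm$snp)
  scan <- admixture_f3_scan("T", c("P1", "P2", "O"), ft, bl)
  top <- scan[1, ]
  expect_true(top$significant)
  expect_setequal(strsplit(top$pops, ",")[[1]][1:2], c("P1", "P2"))
  # an unadmixed leaf as target shows no significant pair
  scan0 <- admixture_f3_scan("P1", c("P2", "O", "T"), ft, bl)
  expect_false(any(scan0$significant))
})

test_that("f4 affinity scan separates attracted from symmetric candidates", {
  e <- function(p, c, l) data.frame(parent = p, child = c, length = l)
  # T shares extra drift with X via an admixture pulse; Y is symmetric
  edges <- rbind(e("R", "O", 0.08), e("R", "I1", 0.01),
                 e("I1", "Y", 0.05),
                 e("I1", "pX", 0.03), e("pX", "X", 0.03),
                 e("I1", "I2", 0.01),
                 e("I2", "pRef", 0.02), e("pRef", "Ref", 0.02),
                 e("Tm", "T", 0.01))
  g <- admixture_graph(edges, list(list(child = "Tm",
                                        parents = c("pRef", "pX"),
                                        weights = c(0.7, 0.3))))
  cfg <- sim_config(g, n_snps = 50000L, n_per_pop = 10L, seed = 31L)
  fr <- simulate_graph_frequencies(cfg)
  gm <- sample_genotypes(fr, cfg, seed = 32L)
  ft <- allele_frequencies(gm); bl <- make_blocks(gm$snp)
  scan <- f4_affinity_scan("O", c("T", "Ref"), c("X", "Y"), ft, bl)
  x_row <- scan[scan$candidate == "X", ]
  y_row <- scan[scan$candidate == "Y", ]
  expect_true(x_row$significant)
  expect_gt(abs(x_row$z), abs(y_row$z))
  # a candidate symmetric to the fixed pair stays near zero
  expect_false(y_row$significant)
})
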