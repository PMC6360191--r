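test_that("EIGENSTRAT write/read round-trips and is byte-stable", {
  gm <- small_genotype_fixture()
  pre <- file.path(tempdir(), "fix1")
  write_eigenstrat(gm, pre)
  back <- read_eigenstrat(paste0(pre, ".geno"), paste0(pre, ".snp"),
                          paste0(pre, ".ind"))
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_identical(back$snp$snp_id, gm$snp$snp_id)
  expect_identical(back$ind$population, gm$ind$population)
  pre2 <- file.path(tempdir(), "fix2")
  write_eigenstrat(back, pre2)
  expect_identical(readLines(paste0(pre, ".geno")),
                   readLines(paste0(pre2, ".geno")))
})

test_that("geno digits map directly, 9 meaning missing", {
  d <- tempdir()
  writeLines("209", file.path(d, "m.geno"))
  writeLines("rs1 1 0.01 100 A G", file.path(d, "m.snp"))
  writeLines(c("a U P", "b U P", "c U P"), file.path(d, "m.ind"))
  gm <- read_eigenstrat(file.path(d, "m.geno"), file.path(d, "m.snp"),
                        file.path(d, "m.ind"))
  expect_identical(as.vector(gm$geno), c(2L, 0L, NA))
})

test_that("malformed EIGENSTRAT input raises informative errors", {
  d <- tempdir()
  writeLines(c("201"), file.path(d, "e.geno"))
  writeLines("rs1 1 0.01 100 A G", file.path(d, "e.snp"))
  writeLines(c("a U P", "b U P", "c U P", "dd U P"), file.path(d, "e.ind"))
  expect_error(read_eigenstrat(file.path(d, "e.geno"), file.path(d, "e.snp"),
                               file.path(d, "e.ind")), "width")
  writeLines(c("2x1"), file.path(d, "e.geno"))
  writeLines(c("a U P", "b U P", "c U P"), file.path(d, "e.ind"))
  expect_error(read_eigenstrat(file.path(d, "e.geno"), file.path(d, "e.snp"),
                               file.path(d, "e.ind")), "parse error")
})

test_that("writing degenerate or invariant-violating matrices errors", {
  gm <- small_genotype_fixture()
  empty <- gm
  empty$geno <- gm$geno[, 0, drop = FALSE]
  empty$ind <- gm$ind[0, , drop = FALSE]
  expect_error(write_eigenstrat(empty, tempfile()), "empty")
  expect_error(
    genotype_matrix(matrix(1L, 1, 1),
                    data.frame(snp_id = "r", chrom = "1", gpos = 0, ppos = 1,
                               ref = "A", alt = "G"),
                    data.frame(sample_id = "x", sex = "U", population = "P"),
                    "pseudo_haploid"),
    "heterozygous")
})

test_that("pseudo-haploid calling follows the single-read-draw model", {
  snp <- simulated_snp_table(3L, n_chr = 1L)
  ind <- data.frame(sample_id = "s", sex = "U", population = "P")
  ref <- matrix(c(5L, 0L, 1L), 3, 1)
  alt <- matrix(c(0L, 0L, 1L), 3, 1)
  gm <- pseudo_haploid_call(ref, alt, snp, ind, seed = 1)
  expect_identical(gm$geno[1, 1], 0L)       # monomorphic pile
  expect_true(is.na(gm$geno[2, 1]))         # zero coverage
  expect_error(pseudo_haploid_call(-ref, alt, snp, ind), "non-negative")
  # binomial oracle: a 1:1 pile is called alt half the time
  snp1 <- simulated_snp_table(10000L, n_chr = 1L)
  r <- matrix(1L, 10000, 1); a <- matrix(1L, 10000, 1)
  gm2 <- pseudo_haploid_call(r, a, snp1, ind, seed = 7)
  frac_alt <- mean(gm2$geno == 2L)
  expect_lt(abs(frac_alt - 0.5), 0.02)
  gm3 <- pseudo_haploid_call(r, a, snp1, ind, seed = 7)
  expect_identical(gm2$geno, gm3$geno)      # deterministic given seed
})

test_that("merge intersects SNPs, reconciles alleles and flags duplicates", {
  gm <- small_genotype_fixture()
  other <- gm
  other$ind$sample_id <- c("t1", "t2")
  doubled <- merge_datasets(list(gm, other))
  expect_equal(ncol(doubled$geno), 4L)
  expect_identical(doubled$snp$snp_id, gm$snp$snp_id)
  expect_error(merge_datasets(list(gm, gm)), "duplicate sample_id")

  # shared subset of SNPs
  sub <- gm
  sub$geno <- gm$geno[1:2, , drop = FALSE]
  sub$snp <- gm$snp[1:2, , drop = FALSE]
  sub$ind$sample_id <- c("u1", "u2")
  m <- merge_datasets(list(gm, sub))
  expect_identical(m$snp$snp_id, c("rs1", "rs2"))

  # swapped ref/alt at rs1 complements the second dataset's calls
  sw <- gm
  sw$ind$sample_id <- c("v1", "v2")
  sw$snp$ref[1] <- gm$snp$alt[1]; sw$snp$alt[1] <- gm$snp$ref[1]
  mf <- merge_datasets(list(gm, sw))
  expect_identical(unname(mf$geno[1, 3:4]), unname(2L - gm$geno[1, ]))
  expect_identical(unname(mf$geno[2, 3:4]), unname(gm$geno[2, ]))

  # strand-ambiguous mismatch (A/T SNP listed swapped) is dropped
  amb <- gm
  amb$ind$sample_id <- c("w1", "w2")
  amb$snp$ref[3] <- "T"; amb$snp$alt[3] <- "A"
  base <- gm; base$snp$ref[3] <- "A"; base$snp$alt[3] <- "T"
  ma <- merge_datasets(list(base, amb))
  expect_false("rs3" %in% ma$snp$snp_id)
  expect_equal(attr(ma, "merge_report")$n_dropped[2], 1L)
})

test_that("merge is associative up to individual order", {
  gm <- small_genotype_fixture()
  g2 <- gm; g2$ind$sample_id <- c("x1", "x2")
  g3 <- gm; g3$ind$sample_id <- c("y1", "y2")
  left <- merge_datasets(list(merge_datasets(list(gm, g2)), g3))
  right <- merge_datasets(list(gm, merge_datasets(list(g2, g3))))
  expect_identical(left$geno[, sort(colnames(left$geno))],
                   right$geno[, sort(colnames(right$geno))])
})

test_that("SNP-count filter applies the 30,000-site cutoff exactly", {
  set.seed(3)
  n_snps <- 40000L
  snp <- simulated_snp_table(n_snps)
  # 59-individual cohort, 14 of which fall below the cutoff
  n_called <- c(rep(35000L, 45L), rep(25000L, 13L), 29999L)
  geno <- matrix(0L, n_snps, 59L)
  for (i in 1:59) geno[seq_len(n_snps - n_called[i]), i] <- NA_integer_
  ind <- data.frame(sample_id = sprintf("s%02d", 1:59), sex = "U",
                    population = "P")
  gm <- genotype_matrix(geno, snp, ind, "diploid")
  res <- filter_by_snp_count(gm, 30000L)
  expect_equal(ncol(res$matrix$geno), 45L)
  expect_false(res$report$retained[59])     # 29,999 sites: removed
  ident <- filter_by_snp_count(gm, 0L)
  expect_equal(ncol(ident$matrix$geno), 59L)
})
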