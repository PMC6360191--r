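#!/usr/bin/env Rscript
# f-statistic scans on the simulated cohort: which targets are admixed,
# and which outside lineages share excess alleles with Maykop relative to
# the Eneolithic steppe.
#
# Reads the cohort written by 01_simulate_cohort.R.

suppressPackageStartupMessages(library(steppeadmix))

gm <- read_eigenstrat("results/analysis/cohort.geno",
                      "results/analysis/cohort.snp",
                      "results/analysis/cohort.ind", "pseudo_haploid")
freqs <- allele_frequencies(gm)
blocks <- make_blocks(gm$snp)

# admixture f3: the Eneolithic steppe as an EHG+CHG mixture
scan_es <- admixture_f3_scan("Eneolithic_steppe",
                             c("EHG", "CHG", "Loschbour", "MA1", "Mbuti"),
                             freqs, blocks)
write.table(scan_es, "results/analysis/f3_scan_eneolithic_steppe.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- scan_es[1, ]
cat(sprintf("Eneolithic steppe admixture f3: best pair %s, Z = %.1f (%s)\n",
            top$pops, top$z,
            if (top$significant) "significant, Z < -3" else "not significant"))

# f4 affinity: which lineages are attracted to Yamnaya_Caucasus relative
# to the Eneolithic steppe (the farmer-related pull)
scan_f4 <- f4_affinity_scan("Mbuti", c("Yamnaya_Caucasus", "Eneolithic_steppe"),
                            c("Globular_Amphora", "Anatolian_farmers",
                              "CHG", "MA1", "Loschbour"),
                            freqs, blocks)
write.table(scan_f4, "results/analysis/f4_scan_yamnaya.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("f4(Mbuti, X; Yamnaya_Caucasus, Eneolithic_steppe) — significant X:\n")
sig <- scan_f4[scan_f4$significant, ]
for (i in seq_len(nrow(sig)))
  cat(sprintf("  %s: Z = %.1f\n", sig$candidate[i], sig$z[i]))

# D statistic sanity: treeness of an unadmixed quadruple
d <- d_stat("Mbuti", "Loschbour", "CHG", "Anatolian_farmers", freqs, blocks)
cat(sprintf("D(Mbuti, Loschbour; CHG, Anatolian_farmers) = %.4f (Z = %.1f)\n",
            d$est, d$z))
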