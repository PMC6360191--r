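#!/usr/bin/env Rscript
# Simulate the package's default Caucasus/steppe world and run sample QC.
#
# The cohort is drawn from the joint admixture graph of Mbuti, Loschbour,
# MA1, EHG, CHG, Anatolian farmers, Globular Amphora, Eneolithic steppe,
# Maykop and Yamnaya_Caucasus, with pseudo-haploid calls and 5%
# missingness — the shape of a real 1240K-capture ancient cohort.
# Writes the EIGENSTRAT trio plus sex and kinship QC reports.

suppressPackageStartupMessages(library(steppeadmix))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

graph <- fig5_graph()
cfg <- sim_config(graph, n_snps = 50000L, n_per_pop = 10L,
                  missing_rate = 0.05, seed = 101L)
freq <- simulate_graph_frequencies(cfg)
gm <- sample_genotypes(freq, cfg, seed = 102L)
write_eigenstrat(gm, "results/analysis/cohort")
cat(sprintf("simulated cohort: %d SNPs x %d individuals from %d populations\n",
            nrow(gm$snp), nrow(gm$ind), length(unique(gm$ind$population))))

# genetic sex from simulated chromosome-mapped read counts
rc <- simulate_read_counts_sex(rep(c("M", "F"), 10L), depth = 0.1, seed = 103L)
sex <- assign_sex(rc)
write.table(sex, "results/analysis/sex_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("sex assignment: %d/%d correct calls, %d undetermined\n",
            sum(sex$call == rc$true_sex), nrow(sex), sum(sex$call == "U")))

# coverage filter at the 30,000-SNP cutoff (all simulated samples pass
# at 5% missingness; the report documents per-sample counts)
flt <- filter_by_snp_count(gm, 30000L)
write.table(flt$report, "results/analysis/snp_count_filter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("coverage filter: %d of %d individuals retained (>= 30,000 SNPs)\n",
            sum(flt$report$retained), nrow(flt$report)))

# pairwise kinship within one population (all unrelated by construction)
sub <- gm
keep <- gm$ind$population == "Maykop"
sub$geno <- gm$geno[, keep]; sub$ind <- gm$ind[keep, ]
kin <- kinship_mismatch(sub)
write.table(kin, "results/analysis/kinship.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("kinship: %d pairs, %d classified unrelated (expected all)\n",
            nrow(kin), sum(kin$classification == "unrelated")))
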