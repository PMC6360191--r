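#!/usr/bin/env Rscript
# Admixture-graph fitting: recover the default graph's admixture
# proportions (Maykop = 86.4% CHG + 9.6% farmer + 4% EHG;
# Yamnaya_Caucasus = 16% Globular-Amphora-related) from a cohort
# simulated under that graph, and demonstrate the grafting search.

suppressPackageStartupMessages(library(steppeadmix))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

graph <- fig5_graph()
cfg <- sim_config(graph, n_snps = 100000L, n_per_pop = 10L, seed = 401L)
fr <- simulate_graph_frequencies(cfg)
gm <- sample_genotypes(fr, cfg, seed = 402L)
freqs <- allele_frequencies(gm)
blocks <- make_blocks(gm$snp)

topo <- fig5_fit_topology()
f2o <- observed_f2_table(topo$leaves, freqs, blocks)
fit <- fit_graph(topo, f2o, n_restarts = 20L, seed = 403L)
write_graph(fit$graph, "results/analysis/fitted_graph.txt")
write.table(fit$residuals, "results/analysis/graph_residuals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("graph fit: score %.1f, worst f2 residual |Z| = %.2f\n",
            fit$score, fit$worst_z))
rz <- graph_residuals(fit, freqs, blocks, stats = c("f2", "f4"))
cat(sprintf("worst |Z| over f2 and f4 residuals: %.2f (accepted: %s)\n",
            rz$worst_z, rz$worst_z <= 3))
cat("recovered ancestry contributions (truth in brackets):\n")
cat(sprintf("  CHG -> Maykop: %.1f%% [86.4]\n",
            100 * ancestry_contribution(fit$graph, "Maykop", "pCHG")))
cat(sprintf("  Anatolian farmer -> Maykop: %.1f%% [9.6]\n",
            100 * ancestry_contribution(fit$graph, "Maykop", "pAF")))
cat(sprintf("  EHG -> Maykop: %.1f%% [4.0]\n",
            100 * ancestry_contribution(fit$graph, "Maykop", "EHG_mix")))
cat(sprintf("  Globular Amphora -> Yamnaya_Caucasus: %.1f%% [16.0]\n",
            100 * ancestry_contribution(fit$graph, "Yamnaya_Caucasus",
                                        "GA_mix")))

# grafting demonstration: re-attach EHG to a skeleton of the deep leaves
skeleton_pops <- c("Mbuti", "Loschbour", "MA1", "CHG")
sk_fit <- fit_graph(
  admixture_graph(data.frame(
    parent = c("Root", "Root", "nonAfr", "nonAfr", "W", "W"),
    child = c("Mbuti", "nonAfr", "CHG", "W", "Loschbour", "MA1"),
    length = rep(0.05, 6))),
  observed_f2_table(skeleton_pops, freqs, blocks), n_restarts = 2L, seed = 404L)
res <- graft_search(sk_fit$graph, "EHG", freqs, blocks, try_admixture = TRUE,
                    n_restarts = 5L, seed = 405L, max_survivors = 3L)
cat(sprintf("\ngraft search for EHG: %d surviving attachments; best: %s\n",
            length(res$survivors),
            if (length(res$survivors)) res$survivors[[1]]$attach else "none"))
write.table(res$trace, "results/analysis/graft_trace.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
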