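#' Run a configuration-driven analysis pipeline
#'
#' Executes the package's stages in dependency order — data (simulation
#' or EIGENSTRAT input), sample QC, f-statistic scans, qpAdm-style
#' models, graph fitting and admixture dating — writing one
#' tab-separated report per requested stage plus a machine-readable run
#' manifest (package version, seeds, file digests). Identical config and
#' seed give identical outputs. A failing stage aborts its dependents
#' but leaves independent stages to complete; the manifest records the
#' per-stage status.
#'
#' @param config a nested list, or path to a JSON file with the same
#'   structure. Recognized blocks: `simulate` (fields `scenario` =
#'   `"fig5"` or a graph file path, `n_snps`, `n_per_pop`,
#'   `missing_rate`), `input` (EIGENSTRAT `geno`/`snp`/`ind` paths and
#'   `ploidy`), `qc_sex` (`n`, `depth`), `qc_kin` (`window_bp`),
#'   `f3_scan` (`target`, `sources`), `f4_scan` (`outgroup`,
#'   `fixed_pair`, `candidates`), `qpadm` (list of models with `target`,
#'   `sources`, `outgroups`), `graph_fit` (`topology` = `"fig5"` or a
#'   graph file), `dating` (`p_admix`, `g`, `n_haplotypes`, `n_snps`,
#'   `map_cm`). Top-level fields: `seed` (required), `output_dir`.
#' @return the manifest, invisibly; reports are written to `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$seed)) stop("config must set an explicit seed")
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir %||% "steppeadmix_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "steppeadmix",
                   version = as.character(utils::packageVersion("steppeadmix")),
                   seed = seed, stages = list(), outputs = character(0))
  write_report <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    manifest$stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$error)
    if (res$ok) res$value else NULL
  }

  gm <- NULL
  if (!is.null(config$simulate)) {
    gm <- stage("simulate", {
      sc <- config$simulate
      graph <- if (identical(sc$scenario %||% "fig5", "fig5")) fig5_graph()
               else read_graph(sc$scenario)
      cfg <- sim_config(graph,
                        n_snps = sc$n_snps %||% 20000L,
                        n_per_pop = sc$n_per_pop %||% 10L,
                        missing_rate = sc$missing_rate %||% 0.05,
                        seed = derive_seed(seed, 1L))
      freq <- simulate_graph_frequencies(cfg)
      g <- sample_genotypes(freq, cfg, seed = derive_seed(seed, 2L))
      write_eigenstrat(g, file.path(out_dir, "simulated"))
      g
    })
  } else if (!is.null(config$input)) {
    gm <- stage("input", {
      with(config$input, read_eigenstrat(geno, snp, ind, ploidy %||% "diploid"))
    })
  }

  if (!is.null(config$qc_sex)) {
    stage("qc_sex", {
      qs <- config$qc_sex
      n <- qs$n %||% 20L
      sexes <- rep(c("M", "F"), length.out = n)
      rc <- simulate_read_counts_sex(sexes, qs$depth %||% 0.1,
                                     seed = derive_seed(seed, 3L))
      write_report(assign_sex(rc), "sex_assignments")
    })
  }

  freqs <- NULL; blocks <- NULL
  if (!is.null(gm)) {
    freqs <- allele_frequencies(gm)
    blocks <- make_blocks(gm$snp)
  }
  needs_data <- function(name) {
    if (is.null(freqs)) {
      manifest$stages[[name]] <<- "skipped: no genotype data (dependency failed)"
      FALSE
    } else TRUE
  }

  if (!is.null(config$f3_scan) && needs_data("f3_scan")) {
    stage("f3_scan", {
      fs <- config$f3_scan
      write_report(admixture_f3_scan(fs$target, unlist(fs$sources), freqs, blocks),
                   "f3_scan")
    })
  }
  if (!is.null(config$f4_scan) && needs_data("f4_scan")) {
    stage("f4_scan", {
      fs <- config$f4_scan
      write_report(f4_affinity_scan(fs$outgroup, unlist(fs$fixed_pair),
                                    unlist(fs$candidates), freqs, blocks),
                   "f4_scan")
    })
  }
  if (!is.null(config$qpadm) && needs_data("qpadm")) {
    stage("qpadm", {
      models <- config$qpadm
      if (!is.null(models$target)) models <- list(models)
      rows <- lapply(models, function(m) {
        fit <- qpadm_estimate(m$target, unlist(m$sources), unlist(m$outgroups),
                              freqs, blocks)
        data.frame(target = m$target,
                   sources = paste(fit$sources, collapse = ","),
                   weights = paste(sprintf("%.4f", fit$weights), collapse = ","),
                   se = paste(sprintf("%.4f", fit$se), collapse = ","),
                   p_rank = fit$p_rank, feasible = fit$feasible)
      })
      write_report(do.call(rbind, rows), "qpadm_models")
    })
  }
  if (!is.null(config$graph_fit) && needs_data("graph_fit")) {
    stage("graph_fit", {
      gf <- config$graph_fit
      topo <- if (identical(gf$topology %||% "fig5", "fig5")) fig5_fit_topology()
              else read_graph(gf$topology)
      f2o <- observed_f2_table(topo$leaves, freqs, blocks)
      fit <- fit_graph(topo, f2o, n_restarts = gf$n_restarts %||% 10L,
                       seed = derive_seed(seed, 4L))
      write_graph(fit$graph, file.path(out_dir, "fitted_graph.txt"))
      write_report(fit$residuals, "graph_fit_residuals")
    })
  }
  if (!is.null(config$dating)) {
    stage("dating", {
      dt <- config$dating
      ns <- dt$n_snps %||% 5000L
      map_cm <- dt$map_cm %||% 250
      map <- data.frame(chrom = "1",
                        gpos = sort(stats::runif(ns, 0, map_cm / 100)))
      s <- derive_seed(seed, 5L)
      p0 <- with_seed(s, stats::runif(ns, 0.05, 0.95))
      f1 <- bn_drift(p0, 0.2); f2 <- bn_drift(p0, 0.2)
      hs <- simulate_admixture_ld(dt$p_admix %||% 0.3, dt$g %||% 20, map,
                                  dt$n_haplotypes %||% 200, f1, f2,
                                  seed = derive_seed(seed, 6L))
      fit <- date_admixture(hs, f1, f2)
      write_report(data.frame(g = fit$g, years = fit$years,
                              amplitude = fit$amplitude, affine = fit$affine,
                              failed = fit$failed), "admixture_date")
    })
  }

  manifest$digests <- as.list(tools::md5sum(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
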