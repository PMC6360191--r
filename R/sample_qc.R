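#' Assign genetic sex from chromosome-mapped read rates
#'
#' Uses the published rate rules for 1240K-capture data: a sample is
#' male when X-rate < 0.42 and Y-rate > 0.26, female when X-rate > 0.68
#' and Y-rate < 0.02, and undetermined otherwise. Rates are per-target
#' read rates on X and Y relative to autosomes, as produced by
#' [simulate_read_counts_sex()] or computed from real pileups.
#'
#' @param counts data.frame with `sample_id`, `x_rate`, `y_rate` (or raw
#'   `auto_reads`/`x_reads`/`y_reads` plus target sizes to derive them).
#' @param male_x,male_y,female_x,female_y classification thresholds.
#' @return data.frame with `sample_id`, `x_rate`, `y_rate`, `call`.
#' @export
assign_sex <- function(counts, male_x = 0.42, male_y = 0.26,
                       female_x = 0.68, female_y = 0.02) {
  x <- counts$x_rate; y <- counts$y_rate
  if (is.null(x) || is.null(y))
    stop("counts must contain x_rate and y_rate columns")
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad))
    warning(sum(bad), " sample(s) with zero autosomal reads; called U")
  call <- rep("U", length(x))
  call[!bad & x < male_x & y > male_y] <- "M"
  call[!bad & x > female_x & y < female_y] <- "F"
  data.frame(sample_id = counts$sample_id, x_rate = x, y_rate = y,
             call = call, stringsAsFactors = FALSE)
}

#' Pairwise kinship classification from genotype mismatch rates
#'
#' READ-style kinship inference for pseudo-haploid data: for every pair
#' of individuals, the pairwise mismatch rate is averaged across
#' fixed-size genomic windows and normalized by the median pair score
#' across all pairs, which stands in for the expected mismatch of
#' unrelated individuals from the same population. Normalized scores
#' classify pairs at the halved-midpoint boundaries 0.625 / 0.8125 /
#' 0.90625 into identical/twin, first degree, second degree and
#' unrelated.
#'
#' @param gm a pseudo-haploid [genotype_matrix()] with >= 2 individuals.
#' @param window_bp window size in base pairs (default 1 Mb).
#' @return data.frame with one row per pair: ids, number of overlapping
#'   SNPs, raw and normalized mismatch, classification.
#' @export
kinship_mismatch <- function(gm, window_bp = 1e6) {
  if (any(gm$ind$ploidy != 1L))
    stop("kinship_mismatch expects pseudo-haploid calls")
  n <- ncol(gm$geno)
  if (n < 2L) stop("need at least 2 individuals")
  win <- paste(gm$snp$chrom, floor(gm$snp$ppos / window_bp), sep = ":")
  win <- factor(win, levels = unique(win))
  ids <- gm$ind$sample_id
  prs <- utils::combn(n, 2L)
  rows <- list()
  for (k in seq_len(ncol(prs))) {
    i <- prs[1L, k]; j <- prs[2L, k]
    a <- gm$geno[, i]; b <- gm$geno[, j]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) {
      message("kinship: no overlapping sites for pair ", ids[i], "-", ids[j],
              "; skipped")
      next
    }
    mm <- rowsum(as.numeric(a[ok] != b[ok]), win[ok])
    nn <- rowsum(rep(1, sum(ok)), win[ok])
    per_win <- mm[, 1L] / nn[, 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      id1 = ids[i], id2 = ids[j], n_overlap = sum(ok),
      n_windows = length(per_win), mismatch = mean(per_win),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pair had overlapping coverage")
  med <- stats::median(out$mismatch)
  if (med <= 0) stop("median pairwise mismatch is zero; cannot normalize")
  out$norm_score <- out$mismatch / med
  out$classification <- cut(out$norm_score,
                            breaks = c(-Inf, 0.625, 0.8125, 0.90625, Inf),
                            labels = c("identical_twin", "first_degree",
                                       "second_degree", "unrelated"),
                            right = FALSE)
  out$classification <- as.character(out$classification)
  out
}

#' Outgroup-f3 shared-drift ranking
#'
#' f3(outgroup; a, b) measures the drift shared by a and b since their
#' divergence from the outgroup; ranking pairs by it highlights closely
#' related samples or populations (an Mbuti outgroup in the published
#' analyses).
#'
#' @param pairs list of length-2 character vectors, or 2-column matrix.
#' @param outgroup outgroup population label.
#' @param freqs,blocks as in [f2_stat()].
#' @return data.frame ranked by descending f3.
#' @export
outgroup_f3_sharing <- function(pairs, outgroup, freqs, blocks) {
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)),
                                        function(i) pairs[i, ])
  rows <- lapply(pairs, function(pr) {
    r <- f3_stat(pr[1L], pr[2L], outgroup, freqs, blocks)
    data.frame(a = pr[1L], b = pr[2L], f3 = r$est, se = r$se, z = r$z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$f3), , drop = FALSE]
}
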