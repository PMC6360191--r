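#' Construct a genotype matrix object
#'
#' The central data container: SNPs in rows, individuals in columns,
#' entries counting alternative alleles (0, 1, 2) with `NA` for missing.
#' Pseudo-haploid data (one sequencing read sampled and doubled, the
#' standard representation for low-coverage ancient genomes) contain only
#' 0, 2 and `NA`; each pseudo-haploid individual contributes a single
#' allele observation to frequency estimates, a diploid individual two.
#'
#' @param geno integer matrix (n_snps x n_ind) with values in {0,1,2,NA}.
#' @param snp data.frame with columns `snp_id`, `chrom`, `gpos` (Morgans),
#'   `ppos` (1-based bp), `ref`, `alt`.
#' @param ind data.frame with columns `sample_id`, `sex` (`M`/`F`/`U`),
#'   `population`, and optionally `ploidy` (1 = pseudo-haploid, 2 =
#'   diploid) which otherwise defaults from `ploidy_mode`.
#' @param ploidy_mode `"diploid"`, `"pseudo_haploid"` or `"mixed"`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, snp, ind, ploidy_mode = c("diploid", "pseudo_haploid", "mixed")) {
  ploidy_mode <- match.arg(ploidy_mode)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(snp))
    stop("geno has ", nrow(geno), " SNP rows but snp table has ", nrow(snp))
  if (ncol(geno) != nrow(ind))
    stop("geno has ", ncol(geno), " individual columns but ind table has ", nrow(ind))
  if (anyDuplicated(ind$sample_id))
    stop("duplicate sample_id: ", ind$sample_id[duplicated(ind$sample_id)][1L])
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(ind$ploidy))
    ind$ploidy <- if (ploidy_mode == "pseudo_haploid") 1L else 2L
  if (any(ind$ploidy == 1L)) {
    ph <- geno[, ind$ploidy == 1L, drop = FALSE]
    if (any(ph == 1L, na.rm = TRUE))
      stop("heterozygous call found for a pseudo-haploid individual")
  }
  if (any(ind$sex %in% c("M", "F", "U") == FALSE))
    stop("sex must be M, F or U")
  if (any(snp$gpos < 0, na.rm = TRUE)) stop("genetic positions must be >= 0")
  if (any(snp$ppos < 1, na.rm = TRUE)) stop("physical positions are 1-based")
  if (any(snp$ref == snp$alt)) stop("ref and alt allele identical at a SNP")
  rownames(geno) <- snp$snp_id
  colnames(geno) <- ind$sample_id
  structure(list(geno = geno, snp = snp, ind = ind, ploidy_mode = ploidy_mode),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$snp), "SNPs x", nrow(x$ind), "individuals (",
      x$ploidy_mode, ")\n")
  cat("populations:", paste(unique(x$ind$population), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Read an ASCII EIGENSTRAT dataset
#'
#' Reads the `.geno` / `.snp` / `.ind` trio. Only the ASCII dialect is
#' supported: one `.geno` row per SNP, one digit per individual, with `9`
#' meaning missing. The `.snp` file has six whitespace-separated columns
#' (id, chromosome, genetic position in Morgans, physical position, ref,
#' alt); the `.ind` file has three (id, sex, population label).
#'
#' @param geno_path,snp_path,ind_path file paths.
#' @param ploidy_mode how calls should be interpreted; pseudo-haploid
#'   datasets must not contain heterozygous calls.
#' @return a [genotype_matrix()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path,
                            ploidy_mode = c("diploid", "pseudo_haploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("snp_id", "chrom", "gpos", "ppos", "ref", "alt"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample_id", "sex", "population"))
  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp))
    stop("format error: ", geno_path, " has ", length(lines),
         " rows but ", snp_path, " lists ", nrow(snp), " SNPs")
  widths <- nchar(lines)
  if (any(widths != nrow(ind))) {
    off <- which(widths != nrow(ind))[1L]
    stop("format error: geno line ", off, " has width ", widths[off],
         " but ", ind_path, " lists ", nrow(ind), " individuals")
  }
  digits <- matrix(utf8ToInt(paste(lines, collapse = "")) - 48L,
                   nrow = nrow(snp), ncol = nrow(ind), byrow = TRUE)
  ok <- digits %in% c(0L, 1L, 2L, 9L)
  if (!all(ok)) {
    off <- which(!matrix(ok, nrow(snp)))[1L]
    stop("parse error: non-{0,1,2,9} genotype character at geno line ",
         (off - 1L) %% nrow(snp) + 1L)
  }
  digits[digits == 9L] <- NA_integer_
  genotype_matrix(digits, snp, ind, ploidy_mode)
}

#' Write an ASCII EIGENSTRAT dataset
#'
#' Missing calls are written as `9`. Writing the same matrix twice gives
#' byte-identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix; `<prefix>.geno/.snp/.ind` are created.
#' @return the three paths, invisibly.
#' @export
write_eigenstrat <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$ind) == 0L || nrow(gm$snp) == 0L)
    stop("refusing to write an empty dataset (0 individuals or 0 SNPs)")
  g <- gm$geno
  g[is.na(g)] <- 9L
  lines <- apply(g, 1L, function(r) paste(r, collapse = ""))
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  writeLines(lines, paths[1L])
  s <- gm$snp
  writeLines(sprintf("%s\t%s\t%.6f\t%d\t%s\t%s", s$snp_id, s$chrom, s$gpos,
                     as.integer(s$ppos), s$ref, s$alt), paths[2L])
  i <- gm$ind
  writeLines(sprintf("%s\t%s\t%s", i$sample_id, i$sex, i$population), paths[3L])
  invisible(paths)
}

#' Pseudo-haploid genotype calls from per-site read counts
#'
#' For every individual and SNP, one read is chosen uniformly at random
#' among the reads covering the site, and its allele is doubled (0 or 2);
#' sites without coverage are missing. This is the standard genotyping
#' strategy for low-coverage ancient DNA.
#'
#' @param ref_reads,alt_reads integer matrices (n_snps x n_ind) of read
#'   counts supporting the reference and alternative allele.
#' @param snp,ind metadata tables as in [genotype_matrix()].
#' @param seed integer seed; calls are deterministic given the seed.
#' @return a pseudo-haploid [genotype_matrix()].
#' @export
pseudo_haploid_call <- function(ref_reads, alt_reads, snp, ind, seed = NULL) {
  ref_reads <- as.matrix(ref_reads); alt_reads <- as.matrix(alt_reads)
  if (any(ref_reads < 0) || any(alt_reads < 0))
    stop("read counts must be non-negative")
  tot <- ref_reads + alt_reads
  with_seed(seed, {
    p_alt <- ifelse(tot > 0, alt_reads / tot, NA_real_)
    draw <- matrix(stats::rbinom(length(p_alt), 1L, ifelse(is.na(p_alt), 0, p_alt)),
                   nrow(p_alt), ncol(p_alt))
    calls <- 2L * draw
    calls[tot == 0] <- NA_integer_
    ind$ploidy <- 1L
    genotype_matrix(calls, snp, ind, "pseudo_haploid")
  })
}

complement_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Merge genotype datasets on their shared SNPs
#'
#' Takes the intersection of SNP ids, reconciling allele orientation
#' against the first dataset: where ref/alt are swapped, calls are
#' complemented (0 <-> 2); where the alleles only match after strand
#' complementing, the complement is applied unless the SNP is
#' strand-ambiguous (A/T or C/G), in which case it is dropped and counted
#' in the report. SNPs whose alleles cannot be reconciled are dropped too.
#'
#' @param gms list of [genotype_matrix()] objects.
#' @return a merged `genotype_matrix`; the attached `"merge_report"`
#'   attribute tabulates flipped and dropped SNPs per dataset.
#' @export
merge_datasets <- function(gms) {
  stopifnot(length(gms) >= 2L)
  ids <- unlist(lapply(gms, function(g) g$ind$sample_id))
  if (anyDuplicated(ids))
    stop("merge error: duplicate sample_id across datasets: ",
         ids[duplicated(ids)][1L])
  shared <- Reduce(intersect, lapply(gms, function(g) g$snp$snp_id))
  base <- gms[[1L]]
  bsnp <- base$snp[match(shared, base$snp$snp_id), , drop = FALSE]
  keep <- rep(TRUE, length(shared))
  report <- list()
  genos <- vector("list", length(gms))
  inds <- vector("list", length(gms))
  for (k in seq_along(gms)) {
    g <- gms[[k]]
    idx <- match(shared, g$snp$snp_id)
    sub <- g$geno[idx, , drop = FALSE]
    n_flip <- 0L; n_drop <- 0L
    if (k > 1L) {
      r1 <- bsnp$ref; a1 <- bsnp$alt
      r2 <- g$snp$ref[idx]; a2 <- g$snp$alt[idx]
      same <- r1 == r2 & a1 == a2
      swap <- r1 == a2 & a1 == r2
      ambiguous <- r1 == complement_allele(a1)   # A/T or C/G pair
      comp_same <- !ambiguous & r1 == complement_allele(r2) & a1 == complement_allele(a2)
      comp_swap <- !ambiguous & r1 == complement_allele(a2) & a1 == complement_allele(r2)
      flip <- (!same & swap & !ambiguous) | comp_swap
      drop <- !(same | (swap & !ambiguous) | comp_same | comp_swap)
      sub[flip, ] <- 2L - sub[flip, , drop = FALSE]
      keep <- keep & !drop
      n_flip <- sum(flip); n_drop <- sum(drop)
    }
    genos[[k]] <- sub
    ind <- g$ind
    if (is.null(ind$ploidy)) ind$ploidy <- if (g$ploidy_mode == "pseudo_haploid") 1L else 2L
    inds[[k]] <- ind
    report[[k]] <- data.frame(dataset = k, n_shared = length(shared),
                              n_flipped = n_flip, n_dropped = n_drop)
  }
  geno <- do.call(cbind, lapply(genos, function(m) m[keep, , drop = FALSE]))
  ind <- do.call(rbind, inds)
  mode <- if (all(ind$ploidy == 1L)) "pseudo_haploid"
          else if (all(ind$ploidy == 2L)) "diploid" else "mixed"
  out <- genotype_matrix(geno, bsnp[keep, , drop = FALSE], ind, mode)
  attr(out, "merge_report") <- do.call(rbind, report)
  out
}

#' Drop individuals below a minimum SNP count
#'
#' Ancient samples with too few covered SNPs carry little information and
#' distort frequency estimates; the cohort analysed here used a cutoff of
#' 30,000 covered sites.
#'
#' @param gm a [genotype_matrix()].
#' @param min_snps minimum number of non-missing calls to retain an
#'   individual.
#' @return list with the filtered `matrix` and a `report` data.frame
#'   (sample_id, n_snps, retained).
#' @export
filter_by_snp_count <- function(gm, min_snps = 30000L) {
  stopifnot(min_snps >= 0)
  n_called <- colSums(!is.na(gm$geno))
  keep <- n_called >= min_snps
  report <- data.frame(sample_id = gm$ind$sample_id, n_snps = as.integer(n_called),
                       retained = keep, row.names = NULL)
  out <- gm
  out$geno <- gm$geno[, keep, drop = FALSE]
  out$ind <- gm$ind[keep, , drop = FALSE]
  list(matrix = out, report = report)
}
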