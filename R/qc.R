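#' Quality-control thresholds
#'
#' The four standard PLINK-style marker/sample filters: individual
#' missingness, SNP missingness, Hardy-Weinberg exact-test p-value, and
#' minor allele frequency.
#'
#' @param max_individual_missing drop individuals with a larger fraction of
#'   missing genotypes (default 0.20).
#' @param max_snp_missing drop SNPs with a larger fraction of missing calls
#'   (default 0.10).
#' @param hwe_p_min drop SNPs with an exact HWE p-value below this
#'   (default 1e-6).
#' @param maf_min drop SNPs with minor allele frequency below this
#'   (default 0.05).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_individual_missing = 0.20,
                          max_snp_missing = 0.10,
                          hwe_p_min = 1e-6,
                          maf_min = 0.05) {
  vals <- c(max_individual_missing, max_snp_missing, hwe_p_min, maf_min)
  if (any(vals < 0) || any(vals > 1)) stop("thresholds must be in [0, 1]")
  structure(list(max_individual_missing = max_individual_missing,
                 max_snp_missing = max_snp_missing,
                 hwe_p_min = hwe_p_min,
                 maf_min = maf_min),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg test p-value
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts: the p-value is the summed probability of every heterozygote
#' configuration whose conditional probability does not exceed that of the
#' observed configuration.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (non-negative, total > 0).
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("counts must be non-negative")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_hom1 + n_het
  nB <- 2 * n_hom2 + n_het
  # possible het counts share the parity of nA (and nB)
  ks <- seq.int(nA %% 2, min(nA, nB), by = 2L)
  # log P(het = k | nA, n) up to a constant:
  #   log 2^k - log((nA-k)/2)! - log k! - log((nB-k)/2)!
  logp <- ks * log(2) - lfactorial((nA - ks) / 2) - lfactorial(ks) -
    lfactorial((nB - ks) / 2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, ks)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Apply quality control to a genotype dataset
#'
#' Sequential passes mirroring PLINK 1.9's internal order: (1) drop
#' individuals above the missingness threshold; then, on the remaining
#' individuals, drop SNPs failing (2) missingness, (3) the exact HWE test,
#' (4) the MAF threshold. Each excluded SNP is attributed to the first
#' filter it fails in this order; per-SNP statistics for (2)-(4) are all
#' computed on the post-step-1 individual set, so the outcome (though not
#' the attribution) is order-insensitive for those filters.
#'
#' @param dataset a `genotype_dataset`.
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `dataset` (the filtered data) and `report`
#'   (class `qc_report`: before/after counts, per-filter exclusion counts,
#'   excluded ID lists).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$geno
  n0 <- nrow(g); m0 <- ncol(g)
  if (n0 == 0L || m0 == 0L) stop("dataset is empty")

  ind_miss <- rowMeans(is.na(g))
  drop_ind <- ind_miss > thresholds$max_individual_missing
  excluded_ind <- rownames(g)[drop_ind]
  g1 <- g[!drop_ind, , drop = FALSE]
  if (nrow(g1) == 0L) stop("no data passes QC: all individuals excluded")

  snp_miss <- colMeans(is.na(g1))
  nn <- colSums(!is.na(g1))
  het <- colSums(g1 == 1L, na.rm = TRUE)
  hom1 <- colSums(g1 == 2L, na.rm = TRUE)
  hom2 <- colSums(g1 == 0L, na.rm = TRUE)
  p1 <- colSums(g1, na.rm = TRUE) / (2 * nn)
  maf <- pmin(p1, 1 - p1)
  hwe_p <- vapply(seq_len(ncol(g1)), function(j) {
    if (nn[j] == 0) return(NA_real_)
    hwe_exact_pvalue(hom1[j], het[j], hom2[j])
  }, numeric(1))

  fail_miss <- snp_miss > thresholds$max_snp_missing | nn == 0
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
  fail_maf <- !fail_miss & (is.na(maf) | maf < thresholds$maf_min)
  # first-failure attribution: missingness > HWE > MAF
  attr_miss <- fail_miss
  attr_hwe <- fail_hwe & !attr_miss
  attr_maf <- fail_maf & !attr_miss & !attr_hwe
  drop_snp <- fail_miss | fail_hwe | fail_maf
  snps <- dataset$map$snp

  keep_snp <- !drop_snp
  if (!any(keep_snp)) stop("no data passes QC: all SNPs excluded")
  out <- genotype_dataset(g1[, keep_snp, drop = FALSE],
                          dataset$map[keep_snp, , drop = FALSE],
                          dataset$fam[!drop_ind, , drop = FALSE])
  report <- structure(list(
    n_individuals_before = n0,
    n_individuals_after = nrow(g1),
    n_snps_before = m0,
    n_snps_after = sum(keep_snp),
    excluded = list(
      individuals = excluded_ind,
      snp_missing = snps[attr_miss],
      hwe = snps[attr_hwe],
      maf = snps[attr_maf]
    ),
    counts = c(individual_missing = sum(drop_ind),
               snp_missing = sum(attr_miss),
               hwe = sum(attr_hwe),
               maf = sum(attr_maf)),
    thresholds = thresholds
  ), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  individuals: %d -> %d (%d excluded for missingness)\n",
              x$n_individuals_before, x$n_individuals_after,
              x$counts[["individual_missing"]]))
  cat(sprintf("  SNPs: %d -> %d (missing %d, HWE %d, MAF %d)\n",
              x$n_snps_before, x$n_snps_after,
              x$counts[["snp_missing"]], x$counts[["hwe"]],
              x$counts[["maf"]]))
  invisible(x)
}

#' Write a QC report as JSON plus keep-lists
#'
#' @param report a `qc_report`.
#' @param dataset the QC-passing `genotype_dataset`.
#' @param prefix output prefix; writes `<prefix>.qc.json`,
#'   `<prefix>.keep_individuals.txt`, `<prefix>.keep_snps.txt`.
#' @return invisibly, the JSON path.
#' @export
write_qc_report <- function(report, dataset, prefix) {
  json_path <- paste0(prefix, ".qc.json")
  jsonlite::write_json(unclass(report)[c("n_individuals_before",
                                         "n_individuals_after",
                                         "n_snps_before", "n_snps_after",
                                         "counts", "excluded")],
                       json_path, auto_unbox = TRUE, digits = NA)
  writeLines(individual_ids(dataset),
             paste0(prefix, ".keep_individuals.txt"))
  writeLines(dataset$map$snp, paste0(prefix, ".keep_snps.txt"))
  invisible(json_path)
}
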