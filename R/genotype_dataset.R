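#' Genotype dataset container
#'
#' Bundles a dosage matrix with its marker map and sample pedigree table.
#' This is the substrate every other module (QC, panel sampling, kinship,
#' prediction) operates on.
#'
#' @param geno integer/numeric matrix, individuals x markers, entries in
#'   \{0, 1, 2\} or `NA` for missing. Dosage is the count of the marker's
#'   first allele (`a1`), fixed at load time to the minor allele.
#' @param map data.frame with columns `snp` (unique marker IDs), `chr`
#'   (chromosome or linkage-group label, treated as an opaque string), `pos`
#'   (non-negative integer base-pair position), `a1`, `a2` (allele codes).
#' @param fam data.frame with columns `fid`, `iid`, `sire`, `dam`, `sex`
#'   (use `"0"` / `0` where unknown).
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `geno`, `map`, `fam`. Rows of `geno` are named `FID_IID`; columns are
#'   named by marker ID. Markers are stored sorted by (chromosome, position).
#' @export
genotype_dataset <- function(geno, map, fam) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  fam <- as.data.frame(fam, stringsAsFactors = FALSE)
  need_map <- c("snp", "chr", "pos", "a1", "a2")
  if (!all(need_map %in% names(map))) {
    stop("map must have columns: ", paste(need_map, collapse = ", "))
  }
  need_fam <- c("fid", "iid", "sire", "dam", "sex")
  for (col in setdiff(need_fam, names(fam))) fam[[col]] <- "0"
  if (anyDuplicated(map$snp)) stop("marker IDs must be unique")
  if (any(map$pos < 0)) stop("marker positions must be non-negative")
  if (nrow(map) != ncol(geno)) stop("map rows must match genotype columns")
  if (nrow(fam) != nrow(geno)) stop("fam rows must match genotype rows")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("dosages must be in {0, 1, 2} or NA")
  }
  ord <- order(as.character(map$chr), map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(map) <- NULL
  ids <- paste(fam$fid, fam$iid, sep = "_")
  if (anyDuplicated(ids)) stop("FID_IID combinations must be unique")
  rownames(geno) <- ids
  colnames(geno) <- map$snp
  structure(list(geno = geno, map = map, fam = fam),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "genotype_dataset: %d individuals x %d markers on %d chromosome(s)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%; families: %d\n",
              100 * miss, length(unique(x$fam$fid))))
  invisible(x)
}

#' Number of individuals / markers
#' @param x a `genotype_dataset`
#' @return integer count
#' @export
n_individuals <- function(x) nrow(x$geno)

#' @rdname n_individuals
#' @export
n_markers <- function(x) ncol(x$geno)

#' Individual identifiers (`FID_IID`)
#' @param x a `genotype_dataset`
#' @return character vector
#' @export
individual_ids <- function(x) rownames(x$geno)

#' Subset a genotype dataset by marker IDs
#'
#' @param x a `genotype_dataset`
#' @param snp_ids character vector of marker IDs (all must be present)
#' @return a `genotype_dataset` restricted to those markers (kept in map
#'   order, i.e. sorted by chromosome and position)
#' @export
subset_markers <- function(x, snp_ids) {
  missing_ids <- setdiff(snp_ids, x$map$snp)
  if (length(missing_ids)) {
    stop("unknown marker IDs: ", paste(utils::head(missing_ids, 5),
                                       collapse = ", "))
  }
  keep <- x$map$snp %in% snp_ids
  genotype_dataset(x$geno[, keep, drop = FALSE],
                   x$map[keep, , drop = FALSE],
                   x$fam)
}

#' Subset a genotype dataset by individual IDs
#'
#' @param x a `genotype_dataset`
#' @param ids character vector of `FID_IID` identifiers
#' @return a `genotype_dataset` restricted to those individuals
#' @export
subset_individuals <- function(x, ids) {
  all_ids <- individual_ids(x)
  missing_ids <- setdiff(ids, all_ids)
  if (length(missing_ids)) {
    stop("unknown individual IDs: ", paste(utils::head(missing_ids, 5),
                                           collapse = ", "))
  }
  keep <- all_ids %in% ids
  genotype_dataset(x$geno[keep, , drop = FALSE], x$map,
                   x$fam[keep, , drop = FALSE])
}
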