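#' Read PLINK text genotypes (PED/MAP)
#'
#' Allele pairs are collapsed to the dosage of the minor allele, determined
#' after reading (ties broken toward the alphabetically first allele code).
#' `"0 0"` (and half-missing calls) parse as missing. Markers are re-sorted
#' by (chromosome, position).
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @return a `genotype_dataset`. `map$a1` is the minor allele the dosage
#'   counts (`"0"` if the marker is monomorphic), `map$a2` the major allele.
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4L) stop("MAP file must have 4 columns")
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L) {
    stop("ragged PED file: line ", which(lens != lens[1])[1],
         " has ", lens[lens != lens[1]][1], " fields, expected ", lens[1])
  }
  if (lens[1] != 6L + 2L * m) {
    stop("PED line width ", lens[1], " does not match MAP marker count ", m)
  }
  mat <- do.call(rbind, toks)
  n <- nrow(mat)
  fam <- data.frame(fid = mat[, 1], iid = mat[, 2], sire = mat[, 3],
                    dam = mat[, 4], sex = mat[, 5], stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    al <- cbind(mat[, 5L + 2L * j], mat[, 6L + 2L * j])
    obs <- al[al != "0"]
    half <- xor(al[, 1] == "0", al[, 2] == "0")
    if (any(half)) al[half, ] <- "0"  # half-missing treated as missing
    codes <- sort(unique(obs))
    if (length(codes) > 2L) {
      stop("marker ", map_raw[j, 2], " has ", length(codes),
           " distinct alleles: ", paste(codes, collapse = ", "))
    }
    if (length(codes) == 0L) {
      a1[j] <- "0"; a2[j] <- "0"
      next
    }
    if (length(codes) == 1L) {
      a1[j] <- "0"; a2[j] <- codes  # monomorphic: dosage 0 everywhere
      geno[al[, 1] != "0", j] <- 0L
      next
    }
    cnt <- c(sum(obs == codes[1]), sum(obs == codes[2]))
    # minor = rarer allele; tie toward the alphabetically first (codes sorted)
    minor <- if (cnt[2] < cnt[1]) codes[2] else codes[1]
    major <- setdiff(codes, minor)
    a1[j] <- minor; a2[j] <- major
    ok <- al[, 1] != "0"
    geno[ok, j] <- (al[ok, 1] == minor) + (al[ok, 2] == minor)
  }
  map <- data.frame(snp = map_raw[, 2], chr = map_raw[, 1],
                    pos = as.integer(map_raw[, 4]),
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_dataset(geno, map, fam)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param dataset a `genotype_dataset`.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_plink_text <- function(dataset, prefix) {
  map <- dataset$map
  a1 <- ifelse(map$a1 == "0", map$a2, map$a1)
  a2 <- map$a2
  n <- n_individuals(dataset); m <- n_markers(dataset)
  alle <- matrix("0", n, 2L * m)
  g <- dataset$geno
  for (j in seq_len(m)) {
    cj <- g[, j]
    c1 <- c2 <- rep("0", n)
    c1[!is.na(cj) & cj == 2L] <- a1[j]; c2[!is.na(cj) & cj == 2L] <- a1[j]
    c1[!is.na(cj) & cj == 1L] <- a1[j]; c2[!is.na(cj) & cj == 1L] <- a2[j]
    c1[!is.na(cj) & cj == 0L] <- a2[j]; c2[!is.na(cj) & cj == 0L] <- a2[j]
    alle[, 2L * j - 1L] <- c1; alle[, 2L * j] <- c2
  }
  ped <- cbind(dataset$fam$fid, dataset$fam$iid, dataset$fam$sire,
               dataset$fam$dam, dataset$fam$sex, "-9", alle)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(ped, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(map$chr, map$snp, 0L, map$pos), map_path,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

# 256 x 4 decode table: byte value -> four A1 dosages
# (PLINK 1 codes: 00 = hom A1 -> 2, 01 = missing, 10 = het, 11 = hom A2 -> 0)
bed_decode_table <- function() {
  vals <- c(2L, NA_integer_, 1L, 0L)
  t(vapply(0:255, function(v) {
    vals[bitwAnd(bitwShiftR(v, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  }, integer(4)))
}

#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' SNP-major PLINK 1 dialect only. Dosage counts the BIM allele-1 (A1);
#' the 01 bit pattern is propagated as missing.
#'
#' @param bed_path,bim_path,fam_path the three file paths.
#' @return a `genotype_dataset`.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  if (ncol(bim) < 6L) stop("BIM file must have 6 columns")
  fam_raw <- utils::read.table(fam_path, header = FALSE,
                               colClasses = "character")
  n <- nrow(fam_raw); m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw",
                 n = file.info(bed_path)$size + 10L)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK 1 BED file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major BED files are supported (mode byte != 0x01)")
  }
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) != 3L + m * bps) {
    stop("BED file size mismatch: expected ", 3L + m * bps, " bytes, found ",
         length(raw))
  }
  body <- as.integer(raw[-(1:3)])
  dec <- bed_decode_table()[body + 1L, , drop = FALSE]  # (m*bps) x 4
  arr <- array(t(dec), dim = c(4L * bps, m))
  geno <- t(arr[seq_len(n), , drop = FALSE])
  map <- data.frame(snp = bim[, 2], chr = bim[, 1],
                    pos = as.integer(bim[, 4]),
                    a1 = bim[, 5], a2 = bim[, 6], stringsAsFactors = FALSE)
  fam <- data.frame(fid = fam_raw[, 1], iid = fam_raw[, 2],
                    sire = fam_raw[, 3], dam = fam_raw[, 4],
                    sex = fam_raw[, 5], stringsAsFactors = FALSE)
  genotype_dataset(t(geno), map, fam)
}

#' Write PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' @param dataset a `genotype_dataset`.
#' @param prefix output path prefix; writes `<prefix>.bed`, `.bim`, `.fam`.
#' @return invisibly, the three file paths.
#' @export
write_plink_binary <- function(dataset, prefix) {
  n <- n_individuals(dataset); m <- n_markers(dataset)
  bps <- ceiling(n / 4)
  # dosage -> 2-bit code on the A1 axis
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  g <- dataset$geno
  out <- raw(3L + m * bps)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  shift <- c(1L, 4L, 16L, 64L)
  pad <- 4L * bps - n
  for (j in seq_len(m)) {
    cj <- g[, j]
    codes <- ifelse(is.na(cj), 1L, code_of[as.character(cj)])
    if (pad > 0L) codes <- c(codes, rep(0L, pad))
    cm <- matrix(codes, nrow = 4L)
    bytes <- as.integer(colSums(cm * shift))
    out[3L + (j - 1L) * bps + seq_len(bps)] <- as.raw(bytes)
  }
  bed_path <- paste0(prefix, ".bed")
  writeBin(out, bed_path)
  map <- dataset$map
  a1 <- ifelse(map$a1 == "0", "0", map$a1)
  utils::write.table(
    data.frame(map$chr, map$snp, 0L, map$pos, a1, map$a2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    cbind(dataset$fam$fid, dataset$fam$iid, dataset$fam$sire,
          dataset$fam$dam, dataset$fam$sex, "-9"),
    paste0(prefix, ".fam"), quote = FALSE, sep = " ",
    row.names = FALSE, col.names = FALSE)
  invisible(c(bed = bed_path, bim = paste0(prefix, ".bim"),
              fam = paste0(prefix, ".fam")))
}

#' Read a phenotype table
#'
#' Tab-delimited with a header. Trait columns are parsed as reals with
#' `"NA"` as the missing sentinel; factor columns are kept as labels.
#'
#' @param path file path.
#' @param trait_columns character vector of trait column names.
#' @param factor_columns character vector of factor column names.
#' @param id_column name of the individual-ID column (default `"id"`).
#' @return data.frame with the ID, trait and factor columns; attributes
#'   `traits` and `factors` record the roles.
#' @export
read_phenotypes <- function(path, trait_columns, factor_columns = character(),
                            id_column = "id") {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  need <- c(id_column, trait_columns, factor_columns)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[[id_column]])) {
    stop("duplicate individual IDs in ", path)
  }
  for (tc in trait_columns) {
    cell <- df[[tc]]
    num <- suppressWarnings(as.numeric(cell))
    # read.delim has already mapped the "NA" sentinel to NA_character_
    bad <- is.na(num) & !is.na(cell) & !(cell %in% c("NA", "", "na"))
    if (any(bad)) {
      stop("non-numeric value '", cell[bad][1], "' in trait column ", tc)
    }
    df[[tc]] <- num
  }
  for (fc in factor_columns) {
    empty <- !nzchar(df[[fc]])
    has_pheno <- Reduce(`|`, lapply(trait_columns,
                                    function(tc) !is.na(df[[tc]])))
    if (any(empty & has_pheno)) {
      stop("empty factor level in column ", fc, " for a phenotyped individual")
    }
  }
  out <- df[, need, drop = FALSE]
  names(out)[1] <- "id"
  attr(out, "traits") <- trait_columns
  attr(out, "factors") <- factor_columns
  out
}

#' Write a phenotype table as TSV
#'
#' @param phenotypes a phenotype data.frame (e.g. from [simulate_trait()]).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a simulation truth record as JSON
#'
#' @param truth a `truth_record` from [simulate_trait()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$true_breeding_values <- as.list(x$true_breeding_values)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
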