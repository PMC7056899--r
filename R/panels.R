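#' Proportional integer allocation of SNPs to chromosomes
#'
#' Largest-remainder apportionment: each chromosome gets
#' `floor(k * len / sum(len))` SNPs, and the shortfall is topped up in order
#' of descending fractional remainder (ties broken by descending length,
#' then by input order). Counts always sum exactly to `k`.
#'
#' @param chrom_lengths named numeric vector of positive chromosome lengths.
#' @param k total number of SNPs to allocate (>= 0).
#' @return named integer vector of counts summing to `k`.
#' @export
allocate_proportional <- function(chrom_lengths, k) {
  if (k < 0) stop("k must be non-negative")
  if (any(chrom_lengths < 0) || sum(chrom_lengths) <= 0) {
    stop("chromosome lengths must be positive")
  }
  largest_remainder(chrom_lengths, k)
}

#' Sample one low-density SNP panel
#'
#' Two selection strategies: `"genomewide_random"` draws `k` markers
#' uniformly without replacement irrespective of position;
#' `"within_chromosome_proportional"` first allocates `k` across
#' chromosomes proportionally to their length (span of QC-passing marker
#' positions, max - min) and then samples uniformly within each chromosome.
#'
#' @param dataset a `genotype_dataset` (typically QC-passing).
#' @param k target panel density (number of SNPs), `k <= n_markers`.
#' @param strategy selection strategy (see above).
#' @param seed integer seed; the panel is a pure function of
#'   (dataset, k, strategy, seed).
#' @param replicate_index optional replicate label stored in the panel.
#' @return an object of class `snp_panel`: list with `snp_ids` (sorted by
#'   chromosome and position), `density`, `strategy`, `replicate`, `seed`.
#' @export
sample_panel <- function(dataset, k,
                         strategy = c("genomewide_random",
                                      "within_chromosome_proportional"),
                         seed = 1L, replicate_index = NA_integer_) {
  strategy <- match.arg(strategy)
  m <- n_markers(dataset)
  if (k > m) stop("panel density ", k, " exceeds available markers ", m)
  map <- dataset$map
  if (k == m) {
    # full-density "panel": the complete marker set, whatever the strategy
    return(structure(list(snp_ids = map$snp, density = as.integer(k),
                          strategy = strategy,
                          replicate = replicate_index,
                          seed = as.integer(seed)),
                     class = "snp_panel"))
  }
  ids <- with_seed(seed, {
    if (strategy == "genomewide_random") {
      map$snp[sample.int(m, k)]
    } else {
      spans <- tapply(map$pos, as.character(map$chr),
                      function(p) diff(range(p)))
      spans <- spans[unique(as.character(map$chr))]
      alloc <- allocate_proportional(spans, k)
      counts <- table(factor(as.character(map$chr), levels = names(alloc)))
      over <- alloc > as.integer(counts)
      if (any(over)) {
        stop("allocation exceeds marker count on chromosome(s) ",
             paste(names(alloc)[over], collapse = ", "),
             "; consider strategy = \"genomewide_random\"")
      }
      unlist(lapply(names(alloc), function(cc) {
        snps_c <- map$snp[map$chr == cc]
        snps_c[sample.int(length(snps_c), alloc[[cc]])]
      }), use.names = FALSE)
    }
  })
  keep <- map$snp %in% ids
  structure(list(snp_ids = map$snp[keep],  # map order = (chr, pos) sorted
                 density = as.integer(k),
                 strategy = strategy,
                 replicate = replicate_index,
                 seed = as.integer(seed)),
            class = "snp_panel")
}

#' The published density grid
#'
#' The standard grid of panel densities evaluated in every dataset, plus
#' extensions at 6,000 / 7,000 / 9,000 that apply only when enough
#' QC-passing SNPs remain.
#'
#' @return increasing integer vector of densities.
#' @export
default_density_grid <- function() {
  c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L, 900L, 1000L, 1200L,
    1400L, 1600L, 1800L, 2000L, 2250L, 2500L, 2750L, 3000L, 3500L, 4000L,
    4500L, 5000L, 6000L, 7000L, 9000L)
}

#' Build the full replicate panel set over a density grid
#'
#' For each density in the grid, draws `replicates` independent panels,
#' each with its own seed derived deterministically from `master_seed`,
#' the strategy, the density, and the replicate index - so extending the
#' grid never perturbs previously drawn panels. Densities exceeding the
#' available marker count are dropped with a notice.
#'
#' @param dataset a `genotype_dataset`.
#' @param grid strictly increasing vector of densities.
#' @param replicates panels per density (default 5).
#' @param strategy passed to [sample_panel()].
#' @param master_seed integer master seed.
#' @return list of `snp_panel` objects.
#' @export
make_panel_set <- function(dataset, grid = default_density_grid(),
                           replicates = 5L,
                           strategy = c("genomewide_random",
                                        "within_chromosome_proportional"),
                           master_seed = 1L) {
  strategy <- match.arg(strategy)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("density grid must be strictly increasing")
  }
  m <- n_markers(dataset)
  usable <- grid[grid <= m]
  dropped <- grid[grid > m]
  if (length(dropped)) {
    message("dropping densities above the available ", m, " SNPs: ",
            paste(dropped, collapse = ", "))
  }
  strat_code <- match(strategy, c("genomewide_random",
                                  "within_chromosome_proportional"))
  panels <- list()
  for (k in usable) {
    for (r in seq_len(replicates)) {
      seed <- derive_seed(master_seed, strat_code, k, r)
      panels[[length(panels) + 1L]] <-
        sample_panel(dataset, k, strategy, seed = seed, replicate_index = r)
    }
  }
  panels
}

#' Write a panel as an extract list plus JSON manifest
#'
#' @param panel an `snp_panel`.
#' @param prefix output prefix; writes `<prefix>.snps.txt` (one marker ID
#'   per line, PLINK `--extract` style) and `<prefix>.manifest.json`.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, prefix) {
  ids_path <- paste0(prefix, ".snps.txt")
  man_path <- paste0(prefix, ".manifest.json")
  writeLines(panel$snp_ids, ids_path)
  jsonlite::write_json(list(density = panel$density,
                            strategy = panel$strategy,
                            replicate = panel$replicate,
                            seed = panel$seed),
                       man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(snps = ids_path, manifest = man_path))
}
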