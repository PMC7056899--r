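#' Simulation configuration for family-structured populations
#'
#' Defines a full-sib breeding population of the kind used in aquaculture
#' sib-testing schemes: unrelated founder pairs, one full-sib family per
#' pair, biallelic SNPs on a physical map, and a polygenic trait with a
#' chosen narrow-sense heritability.
#'
#' @param n_families number of monogamous founder pairs / full-sib families.
#' @param offspring_per_family either a single integer (every family that
#'   size) or an integer vector of length `n_families`.
#' @param n_snps total number of SNPs across the genome.
#' @param n_chromosomes number of chromosomes; markers are apportioned to
#'   chromosomes proportionally to `chrom_lengths`.
#' @param chrom_lengths physical chromosome lengths in base pairs; a single
#'   value is recycled. Default 50 Mb per chromosome.
#' @param cm_per_mb genetic-map scaling in centimorgan per megabase
#'   (default 1, a standard vertebrate ballpark).
#' @param maf_range interval within (0, 0.5] from which founder population
#'   allele frequencies are drawn uniformly.
#' @param h2_true narrow-sense heritability of the simulated trait, in [0,1].
#' @param n_qtl number of causal markers (default 500, a polygenic
#'   architecture); must be at least 1 when `h2_true > 0`.
#' @param n_parents number of founder individuals (default `2 * n_families`).
#' @param fixed_effects list of fixed-effect factors, each a list with
#'   elements `name`, `n_levels`, and `effects` (per-level shifts in units of
#'   the phenotypic standard deviation; first level conventionally 0).
#' @param transform `"none"` or `"log"`. With `"log"` the stored trait is
#'   `exp(latent)`, i.e. a right-skewed observed scale whose log transform
#'   recovers the latent Gaussian trait exactly.
#' @param censor_day optional integer: phenotypes are quantile-binned into
#'   integer days 1..`censor_day`; the top bin plays the role of survivors
#'   recorded at the final day.
#' @param trait_name column name for the trait in the phenotype table.
#' @param seed integer seed; the whole simulation is a pure function of the
#'   configuration including this seed.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_families,
                       offspring_per_family,
                       n_snps,
                       n_chromosomes = 30,
                       chrom_lengths = 50e6,
                       cm_per_mb = 1,
                       maf_range = c(0.05, 0.5),
                       h2_true = 0.3,
                       n_qtl = 500,
                       n_parents = 2L * n_families,
                       fixed_effects = list(),
                       transform = c("none", "log"),
                       censor_day = NULL,
                       trait_name = "trait",
                       seed = 1L) {
  transform <- match.arg(transform)
  if (length(chrom_lengths) == 1L) {
    chrom_lengths <- rep(chrom_lengths, n_chromosomes)
  }
  if (length(chrom_lengths) != n_chromosomes) {
    stop("chrom_lengths must have length n_chromosomes")
  }
  if (any(chrom_lengths <= 0)) stop("chrom_lengths must all be positive")
  if (length(offspring_per_family) == 1L) {
    offspring_per_family <- rep(as.integer(offspring_per_family), n_families)
  }
  if (length(offspring_per_family) != n_families) {
    stop("offspring_per_family must be a scalar or length n_families")
  }
  if (any(offspring_per_family < 1L)) stop("offspring counts must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (h2_true < 0 || h2_true > 1) stop("h2_true must be in [0, 1]")
  if (h2_true > 0 && n_qtl < 1) stop("n_qtl must be >= 1 when h2_true > 0")
  if (n_qtl > n_snps) stop("n_qtl cannot exceed n_snps")
  if (n_parents < 2L * n_families) {
    stop("need at least 2 founders per family")
  }
  if (!is.null(censor_day) && censor_day < 1) {
    stop("censor_day must be a positive integer")
  }
  structure(list(
    n_families = as.integer(n_families),
    offspring_per_family = as.integer(offspring_per_family),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths = as.numeric(chrom_lengths),
    cm_per_mb = cm_per_mb,
    maf_range = maf_range,
    h2_true = h2_true,
    n_qtl = as.integer(n_qtl),
    n_parents = as.integer(n_parents),
    fixed_effects = fixed_effects,
    transform = transform,
    censor_day = if (is.null(censor_day)) NULL else as.integer(censor_day),
    trait_name = trait_name,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Equal family sizes from a total, remainder spread over the first families.
split_offspring <- function(total, n_families) {
  base <- total %/% n_families
  counts <- rep(base, n_families)
  rem <- total %% n_families
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  as.integer(counts)
}

#' Preset simulation configurations emulating published aquaculture datasets
#'
#' Four presets matching the family counts, sample sizes, post-QC SNP
#' densities and trait heritabilities of well-known aquaculture genomic
#' selection datasets: Atlantic salmon (disease challenge, SNP array),
#' common carp (growth, RAD-seq), gilthead sea bream (days to death,
#' 2b-RAD), and Pacific oyster (days to death with survivors recorded at
#' day 8, SNP array).
#'
#' @param name one of `"salmon"`, `"carp"`, `"seabream"`, `"oyster"`.
#' @param h2 optional override of the preset heritability.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
sim_preset <- function(name = c("salmon", "carp", "seabream", "oyster"),
                       h2 = NULL, seed = 1L) {
  name <- match.arg(name)
  tank2 <- list(list(name = "tank", n_levels = 2L, effects = c(0, 0.5)))
  cfg <- switch(name,
    salmon = sim_config(
      n_families = 85L,
      offspring_per_family = split_offspring(1481L, 85L),
      n_snps = 9866L, n_chromosomes = 29L, chrom_lengths = 83e6,
      h2_true = 0.24, fixed_effects = tank2,
      trait_name = "amoebic_load", seed = seed),
    carp = sim_config(
      n_families = 195L,
      offspring_per_family = split_offspring(1211L, 195L),
      n_snps = 6966L, n_chromosomes = 50L, chrom_lengths = 34e6,
      h2_true = 0.27,
      fixed_effects = list(list(name = "cross_group", n_levels = 4L,
                                effects = c(0, 0.2, 0.4, 0.6))),
      transform = "log", trait_name = "length", seed = seed),
    seabream = sim_config(
      n_families = 73L,
      offspring_per_family = split_offspring(741L, 73L),
      n_snps = 7598L, n_chromosomes = 24L, chrom_lengths = 29e6,
      h2_true = 0.20, trait_name = "days_to_death", seed = seed),
    oyster = sim_config(
      n_families = 23L,
      offspring_per_family = split_offspring(718L, 23L),
      n_snps = 14028L, n_chromosomes = 10L, chrom_lengths = 56e6,
      h2_true = 0.49, fixed_effects = tank2, censor_day = 8L,
      trait_name = "days_to_death", seed = seed)
  )
  if (!is.null(h2)) cfg$h2_true <- h2
  cfg
}

#' Simulate founder individuals in linkage equilibrium
#'
#' Draws per-SNP population allele frequencies uniformly from
#' `config$maf_range`, places markers on chromosomes (marker counts
#' proportional to physical length, positions uniform), and samples phased
#' founder haplotypes binomially. Linkage disequilibrium within families
#' later arises from co-segregation during gene dropping, not from founder
#' haplotype structure.
#'
#' @param config a [sim_config()].
#' @return a `genotype_dataset` of `config$n_parents` founders carrying a
#'   `"haplotypes"` attribute (list of two phase matrices) used by
#'   [make_families()].
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 11L), {
    m <- config$n_snps
    n <- config$n_parents
    alloc <- largest_remainder(config$chrom_lengths, m)
    chr_lab <- sprintf("chr%02d", seq_len(config$n_chromosomes))
    chr <- rep(chr_lab, alloc)
    pos <- unlist(lapply(seq_len(config$n_chromosomes), function(i) {
      sort(ceiling(stats::runif(alloc[i], 0, config$chrom_lengths[i])))
    }))
    map <- data.frame(snp = sprintf("snp%06d", seq_len(m)),
                      chr = chr, pos = pos,
                      a1 = "A", a2 = "B", stringsAsFactors = FALSE)
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    h1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    h2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    geno <- h1 + h2
    fam <- data.frame(fid = "FOUNDERS",
                      iid = sprintf("P%04d", seq_len(n)),
                      sire = "0", dam = "0", sex = "0",
                      stringsAsFactors = FALSE)
    ds <- genotype_dataset(geno, map, fam)
    # genotype_dataset() sorts markers; keep the haplotypes aligned
    ord <- match(ds$map$snp, map$snp)
    attr(ds, "haplotypes") <- list(h1[, ord, drop = FALSE],
                                   h2[, ord, drop = FALSE])
    attr(ds, "founder_freq") <- p[ord]
    ds
  })
}

# Per-chromosome index/position structure reused across gametes.
chrom_structure <- function(map) {
  chrs <- unique(map$chr)
  lapply(chrs, function(cc) {
    idx <- which(map$chr == cc)
    list(idx = idx, pos = map$pos[idx])
  })
}

# One meiosis over one chromosome. Crossover count is Poisson with mean equal
# to the genetic length of the marker span in Morgans (Haldane model, no
# interference); crossover positions are uniform on the span.
meiosis_one_chrom <- function(h1, h2, pos, cm_per_mb) {
  span <- pos[length(pos)] - pos[1]
  len_morgan <- span * cm_per_mb / 1e8
  k <- stats::rpois(1L, len_morgan)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (k == 0L) {
    if (start == 0L) h1 else h2
  } else {
    cx <- sort(stats::runif(k, pos[1], pos[length(pos)]))
    strand <- (start + findInterval(pos, cx)) %% 2L
    ifelse(strand == 0L, h1, h2)
  }
}

#' Drop one gamete from a phased parent
#'
#' Simulates meiosis under the Haldane mapping model: per chromosome the
#' crossover count is Poisson with mean equal to the genetic length of the
#' marker span in Morgans (`span_bp * cm_per_mb / 1e8`), crossover positions
#' are uniform, and the returned haplotype alternates between the two
#' parental strands at each crossover. Chromosomes segregate independently.
#' Draws from R's current RNG stream; seed outside for reproducibility.
#'
#' @param parent_haplotypes a 2 x m matrix of 0/1 alleles (the two phases).
#' @param map marker map data.frame (`snp`, `chr`, `pos`), sorted by
#'   position within each chromosome.
#' @param cm_per_mb genetic-map scaling (0 switches recombination off).
#' @return integer vector of length m: the transmitted haplotype.
#' @export
drop_gamete <- function(parent_haplotypes, map, cm_per_mb = 1) {
  if (!is.matrix(parent_haplotypes) || nrow(parent_haplotypes) != 2L) {
    stop("parent_haplotypes must be a 2 x m matrix")
  }
  unsorted <- tapply(map$pos, as.character(map$chr),
                     function(p) is.unsorted(p))
  if (any(unlist(unsorted))) stop("marker map must be sorted within chromosome")
  gam <- integer(ncol(parent_haplotypes))
  for (cs in chrom_structure(map)) {
    gam[cs$idx] <- meiosis_one_chrom(parent_haplotypes[1L, cs$idx],
                                     parent_haplotypes[2L, cs$idx],
                                     cs$pos, cm_per_mb)
  }
  gam
}

#' Simulate full-sib families by gene dropping
#'
#' Pairs founders into `n_families` monogamous couples and generates each
#' offspring as the sum of one gamete from each parent. Offspring dosage is
#' polarized so that allele 1 is the minor allele in the offspring sample
#' (the genomic relationship matrix is invariant to this relabeling).
#'
#' @param config a [sim_config()].
#' @param founders optional founder `genotype_dataset` from
#'   [simulate_founders()] (must carry phased haplotypes); simulated
#'   internally when omitted.
#' @return a `genotype_dataset` of all offspring, with family ID, sire and
#'   dam recorded in `$fam`. The (consistently polarized) founder dataset is
#'   attached as attribute `"founders"`.
#' @export
make_families <- function(config, founders = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(founders)) founders <- simulate_founders(config)
  haps <- attr(founders, "haplotypes")
  if (is.null(haps)) stop("founders must carry phased haplotypes")
  if (config$n_families > nrow(founders$geno) %/% 2L) {
    stop("more families than available founder pairs")
  }
  with_seed(derive_seed(config$seed, 29L), {
    map <- founders$map
    cs <- chrom_structure(map)
    m <- nrow(map)
    n_off <- sum(config$offspring_per_family)
    geno <- matrix(0L, n_off, m)
    fid <- character(n_off); sire <- character(n_off); dam <- character(n_off)
    founder_iid <- founders$fam$iid
    row <- 0L
    for (f in seq_len(config$n_families)) {
      si <- 2L * f - 1L
      di <- 2L * f
      hs <- rbind(haps[[1]][si, ], haps[[2]][si, ])
      hd <- rbind(haps[[1]][di, ], haps[[2]][di, ])
      for (o in seq_len(config$offspring_per_family[f])) {
        row <- row + 1L
        g <- integer(m)
        for (ch in cs) {
          g[ch$idx] <-
            meiosis_one_chrom(hs[1L, ch$idx], hs[2L, ch$idx], ch$pos,
                              config$cm_per_mb) +
            meiosis_one_chrom(hd[1L, ch$idx], hd[2L, ch$idx], ch$pos,
                              config$cm_per_mb)
        }
        geno[row, ] <- g
        fid[row] <- sprintf("FAM%03d", f)
        sire[row] <- founder_iid[si]
        dam[row] <- founder_iid[di]
      }
    }
    # polarize to minor-allele dosage in the offspring sample
    freq <- colMeans(geno) / 2
    flip <- freq > 0.5
    if (any(flip)) {
      geno[, flip] <- 2L - geno[, flip]
      a1 <- map$a1; map$a1[flip] <- map$a2[flip]; map$a2[flip] <- a1[flip]
      fgeno <- founders$geno
      fgeno[, flip] <- 2L - fgeno[, flip]
      fmap <- founders$map
      fmap$a1 <- map$a1; fmap$a2 <- map$a2
      founders <- genotype_dataset(fgeno, fmap, founders$fam)
    }
    fam <- data.frame(fid = fid,
                      iid = sprintf("IND%05d", seq_len(n_off)),
                      sire = sire, dam = dam, sex = "0",
                      stringsAsFactors = FALSE)
    ds <- genotype_dataset(geno, map, fam)
    attr(ds, "founders") <- founders
    ds
  })
}

#' Simulate a polygenic trait with known ground truth
#'
#' Samples `n_qtl` causal markers, draws their effects from a standard
#' normal, and scales true breeding values (TBV) and residuals so that
#' `Var(TBV) / (Var(TBV) + Var(e)) = h2_true`. Fixed-effect factors are
#' assigned to individuals at random and their stated level effects (in
#' phenotypic SD units) added. An optional log transform or quantile-binned
#' right censoring (days to death) is applied last.
#'
#' @param dataset a `genotype_dataset` (no missing calls).
#' @param config the [sim_config()] that generated it.
#' @return a list with elements `phenotypes` (data.frame: `fid`, `iid`,
#'   `id`, the trait column, one column per factor; attributes `traits` and
#'   `factors`) and `truth` (class `truth_record`: `true_breeding_values`,
#'   `qtl_ids`, `qtl_effects`, `realized_h2`).
#' @export
simulate_trait <- function(dataset, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- n_individuals(dataset)
  if (n == 0L) stop("dataset is empty")
  if (config$n_qtl > n_markers(dataset)) stop("n_qtl exceeds marker count")
  with_seed(derive_seed(config$seed, 47L), {
    h2 <- config$h2_true
    qtl_idx <- sort(sample.int(n_markers(dataset), config$n_qtl))
    qtl_ids <- dataset$map$snp[qtl_idx]
    beta <- stats::rnorm(config$n_qtl)
    Xq <- dataset$geno[, qtl_idx, drop = FALSE]
    if (anyNA(Xq)) stop("simulate_trait requires complete genotypes")
    Xc <- sweep(Xq, 2L, colMeans(Xq))
    tbv_raw <- drop(Xc %*% beta)
    if (h2 > 0) {
      s <- stats::sd(tbv_raw)
      if (s == 0) stop("causal genotypes have zero variance; cannot reach h2_true > 0")
      scale_fac <- sqrt(h2) / s
    } else {
      scale_fac <- 0
    }
    tbv <- tbv_raw * scale_fac
    e <- stats::rnorm(n, 0, sqrt(1 - h2))
    y_gen <- tbv + e
    realized_h2 <- if (stats::var(y_gen) > 0) {
      stats::var(tbv) / stats::var(y_gen)
    } else 0
    sd_phen <- stats::sd(y_gen)
    latent <- y_gen
    pheno <- data.frame(fid = dataset$fam$fid,
                        iid = dataset$fam$iid,
                        id = individual_ids(dataset),
                        stringsAsFactors = FALSE)
    factor_names <- character(0)
    for (fe in config$fixed_effects) {
      lev <- sample.int(fe$n_levels, n, replace = TRUE)
      latent <- latent + fe$effects[lev] * sd_phen
      pheno[[fe$name]] <- paste0(fe$name, lev)
      factor_names <- c(factor_names, fe$name)
    }
    y <- switch(config$transform, none = latent, log = exp(latent))
    if (!is.null(config$censor_day)) {
      d <- config$censor_day
      y <- as.integer(ceiling(d * rank(y, ties.method = "first") / n))
      y[y < 1L] <- 1L
    }
    pheno[[config$trait_name]] <- y
    attr(pheno, "traits") <- config$trait_name
    attr(pheno, "factors") <- factor_names
    names(tbv) <- individual_ids(dataset)
    truth <- structure(list(true_breeding_values = tbv,
                            qtl_ids = qtl_ids,
                            qtl_effects = beta * scale_fac,
                            realized_h2 = realized_h2),
                       class = "truth_record")
    list(phenotypes = pheno, truth = truth)
  })
}

#' Simulate a complete dataset: genotypes, phenotypes, and ground truth
#'
#' @param config a [sim_config()], e.g. from [sim_preset()].
#' @return list with `genotypes` (a `genotype_dataset`), `phenotypes`,
#'   `truth`, and the `config` used.
#' @export
simulate_dataset <- function(config) {
  geno <- make_families(config)
  tr <- simulate_trait(geno, config)
  list(genotypes = geno, phenotypes = tr$phenotypes, truth = tr$truth,
       config = config)
}
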