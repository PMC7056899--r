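#' Put a simulated trait on its analysis scale
#'
#' Traits generated with `transform = "log"` are stored on the observed
#' (exponentiated) scale; the standard workflow log-transforms such skewed
#' traits before fitting the animal model. This helper applies that
#' transform; all other traits pass through unchanged.
#'
#' @param phenotypes phenotype data.frame from [simulate_trait()].
#' @param config the `sim_config` used.
#' @return the phenotype data.frame on the analysis scale.
#' @export
analysis_phenotypes <- function(phenotypes, config) {
  if (config$transform == "log") {
    phenotypes[[config$trait_name]] <- log(phenotypes[[config$trait_name]])
  }
  phenotypes
}

#' Factor column names of a simulation config
#' @param config a `sim_config`.
#' @return character vector (possibly empty).
#' @export
config_factors <- function(config) {
  vapply(config$fixed_effects, function(fe) fe$name, character(1))
}

#' Panel-density evaluation experiment on simulated populations
#'
#' The end-to-end pipeline, run once per preset population: simulate
#' genotypes and trait, apply QC, fit the full-panel REML heritability
#' (the accuracy denominator and the shrinkage baseline), draw replicate
#' random genome-wide panels at each requested density, run replicated
#' k-fold cross-validated GBLUP at every density plus the full panel, and
#' aggregate into an accuracy curve. Also fits the REML heritability for
#' replicate panels at `shrinkage_density` to quantify how much low
#' densities shrink the heritability estimate.
#'
#' @param presets character vector of [sim_preset()] names.
#' @param densities panel densities to evaluate against the full panel.
#' @param n_panels random panels per density.
#' @param cv_replicates replicates of k-fold cross-validation.
#' @param k_folds folds per replicate.
#' @param shrinkage_density density for the heritability-shrinkage
#'   comparison (`NULL` to skip).
#' @param shrinkage_panels panels at that density.
#' @param seed master seed; every stage derives its own stream from it.
#' @param verbose print progress.
#' @return list with one element per preset (each containing `curve`,
#'   `cv_results`, `h2_full`, `se_h2_full`, `h2_shrinkage` with the
#'   percent decrease at `shrinkage_density`, `qc_report`, `n_snps_full`)
#'   plus `summary`: a data.frame of per-density proportions of
#'   full-panel accuracy, per preset and averaged.
#' @export
run_density_experiment <- function(presets = c("salmon", "carp", "seabream",
                                               "oyster"),
                                   densities = c(100L, 500L, 1000L, 2000L),
                                   n_panels = 3L,
                                   cv_replicates = 2L,
                                   k_folds = 5L,
                                   shrinkage_density = 200L,
                                   shrinkage_panels = 5L,
                                   seed = 1L,
                                   verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  out <- list()
  for (pi in seq_along(presets)) {
    preset <- presets[pi]
    say("== ", preset, ": simulating")
    cfg <- sim_preset(preset, seed = derive_seed(seed, 1000L + pi))
    sim <- simulate_dataset(cfg)
    phen <- analysis_phenotypes(sim$phenotypes, cfg)
    factors <- config_factors(cfg)
    trait <- cfg$trait_name

    say("== ", preset, ": quality control")
    qc <- apply_qc(sim$genotypes)
    ds <- qc$dataset
    m_full <- n_markers(ds)
    phen <- phen[phen$id %in% individual_ids(ds), , drop = FALSE]

    say("== ", preset, ": full-panel REML (", m_full, " SNPs)")
    grm_full <- build_grm(ds)
    vc_full <- fit_genomic_model(grm_full, phen, trait, factors)
    h2_ref <- vc_full$h2

    des <- build_design(phen, trait, factors)
    folds <- make_folds(des$ids, k = k_folds,
                        replicate_seeds = vapply(
                          seq_len(cv_replicates),
                          function(r) derive_seed(seed, 2000L + pi, r),
                          integer(1)))

    dens_ok <- densities[densities <= m_full]
    panels <- make_panel_set(ds, grid = sort(unique(dens_ok)),
                             replicates = n_panels,
                             strategy = "genomewide_random",
                             master_seed = derive_seed(seed, 3000L + pi))
    full_panel <- sample_panel(ds, m_full, "genomewide_random",
                               seed = derive_seed(seed, 3500L + pi),
                               replicate_index = 1L)

    say("== ", preset, ": cross-validation (", length(panels),
        " low-density panels + full)")
    res_full <- run_cv(ds, phen, trait, factors, full_panel, folds,
                       h2_ref = h2_ref, grm = grm_full)
    res_low <- lapply(panels, function(pn) {
      run_cv(ds, phen, trait, factors, pn, folds, h2_ref = h2_ref)
    })
    cv_results <- do.call(rbind, c(list(res_full), res_low))
    curve <- accuracy_curve(cv_results, full_density = m_full)

    h2_shrinkage <- NULL
    if (!is.null(shrinkage_density) && shrinkage_density <= m_full) {
      say("== ", preset, ": heritability shrinkage at ", shrinkage_density,
          " SNPs")
      pans200 <- make_panel_set(ds, grid = shrinkage_density,
                                replicates = shrinkage_panels,
                                strategy = "genomewide_random",
                                master_seed = derive_seed(seed, 4000L + pi))
      h2c <- estimate_h2_curve(ds, phen, trait, factors, pans200)
      mean_h2_low <- mean(h2c$h2[h2c$converged])
      h2_shrinkage <- list(
        density = shrinkage_density,
        h2_panels = h2c,
        mean_h2_low = mean_h2_low,
        percent_decrease = 100 * (h2_ref - mean_h2_low) / h2_ref)
    }

    out[[preset]] <- list(curve = curve,
                          cv_results = cv_results,
                          h2_full = h2_ref,
                          se_h2_full = vc_full$se_h2,
                          h2_shrinkage = h2_shrinkage,
                          qc_report = qc$report,
                          n_snps_full = m_full,
                          realized_h2 = sim$truth$realized_h2)
  }

  all_dens <- sort(unique(unlist(lapply(out, function(r) r$curve$density))))
  low_dens <- setdiff(all_dens,
                      vapply(out, function(r) r$n_snps_full, numeric(1)))
  summary_df <- do.call(rbind, lapply(low_dens, function(d) {
    props <- vapply(out, function(r) {
      cu <- r$curve
      if (d %in% cu$density) cu$proportion_full[cu$density == d] else NA_real_
    }, numeric(1))
    data.frame(density = d,
               t(stats::setNames(props, names(out))),
               mean_proportion = mean(props, na.rm = TRUE))
  }))
  list(datasets = out, summary = summary_df)
}
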