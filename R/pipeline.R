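#' Pipeline configuration
#'
#' One declarative object tying together the simulation design and every
#' analysis constant, so a whole run is reproducible from the
#' configuration and seed alone.
#'
#' @param design A [cohort_design()]; its seed drives all per-stage
#'   sub-seeds.
#' @param outdir Optional output directory; when given, every stage writes
#'   its table there.
#' @param n_positive_controls Positive-control runs per assay series.
#' @param onset_window,rise_threshold Recirculation-onset detection
#'   parameters, see [detect_ehr_onset()].
#' @param prevalence_min_fraction Marker prevalence filter threshold.
#' @param restriction_min_rel,restriction_min_fraction Taxa restriction
#'   filter thresholds (percent, fraction).
#' @param n_perm Permutations for PERMANOVA.
#' @param min_library_reads Library-size sample filter.
#' @param da_groups Length-2 group labels compared by the
#'   differential-abundance screen.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(),
                            outdir = NULL,
                            n_positive_controls = 11L,
                            onset_window = c(3, 11),
                            rise_threshold = 0.1,
                            prevalence_min_fraction = 0.5,
                            restriction_min_rel = 0.01,
                            restriction_min_fraction = 0.5,
                            n_perm = 999L,
                            min_library_reads = 2.9e6,
                            da_groups = c("week_1", "pre_tx")) {
  stopifnot(inherits(design, "cohort_design"))
  if (n_positive_controls < 2) stop("need at least 2 positive controls")
  structure(
    list(design = design, outdir = outdir,
         n_positive_controls = as.integer(n_positive_controls),
         onset_window = onset_window, rise_threshold = rise_threshold,
         prevalence_min_fraction = prevalence_min_fraction,
         restriction_min_rel = restriction_min_rel,
         restriction_min_fraction = restriction_min_fraction,
         n_perm = as.integer(n_perm),
         min_library_reads = min_library_reads,
         da_groups = da_groups),
    class = "pipeline_config"
  )
}

#' Run the full simulation-to-statistics pipeline
#'
#' Executes the analysis chain end to end on a simulated cohort: cohort
#' generation, assay simulation and reactivation-rate estimation, control
#' QC, pharmacokinetic simulation and non-compartmental analysis, the
#' rate-recirculation correlation, the gene-marker association screen, and
#' the community statistics. Sub-seeds for each stochastic stage are
#' derived deterministically from the design seed, so identical
#' configurations yield identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage outputs and headline
#'   statistics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  base_seed <- design$seed
  stage_seed <- function(k) (base_seed + k) %% .Machine$integer.max

  cohort <- simulate_cohort(design)
  n <- nrow(cohort)

  # assay stage: one time course and rate estimate per subject
  set.seed(stage_seed(1L))
  tcs <- lapply(seq_len(n), function(i) {
    simulate_assay_timecourse(cohort[i, ], "sample", design)
  })
  rate_tab <- do.call(rbind, lapply(tcs, function(tc) {
    est <- estimate_reactivation_rate(tc, warn_depletion = FALSE)
    data.frame(sample_id = est$sample_id, rate = est$rate,
               stderr = est$stderr, r_squared = est$r_squared,
               baseline_subtracted = est$baseline_subtracted,
               below_lloq_points = est$below_lloq_points,
               flagged_negative = est$flagged_negative,
               stringsAsFactors = FALSE)
  }))
  rates <- stats::setNames(rate_tab$rate, rate_tab$sample_id)

  # control QC stage
  set.seed(stage_seed(2L))
  negative <- simulate_assay_timecourse(0, "negative_control", design)
  positives <- lapply(seq_len(config$n_positive_controls), function(i) {
    simulate_assay_timecourse(NA, "positive_control", design,
                              sample_id = sprintf("positive_%02d", i))
  })
  qc <- qc_controls(negative, positives, design$achim_rate)

  # pharmacokinetic stage
  set.seed(stage_seed(3L))
  profiles <- lapply(seq_len(n), function(i) {
    simulate_pk_profile(cohort[i, ], design)
  })
  pk <- summarize_pk_cohort(profiles, nominal_times = design$pk_times,
                            window = config$onset_window,
                            rise_threshold = config$rise_threshold)
  ehr <- stats::setNames(pk$nca$ehr_percent, pk$nca$patient_id)
  rate_ehr <- spearman_test(rates[names(ehr)], ehr)

  # gene-marker association stage
  genes <- simulate_gus_gene_table(cohort, seed = stage_seed(4L))
  rpkm <- compute_rpkm(genes)
  filtered <- prevalence_filter(rpkm, config$prevalence_min_fraction)
  association <- correlate_markers_with_rates(filtered, rates)
  grp2 <- ifelse(cohort$group == "healthy", "healthy", "patient")
  names(grp2) <- cohort$subject_id
  totals <- if (length(unique(grp2)) == 2) {
    compare_group_totals(rpkm, grp2)
  } else NULL

  # community stage
  taxa <- simulate_taxa_table(cohort, seed = stage_seed(5L))
  taxa <- filter_min_library(taxa, config$min_library_reads)
  alpha <- apply(taxa$values, 2, shannon)
  d <- bray_curtis(taxa)
  md <- taxa$metadata
  perm_group <- permanova(d, md$group, n_perm = config$n_perm,
                          seed = stage_seed(6L))
  rate_cov <- rates[md$sample_id]
  perm_rate <- permanova(d, unname(rate_cov), n_perm = config$n_perm,
                         seed = stage_seed(7L))
  grp2_taxa <- ifelse(md$group == "healthy", "healthy", "patient")
  dist_test <- if (length(unique(grp2_taxa)) == 2 &&
                   min(table(grp2_taxa)) >= 2) {
    within_group_distance_test(d, grp2_taxa)
  } else NULL
  da <- NULL
  da_taxa <- character(0)
  if (all(config$da_groups %in% md$group) &&
      min(table(md$group)[config$da_groups]) >= 3) {
    da_taxa <- restriction_filter(taxa, config$da_groups,
                                  config$restriction_min_rel,
                                  config$restriction_min_fraction)
    da <- differential_abundance_screen(taxa, config$da_groups,
                                        taxa = da_taxa,
                                        min_rel = config$restriction_min_rel)
  }

  outputs <- list()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(config$outdir, f)
    write_assay_csv(tcs, op("assay_timecourses.csv"))
    write_rates_csv(rates, op("rates.csv"))
    write_pk_csv(profiles, op("pk_profiles.csv"))
    utils::write.csv(pk$nca, op("nca.csv"), row.names = FALSE)
    utils::write.csv(pk$profile_summary, op("pk_mean_sem.csv"),
                     row.names = FALSE)
    write_marker_tsv(genes, op("gus_markers.tsv"))
    write_catalog_tsv(genes$catalog, op("gus_catalog.tsv"))
    utils::write.csv(association, op("gus_association.csv"),
                     row.names = FALSE)
    write_taxa_tsv(taxa, op("taxa_percent.tsv"))
    utils::write.csv(md, op("taxa_metadata.csv"), row.names = FALSE)
    if (!is.null(da)) utils::write.csv(da, op("da_screen.csv"),
                                       row.names = FALSE)
    outputs <- list(
      assay = op("assay_timecourses.csv"), rates = op("rates.csv"),
      pk = op("pk_profiles.csv"), nca = op("nca.csv"),
      markers = op("gus_markers.tsv"), association = op("gus_association.csv"),
      taxa = op("taxa_percent.tsv")
    )
  }

  structure(
    list(
      seed = base_seed,
      config = config,
      cohort = cohort,
      rates = rate_tab,
      qc = qc,
      nca = pk$nca,
      pk_mean_sem = pk$profile_summary,
      rate_ehr_spearman = rate_ehr,
      association = association,
      group_totals = totals,
      shannon = alpha,
      bray_curtis = d,
      permanova_group = perm_group,
      permanova_rate = perm_rate,
      within_group_distance = dist_test,
      restriction_taxa = da_taxa,
      da_screen = da,
      headline = list(
        group_rate_means = tapply(rate_tab$rate, cohort$group, mean),
        qc_cv_percent = qc$cv_percent,
        rate_ehr_rho = rate_ehr$statistic,
        top_marker = association$marker_id[1]
      ),
      outputs = outputs
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  cat(sprintf("  %d subjects in %d groups\n", nrow(x$cohort),
              length(unique(x$cohort$group))))
  cat(sprintf("  control QC CV: %.2f%%\n", x$qc$cv_percent))
  cat(sprintf("  rate-EHR Spearman rho: %.3f (p = %.3g)\n",
              x$rate_ehr_spearman$statistic, x$rate_ehr_spearman$p_value))
  cat(sprintf("  top-ranked marker: %s\n", x$headline$top_marker))
  invisible(x)
}
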