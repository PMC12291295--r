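#' Marker-by-sample feature table
#'
#' Container for gene-marker abundance matrices as produced by
#' marker-mapping pipelines: raw mapped-read counts or RPKM values, a
#' per-sample library size, and a marker catalog carrying the target length
#' and taxon assignment needed for RPKM normalisation and annotation.
#'
#' @param values Numeric matrix, markers in rows, samples in columns,
#'   non-negative, with unique dimnames.
#' @param value_kind `"counts"` or `"rpkm"`.
#' @param library_sizes Named vector of per-sample read counts; required
#'   (and positive) when `value_kind = "counts"`.
#' @param catalog Data frame with columns `marker_id`, `length_bp`,
#'   `taxon` (additional columns are kept).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, value_kind = c("counts", "rpkm"),
                          library_sizes = NULL, catalog = NULL) {
  value_kind <- match.arg(value_kind)
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("feature values must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs marker rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate marker labels")
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  if (value_kind == "counts") {
    if (is.null(library_sizes)) stop("counts require library_sizes")
    library_sizes <- library_sizes[colnames(values)]
    if (anyNA(library_sizes) || any(library_sizes <= 0)) {
      stop("library_sizes must be positive for every sample")
    }
  }
  if (!is.null(catalog)) {
    req <- c("marker_id", "length_bp", "taxon")
    if (!all(req %in% names(catalog))) {
      stop("catalog must have columns ", paste(req, collapse = ", "))
    }
    if (anyDuplicated(catalog$marker_id)) stop("duplicate catalog marker_id")
  }
  structure(
    list(values = values, value_kind = value_kind,
         library_sizes = library_sizes, catalog = catalog),
    class = "feature_table"
  )
}

#' Default beta-glucuronidase marker catalog
#'
#' A compact synthetic catalog emulating the structure of a gene-variant
#' reference: a strongly rate-predictive Faecalibacterium prausnitzii
#' marker, a few weakly predictive variants, a highly abundant but inert
#' Faecalibacterium variant, and assorted inert markers from other
#' glucuronidase-carrying taxa, several of them sparse enough to fall below
#' a 50% prevalence filter. `causal_weight` scales how strongly a marker's
#' abundance tracks the subject's true reactivation rate (0 = inert);
#' `base_meanlog`/`base_sdlog` parameterise the lognormal baseline
#' abundance (RPKM) and `dropout_prob` the probability a marker goes
#' unobserved in a sample.
#'
#' @return Data frame with columns `marker_id`, `length_bp`, `taxon`,
#'   `causal_weight`, `base_meanlog`, `base_sdlog`, `dropout_prob`.
#' @export
default_gus_catalog <- function() {
  data.frame(
    marker_id = c(
      "FP_GUS_A1", "FP_GUS_A2", "FP_GUS_A3", "FP_GUS_B1", "FP_GUS_B2",
      "BF_GUS_1", "BF_GUS_2", "BU_GUS_1", "BT_GUS_1", "EC_GUS_1",
      "RG_GUS_1", "RH_GUS_1", "CL_GUS_1", "CL_GUS_2", "RI_GUS_1",
      "AK_GUS_1", "PR_GUS_1", "LC_GUS_1"
    ),
    length_bp = c(1809L, 1812L, 1797L, 1950L, 1902L, 1893L, 1860L, 1845L,
                  1878L, 1812L, 1791L, 1800L, 1764L, 1770L, 1806L, 1920L,
                  1836L, 1755L),
    taxon = c(
      rep("Faecalibacterium_prausnitzii", 5),
      "Bacteroides_fragilis", "Bacteroides_fragilis",
      "Bacteroides_uniformis", "Bacteroides_thetaiotaomicron",
      "Escherichia_coli", "Ruminococcus_gnavus", "Roseburia_hominis",
      "Clostridium_sp", "Clostridium_sp", "Roseburia_intestinalis",
      "Akkermansia_muciniphila", "Prevotella_copri", "Lacticaseibacillus_sp"
    ),
    causal_weight = c(1.5, 0.4, 0.3, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                      0, 0, 0),
    base_meanlog = log(c(20, 8, 6, 150, 30, 5, 4, 12, 10, 25, 7, 6, 3, 2,
                         9, 4, 15, 1)),
    base_sdlog = c(0.9, 0.9, 0.9, 0.7, 0.8, 1.0, 1.0, 0.9, 0.9, 0.8, 0.9,
                   0.9, 1.0, 1.0, 0.9, 1.1, 0.9, 1.0),
    dropout_prob = c(0.05, 0.10, 0.15, 0.02, 0.10, 0.60, 0.65, 0.20, 0.25,
                     0.05, 0.30, 0.35, 0.55, 0.60, 0.25, 0.40, 0.15, 0.70),
    stringsAsFactors = FALSE
  )
}

#' Simulate a gene-marker count table for a cohort
#'
#' Per marker and subject, a lognormal baseline abundance (RPKM scale) is
#' modulated by `exp(causal_weight * z)` where `z` is the subject's
#' standardised true reactivation rate, converted to an expected mapped
#' read count through the marker length and a lognormal library size, and
#' drawn as a Poisson count. Marker-specific dropout zeroes a configurable
#' fraction of entries to create prevalence structure.
#'
#' @param cohort An `mpa_cohort` data frame from [simulate_cohort()].
#' @param catalog Marker catalog; defaults to [default_gus_catalog()].
#' @param seed Optional integer seed.
#' @param library_meanlog,library_sdlog Lognormal parameters of the
#'   per-sample library size (reads).
#' @return A [feature_table()] with `value_kind = "counts"`, library sizes
#'   and the catalog attached.
#' @export
simulate_gus_gene_table <- function(cohort, catalog = default_gus_catalog(),
                                    seed = NULL,
                                    library_meanlog = log(3.5e7),
                                    library_sdlog = 0.5) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 2)
  if (nrow(catalog) == 0) stop("catalog must be non-empty")
  if (!any(catalog$causal_weight > 0)) {
    stop("catalog needs at least one causal marker")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- as.numeric(scale(cohort$true_rate))
  if (anyNA(z)) z <- rep(0, nrow(cohort))  # zero-variance cohort
  n_s <- nrow(cohort)
  n_m <- nrow(catalog)
  libs <- round(stats::rlnorm(n_s, library_meanlog, library_sdlog))
  libs <- pmax(libs, 5e5)
  names(libs) <- cohort$subject_id
  counts <- matrix(0L, nrow = n_m, ncol = n_s,
                   dimnames = list(catalog$marker_id, cohort$subject_id))
  for (m in seq_len(n_m)) {
    meanlog <- catalog$base_meanlog[m] + catalog$causal_weight[m] * z
    rpkm_true <- stats::rlnorm(n_s, meanlog, catalog$base_sdlog[m])
    lambda <- rpkm_true * (catalog$length_bp[m] / 1000) * (libs / 1e6)
    cts <- stats::rpois(n_s, lambda)
    cts[stats::runif(n_s) < catalog$dropout_prob[m]] <- 0L
    counts[m, ] <- cts
  }
  feature_table(counts, value_kind = "counts", library_sizes = libs,
                catalog = catalog)
}
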