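#' Taxon-by-sample relative abundance table
#'
#' Container for species-level relative abundance profiles (percent,
#' summing to 100 per sample) together with per-sample metadata.
#'
#' @param values Numeric matrix, taxa in rows, samples in columns; each
#'   column must sum to the declared `total` within `1e-6`.
#' @param metadata Data frame with one row per sample: `sample_id`,
#'   `subject_id`, `group`, `library_size`.
#' @param total Declared per-sample total (100 for percent, 1 for
#'   proportions).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, metadata, total = 100) {
  stopifnot(is.matrix(values), is.data.frame(metadata))
  if (any(values < 0)) stop("abundances must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs taxon rownames and sample colnames")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  if (anyDuplicated(rownames(values))) stop("duplicate taxon labels")
  sums <- colSums(values)
  bad <- which(abs(sums - total) > 1e-6 * max(1, total))
  if (length(bad)) {
    stop("sample '", colnames(values)[bad[1]], "' sums to ",
         format(sums[bad[1]]), " instead of ", total)
  }
  req <- c("sample_id", "group")
  if (!all(req %in% names(metadata))) {
    stop("metadata must have columns ", paste(req, collapse = ", "))
  }
  if (!identical(sort(metadata$sample_id), sort(colnames(values)))) {
    stop("metadata sample_id must match table columns")
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  structure(list(values = values, metadata = metadata, total = total),
            class = "abundance_table")
}

#' Default taxa profile for the community simulator
#'
#' Group-specific geometric-mean relative abundances (percent) for the two
#' focal species whose printed shifts the simulator reproduces — an
#' Akkermansia muciniphila-like taxon collapsing after transplantation
#' (2.52% pre-transplant, 0.14% at week 1, 0.02% at weeks 3-6) and a
#' Faecalibacterium prausnitzii-like taxon rising from 4.2% pre-transplant
#' to 7% at one year — plus a fixed spectrum of background taxa shared
#' across groups, spanning abundances above and below the 0.01% restriction
#' threshold.
#'
#' @param n_background Number of background taxa.
#' @return Data frame with columns `taxon`, `base_sdlog` and one
#'   `gm_<group>` column per default group.
#' @export
default_taxa_profile <- function(n_background = 48) {
  groups <- default_cohort_groups()$label
  focal <- data.frame(
    taxon = c("Akkermansia_muciniphila", "Faecalibacterium_prausnitzii"),
    base_sdlog = c(0.8, 0.6),
    gm_pre_tx = c(2.52, 4.2),
    gm_week_1 = c(0.14, 8.2),
    gm_week_3_6 = c(0.02, 10.9),
    gm_year_1 = c(0.10, 7.0),
    gm_healthy = c(2.0, 5.0),
    stringsAsFactors = FALSE
  )
  gm_bg <- exp(seq(log(8), log(0.002), length.out = n_background))
  bg <- data.frame(
    taxon = sprintf("SGB%04d", seq_len(n_background)),
    base_sdlog = 0.6,
    stringsAsFactors = FALSE
  )
  for (g in groups) bg[[paste0("gm_", g)]] <- gm_bg
  out <- rbind(focal, bg[, names(focal)])
  rownames(out) <- NULL
  out
}

#' Simulate a taxa relative-abundance table for a cohort
#'
#' Draws lognormal abundances around group-specific geometric means and
#' renormalises each sample to 100%. Library sizes are lognormal around the
#' sequencing depth typical of deep shotgun metagenomes so the library-size
#' sample filter can be exercised.
#'
#' @param cohort An `mpa_cohort` data frame.
#' @param taxa Taxa profile; defaults to [default_taxa_profile()].
#' @param seed Optional integer seed.
#' @param library_meanlog,library_sdlog Lognormal parameters of the
#'   per-sample sequencing library size (reads).
#' @return An [abundance_table()] in percent.
#' @export
simulate_taxa_table <- function(cohort, taxa = default_taxa_profile(),
                                seed = NULL,
                                library_meanlog = log(3.2e7),
                                library_sdlog = 0.75) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1, nrow(taxa) >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_s <- nrow(cohort)
  n_t <- nrow(taxa)
  vals <- matrix(0, nrow = n_t, ncol = n_s,
                 dimnames = list(taxa$taxon, cohort$subject_id))
  for (j in seq_len(n_s)) {
    col <- paste0("gm_", cohort$group[j])
    if (!col %in% names(taxa)) {
      stop("taxa profile has no geometric means for group '",
           cohort$group[j], "'")
    }
    vals[, j] <- stats::rlnorm(n_t, meanlog = log(taxa[[col]]),
                               sdlog = taxa$base_sdlog)
  }
  vals <- sweep(vals, 2, colSums(vals), "/") * 100
  libs <- round(stats::rlnorm(n_s, library_meanlog, library_sdlog))
  abundance_table(
    vals,
    metadata = data.frame(sample_id = cohort$subject_id,
                          subject_id = cohort$subject_id,
                          group = cohort$group,
                          library_size = libs,
                          stringsAsFactors = FALSE),
    total = 100
  )
}
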