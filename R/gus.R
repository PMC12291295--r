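#' Normalise mapped-read counts to RPKM
#'
#' Reads per kilobase of target sequence per million reads in library:
#' `count / (length_bp/1000) / (library_size/1e6)` per marker and sample.
#'
#' @param table A [feature_table()] with `value_kind = "counts"`, catalog
#'   lengths and library sizes present.
#' @return A [feature_table()] with `value_kind = "rpkm"`.
#' @examples
#' ct <- feature_table(matrix(1000, 1, 1, dimnames = list("m1", "s1")),
#'                     "counts", c(s1 = 1e6),
#'                     data.frame(marker_id = "m1", length_bp = 1000L,
#'                                taxon = "t"))
#' compute_rpkm(ct)$values # 1000 RPKM
#' @export
compute_rpkm <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$value_kind != "counts") stop("input must hold raw counts")
  if (is.null(table$catalog)) stop("catalog with marker lengths required")
  if (is.null(table$library_sizes)) stop("library sizes required")
  len <- table$catalog$length_bp[match(rownames(table$values),
                                       table$catalog$marker_id)]
  if (anyNA(len)) stop("catalog is missing lengths for some markers")
  rpkm <- sweep(table$values, 1, len / 1000, "/")
  rpkm <- sweep(rpkm, 2, table$library_sizes / 1e6, "/")
  feature_table(rpkm, value_kind = "rpkm",
                library_sizes = table$library_sizes,
                catalog = table$catalog)
}

#' Filter markers by prevalence
#'
#' Keeps markers observed (value above the detection threshold) in at least
#' `min_fraction` of the samples; the boundary is inclusive and the row
#' order is preserved.
#'
#' @param table A [feature_table()].
#' @param min_fraction Minimum fraction of samples, in `(0, 1]`.
#' @param detection_eps Values strictly above this count as observed.
#' @return The filtered [feature_table()].
#' @export
prevalence_filter <- function(table, min_fraction = 0.5,
                              detection_eps = 0) {
  stopifnot(inherits(table, "feature_table"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]")
  }
  keep <- rowMeans(table$values > detection_eps) >= min_fraction
  feature_table(table$values[keep, , drop = FALSE],
                value_kind = table$value_kind,
                library_sizes = table$library_sizes,
                catalog = table$catalog)
}

#' Rank gene markers by correlation with reactivation rates
#'
#' Per marker, the rank correlation (average ranks for ties) between its
#' abundance across samples and the per-sample reactivation rate, with
#' Benjamini-Hochberg q-values computed across the marker set actually
#' tested. Markers with constant abundance get `NA` correlations and are
#' excluded from the multiplicity correction.
#'
#' @param table A [feature_table()] (typically RPKM after
#'   [prevalence_filter()]).
#' @param rates Named numeric vector of reactivation rates; names must
#'   cover the table's samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Data frame of class `gus_association`, sorted by decreasing
#'   correlation: `marker_id`, `taxon`, `rho`, `p_value`, `q_value`,
#'   `prevalence`, `mean_abundance`.
#' @export
correlate_markers_with_rates <- function(table, rates,
                                         method = c("spearman", "pearson")) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  samples <- colnames(table$values)
  if (is.null(names(rates))) {
    if (length(rates) != length(samples)) {
      stop("unnamed 'rates' must match the number of samples")
    }
    names(rates) <- samples
  }
  if (!all(samples %in% names(rates))) {
    stop("rates are missing for some samples")
  }
  rates <- rates[samples]
  if (length(samples) < 4) stop("need at least 4 samples")
  if (stats::sd(rates) == 0) {
    stop("constant rate vector: correlation undefined")
  }
  res <- lapply(rownames(table$values), function(m) {
    x <- table$values[m, ]
    if (stats::sd(x) == 0) {
      return(data.frame(marker_id = m, rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, rates, method = method, exact = FALSE)
    )
    data.frame(marker_id = m, rho = unname(ct$estimate),
               p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- bh_adjust(out$p_value[tested])
  out$prevalence <- rowMeans(table$values > 0)
  out$mean_abundance <- rowMeans(table$values)
  if (!is.null(table$catalog)) {
    out$taxon <- table$catalog$taxon[match(out$marker_id,
                                           table$catalog$marker_id)]
  } else {
    out$taxon <- NA_character_
  }
  out <- out[order(-out$rho, na.last = TRUE), c(
    "marker_id", "taxon", "rho", "p_value", "q_value", "prevalence",
    "mean_abundance")]
  rownames(out) <- NULL
  class(out) <- c("gus_association", "data.frame")
  out
}

#' Compare total marker mapping between two groups
#'
#' Sums each sample's abundance over all markers and compares the two
#' groups with Welch's unequal-variance two-sample t-test.
#'
#' @param table A [feature_table()].
#' @param groups Named character vector (or factor) assigning each sample
#'   to one of exactly two groups.
#' @return List with `statistic` (t), `df`, `p_value`, `group_means` and
#'   `totals`.
#' @export
compare_group_totals <- function(table, groups) {
  stopifnot(inherits(table, "feature_table"))
  samples <- colnames(table$values)
  groups <- groups[samples]
  if (anyNA(groups)) stop("group labels missing for some samples")
  lev <- unique(as.character(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  totals <- colSums(table$values)
  x <- totals[groups == lev[1]]
  y <- totals[groups == lev[2]]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 samples")
  tt <- welch_t(x, y)
  list(statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
       group_means = stats::setNames(c(mean(x), mean(y)), lev),
       totals = totals)
}
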