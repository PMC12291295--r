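# Resolve a taxa input into a plain taxon-by-sample matrix.
.as_taxa_matrix <- function(table) {
  if (inherits(table, "abundance_table")) table$values else as.matrix(table)
}

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log(p_i))` over the non-zero proportions, after
#' renormalising the abundances to sum to 1. Natural-log units by default
#' (the ecology convention); other bases via `base`.
#'
#' @param x Non-negative abundance vector with at least one non-zero entry.
#' @param base Logarithm base.
#' @return Shannon index.
#' @examples
#' shannon(rep(25, 4)) # log(4)
#' @export
shannon <- function(x, base = exp(1)) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) stop("all-zero sample")
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` between every pair of
#' samples, computed on relative abundances.
#'
#' @param table An [abundance_table()] or a taxon-by-sample matrix with at
#'   least 2 samples.
#' @return A square symmetric matrix with zero diagonal and entries in
#'   `[0, 1]`, labelled by sample.
#' @export
bray_curtis <- function(table) {
  m <- .as_taxa_matrix(table)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (any(colSums(m) == 0)) stop("zero-sum sample")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Gower-centers the squared distance matrix and partitions its total sum
#' of squares against the predictor's hat matrix (one-hot design for
#' factors, a single column for continuous covariates, intercept included).
#' The permutation p-value carries the `1/(n_perm+1)` floor so p is never
#' reported as 0; alternatively an explicit permutation matrix (e.g. the
#' full enumeration for tiny designs) can be supplied.
#'
#' @param dist Square distance matrix (or `dist` object) with sample
#'   labels.
#' @param predictor Factor/character (grouping) or numeric (covariate),
#'   one value per sample, in the order of the distance matrix.
#' @param n_perm Number of random label permutations.
#' @param seed Integer seed for the permutations.
#' @param permutations Optional integer matrix, one permutation of
#'   `1:n` per row, used instead of random permutations; the p-value is
#'   then the fraction of supplied permutations with `F >= F_observed`.
#' @return An `mpa_test` with `statistic` = pseudo-F, plus `r_squared`,
#'   `df`, `n_perm` and `seed`.
#' @export
permanova <- function(dist, predictor, n_perm = 999, seed = 1L,
                      permutations = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 samples")
  if (length(predictor) != n) stop("one predictor value per sample required")
  if (is.numeric(predictor)) {
    if (stats::var(predictor) == 0) stop("constant predictor: no contrast")
    X <- cbind(1, predictor)
  } else {
    predictor <- factor(predictor)
    if (nlevels(predictor) < 2) stop("constant predictor: no contrast")
    X <- stats::model.matrix(~predictor)
  }
  rank <- qr(X)$rank
  df_model <- rank - 1
  df_resid <- n - rank
  if (df_resid <= 0) stop("confounded design: zero residual degrees of freedom")
  H <- X %*% solve(crossprod(X), t(X))
  pseudo_f <- function(dm) {
    A <- -0.5 * dm^2
    rm <- rowMeans(A)
    G <- A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
    ss_total <- sum(diag(G))
    ss_model <- sum(H * G)  # trace(H G) for symmetric G
    ss_resid <- ss_total - ss_model
    c(f = (ss_model / df_model) / (ss_resid / df_resid),
      r2 = ss_model / ss_total)
  }
  obs <- pseudo_f(d)
  if (is.null(permutations)) {
    set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      if (pseudo_f(d[p, p])["f"] >= obs["f"] - 1e-12) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  } else {
    stopifnot(is.matrix(permutations), ncol(permutations) == n)
    fs <- apply(permutations, 1, function(p) pseudo_f(d[p, p])["f"])
    p_value <- mean(fs >= obs["f"] - 1e-12)
    n_used <- nrow(permutations)
  }
  .mpa_test("permanova_pseudo_F", obs["f"], p_value, n,
            extra = list(r_squared = unname(obs["r2"]),
                         df = c(model = df_model, residual = df_resid),
                         n_perm = n_used, seed = seed))
}

#' Compare within-group pairwise distances between two groups
#'
#' Pools each group's within-group pairwise dissimilarities and compares
#' the two multisets with an unpaired two-sample t-test. Pairwise
#' distances sharing samples are not independent; the result carries an
#' explicit caveat flag rather than silently endorsing the assumption.
#'
#' @param dist Square distance matrix with sample labels.
#' @param groups Vector of group labels, one per sample (exactly two
#'   groups, each with at least 2 samples).
#' @return List with `statistic`, `p_value`, per-group `means`, `sds`,
#'   `n_pairs`, the pooled `distances` and `nonindependence_caveat = TRUE`.
#' @export
within_group_distance_test <- function(dist, groups) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (length(groups) != n) stop("one group label per sample required")
  lev <- unique(as.character(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  pull <- function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      stop("group '", g, "' needs at least 2 samples")
    }
    d[idx, idx][upper.tri(diag(length(idx)))]
  }
  dx <- pull(lev[1])
  dy <- pull(lev[2])
  tt <- stats::t.test(dx, dy, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       means = stats::setNames(c(mean(dx), mean(dy)), lev),
       sds = stats::setNames(c(stats::sd(dx), stats::sd(dy)), lev),
       n_pairs = stats::setNames(c(length(dx), length(dy)), lev),
       distances = stats::setNames(list(dx, dy), lev),
       nonindependence_caveat = TRUE)
}

#' Restriction filter for differential-abundance testing
#'
#' For a given pair of groups, keeps taxa observed at a relative abundance
#' of at least `min_rel` in at least `min_fraction` of the samples pooled
#' across the two groups (both boundaries inclusive).
#'
#' @param table An [abundance_table()].
#' @param groups Length-2 character vector naming the two compared groups.
#' @param min_rel Minimum relative abundance (same units as the table,
#'   percent by default).
#' @param min_fraction Minimum fraction of the pooled samples.
#' @return Character vector of surviving taxon names.
#' @export
restriction_filter <- function(table, groups, min_rel = 0.01,
                               min_fraction = 0.5) {
  stopifnot(inherits(table, "abundance_table"), length(groups) == 2)
  if (min_rel < 0) stop("min_rel must be >= 0")
  sel <- table$metadata$group %in% groups
  if (!any(table$metadata$group == groups[1]) ||
      !any(table$metadata$group == groups[2])) {
    stop("both groups must be present in the table")
  }
  sub <- table$values[, sel, drop = FALSE]
  keep <- rowMeans(sub >= min_rel) >= min_fraction
  rownames(sub)[keep]
}

#' Descriptive differential-abundance screen between two groups
#'
#' A deliberately simple screen: per taxon, the fold change of group
#' geometric means (with pseudocount `min_rel / 2`) and a Wilcoxon rank
#' test (rank-sum for independent groups, signed-rank for paired designs),
#' with Benjamini-Hochberg correction across the tested taxa. This is a
#' descriptive replacement for count-model differential abundance, not a
#' reimplementation of it.
#'
#' @param table An [abundance_table()], ideally already reduced to the
#'   taxa surviving [restriction_filter()] via `taxa`.
#' @param groups Length-2 character vector; fold changes are
#'   `groups[1] / groups[2]`.
#' @param taxa Optional subset of taxa to test (default: all rows).
#' @param paired Use the signed-rank test, matching samples by
#'   `subject_id`.
#' @param min_rel Pseudocount scale, half of which is added before taking
#'   geometric means.
#' @return Data frame `taxon`, `fold_change`, `log2_fc`, `p_value`,
#'   `q_value`.
#' @export
differential_abundance_screen <- function(table, groups, taxa = NULL,
                                          paired = FALSE, min_rel = 0.01) {
  stopifnot(inherits(table, "abundance_table"), length(groups) == 2)
  if (is.null(taxa)) taxa <- rownames(table$values)
  ia <- which(table$metadata$group == groups[1])
  ib <- which(table$metadata$group == groups[2])
  if (length(ia) < 3 || length(ib) < 3) {
    stop("each group needs at least 3 samples")
  }
  if (paired) {
    sa <- table$metadata$subject_id[ia]
    sb <- table$metadata$subject_id[ib]
    common <- intersect(sa, sb)
    if (length(common) != length(ia) || length(common) != length(ib)) {
      stop("paired test requested but subjects are unmatched across groups")
    }
    ia <- ia[match(common, sa)]
    ib <- ib[match(common, sb)]
  }
  pseudo <- min_rel / 2
  res <- lapply(taxa, function(tx) {
    a <- table$values[tx, ia]
    b <- table$values[tx, ib]
    fc <- exp(mean(log(a + pseudo)) - mean(log(b + pseudo)))
    p <- if (paired) {
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
    } else {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    data.frame(taxon = tx, fold_change = fc, log2_fc = log2(fc),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Drop samples with small sequencing libraries
#'
#' Removes samples whose library size falls below the minimum read count
#' before any community analysis.
#'
#' @param table An [abundance_table()] whose metadata carries
#'   `library_size`.
#' @param min_reads Minimum library size in reads.
#' @return The filtered [abundance_table()].
#' @export
filter_min_library <- function(table, min_reads = 2.9e6) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- table$metadata$library_size >= min_reads
  if (!any(keep)) stop("no samples pass the library-size filter")
  abundance_table(table$values[, keep, drop = FALSE],
                  table$metadata[keep, , drop = FALSE],
                  total = table$total)
}

#' Select one sample per subject by largest library
#'
#' Utility mirroring the one-sample-per-healthy-subject selection rule:
#' for each subject, the sample with the highest library size is kept.
#'
#' @param table An [abundance_table()] with `subject_id` and
#'   `library_size` metadata.
#' @return The reduced [abundance_table()].
#' @export
select_highest_library <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  md <- table$metadata
  keep <- unlist(lapply(split(seq_len(nrow(md)), md$subject_id),
                        function(idx) idx[which.max(md$library_size[idx])]))
  keep <- sort(unname(keep))
  abundance_table(table$values[, keep, drop = FALSE],
                  md[keep, , drop = FALSE], total = table$total)
}
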