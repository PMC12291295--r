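# Thin, validated wrappers around the standard tests used throughout the
# analysis chain, so every module reports statistics in one common shape.

.mpa_test <- function(kind, statistic, p_value, n, extra = list()) {
  structure(c(list(kind = kind, statistic = unname(statistic),
                   p_value = p_value, n = n), extra),
            class = "mpa_test")
}

#' @export
print.mpa_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$kind, x$statistic, x$p_value,
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' Rank correlation test
#'
#' Spearman rank correlation with average ranks for ties (exact p-value for
#' small tie-free samples, t-approximation otherwise, as in
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `>= 4` with non-zero
#'   variance.
#' @param exact Passed to [stats::cor.test()]; `NULL` lets the backend
#'   choose.
#' @return An `mpa_test` with `statistic` = rho.
#' @export
spearman_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  .mpa_test("spearman", ct$estimate, ct$p.value, length(x))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Exact for small samples without ties or zero differences, normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Paired numeric vectors; `y` may be omitted to test `x`
#'   against 0.
#' @return An `mpa_test` with `statistic` = V.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (sum(d != 0) < 5) stop("need at least 5 non-zero differences")
  wt <- suppressWarnings(stats::wilcox.test(d, correct = TRUE))
  .mpa_test("wilcoxon_signed_rank", wt$statistic, wt$p.value, length(d))
}

#' Wilcoxon rank-sum (Mann-Whitney) test for two independent samples
#'
#' @param x,y Numeric vectors.
#' @return An `mpa_test` with `statistic` = W.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  .mpa_test("wilcoxon_rank_sum", wt$statistic, wt$p.value,
            c(length(x), length(y)))
}

#' Welch's unequal-variance two-sample t-test
#'
#' @param x,y Numeric vectors with at least 2 observations each.
#' @return An `mpa_test` with `statistic` = t and Welch-Satterthwaite `df`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("both groups constant: t statistic undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  .mpa_test("welch_t", tt$statistic, tt$p.value, c(length(x), length(y)),
            extra = list(df = unname(tt$parameter)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, `q(i) = min over j >= i of p(j) * m / j` on
#' the sorted vector.
#'
#' @param p Vector of p-values.
#' @return Adjusted q-values in the original order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
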