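#' Kruskal-Wallis rank-sum test
#'
#' Mid-rank H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]). The fully
#' degenerate case (every value identical across all groups) returns
#' `H = 0, p = 1` rather than an error.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need at least three observations in total")
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on the paired differences `before - after`. Pairs with
#' a zero difference are dropped (their count is reported). The p-value
#' is exact (enumeration of all sign patterns) when the effective n is at
#' most 25 and the absolute differences are tie-free; otherwise a
#' mid-rank normal approximation with tie-variance correction and no
#' continuity correction is used.
#'
#' @param before,after Equal-length numeric vectors.
#' @return List with `W` (signed-rank statistic, sum of positive ranks),
#'   `p`, `n_effective` and `n_dropped`.
#' @export
wilcoxon_signed_rank <- function(before, after) {
  stopifnot(length(before) == length(after))
  d <- before - after
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) stop("no informative pairs: all differences are zero")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = FALSE))
  list(W = unname(wt$statistic), p = unname(wt$p.value),
       n_effective = length(d), n_dropped = n_dropped)
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. Exact enumeration when
#' `length(a) * length(b) <= 400` and the pooled sample is tie-free;
#' otherwise a mid-rank normal approximation with tie correction and no
#' continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `U` (number of (a, b) pairs with a > b) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  exact <- length(a) * length(b) <= 400L && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment
#' `adj_(i) = min_{j >= i} min(1, p_(j) * m / j)` mapped back to input
#' order (via [stats::p.adjust()]). Every adjusted value dominates its
#' raw p-value, and the adjusted values are nondecreasing in the order of
#' the raw ones; uniform vectors are fixed points. (Note the map is not
#' idempotent in general: re-adjusting already-adjusted values inflates
#' them further.)
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Paired / unpaired (Welch) t-test for clinical variables
#'
#' @param values_t0,values_t1 Numeric vectors (equal length when paired).
#' @param paired Logical.
#' @return List with `t` and `p` (two-sided).
#' @export
clinical_t_tests <- function(values_t0, values_t1, paired = FALSE) {
  if (paired) {
    stopifnot(length(values_t0) == length(values_t1))
    d <- values_t1 - values_t0
    if (stats::sd(d) == 0) {
      stop("degenerate paired t-test: all differences identical")
    }
    tt <- stats::t.test(values_t1, values_t0, paired = TRUE)
  } else {
    if (stats::sd(values_t0) == 0 && stats::sd(values_t1) == 0) {
      stop("degenerate t-test: zero variance in both samples")
    }
    tt <- stats::t.test(values_t1, values_t0, var.equal = FALSE)
  }
  list(t = unname(tt$statistic), p = unname(tt$p.value))
}

#' Per-metabolite nonparametric statistics table
#'
#' For every metabolite (feature column): group means and SDs, a
#' Kruskal-Wallis test across B/AT/HI, a paired Wilcoxon signed-rank test
#' of B vs AT (paired by subject), and a Mann-Whitney test of HI vs AT.
#' Benjamini-Hochberg FDR adjustment is applied separately within each
#' test family (m = number of metabolites per column).
#'
#' @param fm A [feature_matrix()] of metabolite concentrations.
#' @param md A [sample_metadata()] with all three groups present.
#' @return Data frame of class `metabolite_stats` with columns
#'   `metabolite`, `mean_B`, `sd_B`, `mean_AT`, `sd_AT`, `mean_HI`,
#'   `sd_HI`, `p_kw`, `fdr_kw`, `p_wilcoxon_paired`, `fdr_wilcoxon`,
#'   `p_mannwhitney`, `fdr_mannwhitney`.
#' @export
build_metabolite_stats_table <- function(fm, md) {
  stopifnot(inherits(fm, "feature_matrix"))
  md <- align_metadata(fm, md)
  for (g in c("B", "AT", "HI")) {
    if (!any(md$group == g)) stop("group ", g, " is missing from the data")
  }
  X <- fm_values(fm)
  pm <- pairing_map(md)
  if (nrow(pm) == 0L) stop("no complete B/AT pairs")
  iB <- match(pm$sample_B, rownames(X))
  iAT <- match(pm$sample_AT, rownames(X))
  iHI <- which(md$group == "HI")
  rows <- lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    kw <- kruskal_wallis(list(v[md$group == "B"], v[md$group == "AT"], v[iHI]))
    wx <- wilcoxon_signed_rank(v[iB], v[iAT])
    mw <- mann_whitney_u(v[iHI], v[iAT])
    data.frame(metabolite = colnames(X)[j],
               mean_B = mean(v[md$group == "B"]), sd_B = stats::sd(v[md$group == "B"]),
               mean_AT = mean(v[md$group == "AT"]), sd_AT = stats::sd(v[md$group == "AT"]),
               mean_HI = mean(v[iHI]), sd_HI = stats::sd(v[iHI]),
               p_kw = kw$p, p_wilcoxon_paired = wx$p, p_mannwhitney = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_kw <- benjamini_hochberg(out$p_kw)
  out$fdr_wilcoxon <- benjamini_hochberg(out$p_wilcoxon_paired)
  out$fdr_mannwhitney <- benjamini_hochberg(out$p_mannwhitney)
  out <- out[, c("metabolite", "mean_B", "sd_B", "mean_AT", "sd_AT",
                 "mean_HI", "sd_HI", "p_kw", "fdr_kw",
                 "p_wilcoxon_paired", "fdr_wilcoxon",
                 "p_mannwhitney", "fdr_mannwhitney")]
  class(out) <- c("metabolite_stats", "data.frame")
  out
}

#' Long-format table for per-metabolite boxplots
#'
#' @param fm A [feature_matrix()] of metabolite concentrations.
#' @param md A [sample_metadata()].
#' @return Data frame with columns `metabolite`, `sample_id`, `group`,
#'   `value`, suitable for faceted boxplots.
#' @export
metabolite_long_table <- function(fm, md) {
  stopifnot(inherits(fm, "feature_matrix"))
  md <- align_metadata(fm, md)
  X <- fm_values(fm)
  data.frame(
    metabolite = rep(colnames(X), each = nrow(X)),
    sample_id = rep(rownames(X), times = ncol(X)),
    group = rep(as.character(md$group), times = ncol(X)),
    value = as.vector(X), stringsAsFactors = FALSE)
}
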