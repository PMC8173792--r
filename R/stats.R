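#' Welch two-sample upper-tailed t-test
#'
#' Tests whether `groupA` exceeds `groupB` in mean, with the
#' Welch-Satterthwaite degrees of freedom (no equal-variance assumption).
#' Used for enrichment-above-control comparisons; correct the family of
#' such tests with [holm_adjust()].
#'
#' @param groupA,groupB Numeric vectors, each n >= 2; at least one group
#'   must have non-zero variance.
#' @return List with `t`, `df`, `p_value` (upper tail), group means and
#'   sizes.
#' @export
welch_upper_t <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    stop("both groups have zero variance: test degenerate", call. = FALSE)
  }
  ht <- stats::t.test(groupA, groupB, alternative = "greater",
                      var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_A = mean(groupA), mean_B = mean(groupB),
       n_A = length(groupA), n_B = length(groupB))
}

#' Holm step-down multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (step-down adjustment with
#' monotonicity enforcement, capped at 1), kept as a named operation so
#' reports document the correction applied.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (>= 2 groups).
#' @return List with `chi2` (tie-corrected statistic), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(chi2 = 0, df = nlevels(groups) - 1, p_value = 1))
  }
  ht <- stats::kruskal.test(values, groups)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Exact Wilcoxon rank-sum test
#'
#' Exact null distribution for small samples (both n <= 25 and no ties),
#' tie-corrected normal approximation otherwise — the behaviour of
#' [stats::wilcox.test()], surfaced explicitly.
#'
#' @param a,b Numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `W`, `p_value`, `exact` (whether the exact null was
#'   used).
#' @export
wilcoxon_exact <- function(a, b, alternative = "two.sided") {
  exact_ok <- length(a) <= 25 && length(b) <= 25 &&
    !anyDuplicated(c(a, b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact_ok))
  list(W = unname(ht$statistic), p_value = ht$p.value, exact = exact_ok)
}

#' Ordinary least squares regression summary
#'
#' Simple OLS of `y` on `x` with adjusted R-squared and the two-sided
#' slope p-value, as used for enrichment ~ covariate relationships
#' (e.g. host 13C enrichment ~ symbiont density, host 15N enrichment ~
#' bell diameter or phylogenetic diversity).
#'
#' @param x,y Numeric vectors, n >= 3, `x` non-constant.
#' @return List with `slope`, `intercept`, `r2_adj`, `p_value`, `n`, and
#'   the `lm` fit.
#' @export
linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("`x` has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2_adj = sm$adj.r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(x), fit = fit)
}

#' Pairwise enrichment tests with Holm correction
#'
#' Runs [welch_upper_t()] for every requested (treatment vs control)
#' comparison in a tidy APE table and Holm-adjusts the family.
#'
#' @param ape_tab Output of [ape_table()] (columns `treatment`,
#'   `fraction`, `timepoint`, `element`, `ape`).
#' @param control_tab Data frame of T0 control measurements with columns
#'   `fraction`, `element`, `value`; each comparison uses the matching
#'   element-fraction controls expressed as deviations from their own mean
#'   (the natural-abundance spread).
#' @return Data frame: one row per (treatment, fraction, timepoint,
#'   element) with `t`, `df`, `p_value`, `p_holm`.
#' @export
enrichment_tests <- function(ape_tab, control_tab) {
  key <- interaction(ape_tab$treatment, ape_tab$fraction,
                     ape_tab$timepoint, ape_tab$element, drop = TRUE)
  rows <- lapply(split(ape_tab, key), function(d) {
    ctl <- control_tab$value[control_tab$element == d$element[1] &
                               control_tab$fraction == d$fraction[1]]
    if (length(ctl) < 2) {
      stop("need at least two T0 controls for ", d$element[1], "/",
           d$fraction[1], call. = FALSE)
    }
    res <- welch_upper_t(d$ape, ctl - mean(ctl))
    data.frame(treatment = d$treatment[1], fraction = d$fraction[1],
               timepoint = d$timepoint[1], element = d$element[1],
               n = nrow(d), t = res$t, df = res$df, p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_holm <- holm_adjust(out$p_value)
  out
}
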