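#' Fit and select a wet-weight ~ bell-diameter calibration model
#'
#' Ordinary least squares polynomial fits of wet weight (g) on bell
#' diameter (mm), one per candidate degree, compared by information
#' criterion. The criterion is the Gaussian-likelihood form
#' `AIC = n log(RSS/n) + 2k` with `k = degree + 2` (coefficients plus the
#' error variance); by default the small-sample correction
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` is applied, which is standard when
#' `n/k` is small (calibration sets here have n of 12-35). Ties go to the
#' lower degree. RSS is floored at 1e-12 so exact fits keep a finite
#' criterion.
#'
#' @param bd_mm,ww_g Paired bell diameters (mm) and wet weights (g).
#' @param degrees Candidate polynomial degrees, subset of `c(1, 2)`.
#' @param state Optional label (`"symbiotic"`/`"aposymbiotic"`) carried in
#'   the result.
#' @param small_sample Use AICc (default) rather than plain AIC.
#' @return An object of class `allometry_model`: list with `state`,
#'   `degree`, `coefficients` (intercept first), `n`, `RSS`, `AIC`,
#'   `candidates` (criterion per degree), `bd_range`, and the underlying
#'   `lm` fit.
#' @export
fit_ww_bd <- function(bd_mm, ww_g, degrees = c(1, 2), state = NULL,
                      small_sample = TRUE) {
  stopifnot(length(bd_mm) == length(ww_g), all(degrees %in% c(1, 2)))
  degrees <- sort(unique(degrees))
  n <- length(bd_mm)
  if (n < max(degrees) + 2) {
    stop("need at least degree + 2 observations", call. = FALSE)
  }
  if (stats::var(bd_mm) == 0) {
    stop("bell diameters are constant: fit is degenerate", call. = FALSE)
  }
  fits <- lapply(degrees, function(d) {
    stats::lm(ww_g ~ stats::poly(bd_mm, d, raw = TRUE))
  })
  crit <- vapply(seq_along(degrees), function(i) {
    d <- degrees[i]
    k <- d + 2
    rss <- max(sum(stats::resid(fits[[i]])^2), 1e-12)
    aic <- n * log(rss / n) + 2 * k
    if (small_sample) {
      if (n - k - 1 <= 0) return(Inf)
      aic <- aic + 2 * k * (k + 1) / (n - k - 1)
    }
    aic
  }, numeric(1))
  best <- which.min(crit)  # which.min takes the first (lowest-degree) tie
  fit <- fits[[best]]
  coefs <- unname(stats::coef(fit))
  structure(list(
    state = state,
    degree = degrees[best],
    coefficients = coefs,
    n = n,
    RSS = sum(stats::resid(fit)^2),
    AIC = crit[best],
    candidates = stats::setNames(crit, paste0("degree", degrees)),
    bd_range = range(bd_mm),
    fit = fit
  ), class = "allometry_model")
}

#' Predict wet weight from bell diameter
#'
#' Evaluates the selected calibration polynomial. Predictions outside the
#' calibration range are allowed but warned about.
#'
#' @param model An [fit_ww_bd()] result, or a list with `coefficients`
#'   (intercept first) to evaluate printed coefficients directly.
#' @param bd_mm Bell diameter(s) in mm.
#' @param warn_extrapolation Warn when `bd_mm` falls outside the observed
#'   calibration range (only when the model records one).
#' @return Predicted wet weight(s) in g.
#' @examples
#' m <- list(coefficients = c(8.540, -0.494, 0.009))
#' predict_ww(m, 50)  # 6.34
#' @export
predict_ww <- function(model, bd_mm, warn_extrapolation = TRUE) {
  coefs <- model$coefficients
  if (warn_extrapolation && !is.null(model$bd_range) &&
      any(bd_mm < model$bd_range[1] | bd_mm > model$bd_range[2])) {
    warning("predicting outside the calibration bell-diameter range")
  }
  vapply(bd_mm, function(x) sum(coefs * x^(seq_along(coefs) - 1)),
         numeric(1))
}

#' @export
print.allometry_model <- function(x, ...) {
  lab <- if (is.null(x$state)) "" else paste0(" (", x$state, ")")
  cat("Wet weight ~ bell diameter calibration", lab, "\n", sep = "")
  cat("  selected degree:", x$degree, " n =", x$n, "\n")
  cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "),
      "\n")
  cat("  criterion:", paste(names(x$candidates),
                            signif(x$candidates, 6), collapse = "  "), "\n")
  invisible(x)
}
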