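#' Effort-weighted linear trend of a reference-point series
#'
#' Weighted least squares of reference-point elevation on calendar year,
#' with the yearly number of sampling units as weight. The slope's two-sided
#' t-test (n - 2 df) is the trend test.
#'
#' @param series data frame `year`, `elevation`, `n_y` (weights > 0).
#' @return A list of class `trend_fit`: `slope` (m/yr), `se`, `p`, `n`,
#'   `residuals` (in year order), `years`, `weights`, `intercept`.
#' @export
fit_weighted_trend <- function(series) {
  if (nrow(series) < 3) stop("need at least 3 years for a trend test")
  if (stats::var(series$year) == 0) stop("zero variance in the year vector")
  if (any(series$n_y <= 0)) stop("weights must be positive")
  series <- series[order(series$year), ]
  fit <- stats::lm(elevation ~ year, data = series, weights = n_y)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients["year", "Std. Error"],
                 p = sm$coefficients["year", "Pr(>|t|)"],
                 intercept = unname(stats::coef(fit)[1]),
                 n = nrow(series),
                 residuals = unname(stats::residuals(fit)),
                 years = series$year, weights = series$n_y),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.3f m/yr (SE %.3f, p = %.4g, n = %d)\n",
              x$slope, x$se, x$p, x$n))
  invisible(x)
}

#' Compare two trend slopes
#'
#' Two-sided z test on the difference of two independently estimated slopes,
#' `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param a,b `trend_fit` objects (or lists with `slope` and `se`).
#' @param alpha significance level.
#' @return List: `different` (logical), `higher` (`"a"`, `"b"` or `NA`),
#'   `z`, `p`.
#' @export
compare_slopes <- function(a, b, alpha = 0.05) {
  if (is.null(a$se) || is.null(b$se) || is.na(a$se) || is.na(b$se))
    stop("both fits must carry a standard error")
  z <- (a$slope - b$slope) / sqrt(a$se^2 + b$se^2)
  p <- 2 * stats::pnorm(-abs(z))
  diff <- p <= alpha
  list(different = diff,
       higher = if (diff) (if (z > 0) "a" else "b") else NA_character_,
       z = z, p = p)
}

#' Durbin--Watson statistic of trend residuals
#'
#' `d = sum((e_t - e_{t-1})^2) / sum(e_t^2)` over residuals in year order.
#' Reported as a temporal-autocorrelation diagnostic only; it never alters
#' the trend classification.
#'
#' @param residuals numeric residuals in year order (or a `trend_fit`).
#' @return List: `d` (NA when all residuals are zero), `defined` (logical).
#' @export
durbin_watson <- function(residuals) {
  if (inherits(residuals, "trend_fit")) residuals <- residuals$residuals
  if (length(residuals) < 3) stop("need at least 3 residuals")
  denom <- sum(residuals^2)
  if (denom == 0) return(list(d = NA_real_, defined = FALSE))
  list(d = sum(diff(residuals)^2) / denom, defined = TRUE)
}

#' Classify a species' pattern of elevational range change
#'
#' Applies the landmark-based decision rules to the per-landmark trend
#' tests of one species. A landmark is significant when its two-sided
#' p-value is at most `alpha`; the classification branches on which
#' landmarks moved (slopes of the same sign are required; all observed
#' changes in the emulated study were upward):
#'
#' 1. both extremes (OBL and OBR) significant with the same sign: compare
#'    their slopes — OBL significantly steeper means the range shrank
#'    (lower boundary contraction), OBR significantly steeper means it
#'    grew (upper boundary expansion), slopes not different means the whole
#'    range moved (shift);
#' 2. only OBL significant: lower boundary contraction;
#' 3. only OBR significant: upper boundary expansion;
#' 4. otherwise any central landmark (CBL, OPT, CBR) significant: shift;
#' 5. otherwise: none.
#'
#' For downward (negative-slope) changes the same branches return the
#' mirrored labels (`"lower boundary expansion"`, `"upper boundary
#' contraction"`, `"downward shift"`).
#'
#' @param trends data frame with columns `landmark`, `slope`, `p` and
#'   optionally `se` (one row per informative landmark). Landmarks absent
#'   from the table (truncated or non-informative) are treated as
#'   non-significant.
#' @param alpha significance level (default 0.05; significance is `p <=
#'   alpha`).
#' @param extremes_comparison optional pre-computed outcome of the extreme
#'   slope comparison, one of `"obl_steeper"`, `"obr_steeper"`,
#'   `"not_different"`. Used when standard errors are unavailable (e.g.
#'   published tables); when `NULL` the comparison is computed from the
#'   supplied `se` values via [compare_slopes()].
#'
#' @return List of class `pattern_call`: `pattern`, `direction`
#'   (`"upward"`, `"downward"` or `NA`), `significant` (landmark names),
#'   `comparison` (slope-comparison outcome or NA).
#' @export
classify_pattern <- function(trends, alpha = 0.05, extremes_comparison = NULL) {
  if (nrow(trends) == 0) stop("no landmarks supplied")
  sig <- !is.na(trends$p) & trends$p <= alpha
  sig_lm <- trends$landmark[sig]
  if (!any(sig))
    return(structure(list(pattern = "none", direction = NA_character_,
                          significant = character(), comparison = NA_character_),
                     class = "pattern_call"))
  signs <- sign(trends$slope[sig])
  if (length(unique(signs)) > 1)
    return(structure(list(pattern = "mixed", direction = NA_character_,
                          significant = sig_lm, comparison = NA_character_),
                     class = "pattern_call"))
  up <- signs[1] > 0
  # keys name the dominant boundary; labels mirror with direction (a lower
  # boundary moving up contracts the range, moving down expands it)
  lab <- function(key) {
    if (up) switch(key, lower = "lower boundary contraction",
                   upper = "upper boundary expansion", shift = "upward shift")
    else switch(key, lower = "lower boundary expansion",
                upper = "upper boundary contraction", shift = "downward shift")
  }
  has <- function(lm) lm %in% sig_lm
  comparison <- NA_character_
  if (has("OBL") && has("OBR")) {
    if (!is.null(extremes_comparison)) {
      comparison <- match.arg(extremes_comparison,
                              c("obl_steeper", "obr_steeper", "not_different"))
    } else {
      a <- as.list(trends[trends$landmark == "OBL", ])
      b <- as.list(trends[trends$landmark == "OBR", ])
      if (is.null(a$se) || is.null(b$se) || is.na(a$se) || is.na(b$se))
        stop("extreme landmarks both significant but no SEs and no ",
             "'extremes_comparison' supplied")
      cmp <- compare_slopes(a, b, alpha)
      comparison <- if (!cmp$different) "not_different"
                    else if (abs(a$slope) > abs(b$slope)) "obl_steeper"
                    else "obr_steeper"
    }
    pattern <- switch(comparison,
                      obl_steeper = lab("lower"),
                      obr_steeper = lab("upper"),
                      not_different = lab("shift"))
  } else if (has("OBL")) {
    pattern <- lab("lower")
  } else if (has("OBR")) {
    pattern <- lab("upper")
  } else {
    pattern <- lab("shift")      # only central landmarks significant
  }
  structure(list(pattern = pattern,
                 direction = if (up) "upward" else "downward",
                 significant = sig_lm, comparison = comparison),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> %s (significant: %s)\n", x$pattern,
              if (length(x$significant)) paste(x$significant, collapse = ", ")
              else "none"))
  invisible(x)
}
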