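#' Weighted two-driver regression of a reference-point series
#'
#' Weighted least squares of reference-point elevation on the belt's
#' minimum-temperature series (`tn`, °C) and shrub-and-forest cover series
#' (`SF`, km^2), with yearly sampling effort as weight. Coefficient t-tests
#' and the adjusted R-squared are reported.
#'
#' @param series data frame `year`, `elevation`, `n_y`.
#' @param tn data frame `year`, `tn`.
#' @param sf data frame `year`, `sf`.
#' @param collin_tol absolute correlation between `tn` and `sf` beyond which
#'   the fit is flagged collinear (flag only; the partition remains
#'   computable).
#'
#' @return List of class `driver_regression`: `beta_tn`, `p_tn`, `beta_sf`,
#'   `p_sf`, `r2`, `r2_adj`, `residuals`, `collinear` flag, `n`, and the
#'   aligned model frame `data`.
#' @export
fit_driver_regression <- function(series, tn, sf, collin_tol = 0.999) {
  d <- merge(merge(series, tn, by = "year"), sf, by = "year")
  if (nrow(d) < nrow(series)) stop("covariate years do not cover the series")
  if (nrow(d) < 5) stop("need at least 5 aligned years")
  d <- d[order(d$year), ]
  if (stats::var(d$tn) == 0 || stats::var(d$sf) == 0)
    stop("zero-variance predictor")
  collinear <- abs(stats::cor(d$tn, d$sf)) > collin_tol
  fit <- stats::lm(elevation ~ tn + sf, data = d, weights = n_y)
  sm <- summary(fit)
  cf <- sm$coefficients
  structure(list(beta_tn = cf["tn", "Estimate"], p_tn = cf["tn", "Pr(>|t|)"],
                 beta_sf = cf["sf", "Estimate"], p_sf = cf["sf", "Pr(>|t|)"],
                 r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
                 residuals = unname(stats::residuals(fit)),
                 collinear = collinear, n = nrow(d), data = d),
            class = "driver_regression")
}

#' @export
print.driver_regression <- function(x, ...) {
  cat(sprintf(
    "<driver_regression> beta_tn %.3f (p %.3g), beta_SF %.3f (p %.3g), R2adj %.3f\n",
    x$beta_tn, x$p_tn, x$beta_sf, x$p_sf, x$r2_adj))
  invisible(x)
}

# weighted R^2 of y on the columns of X (with intercept)
weighted_r2 <- function(y, X, w) {
  fit <- stats::lm.wfit(cbind(1, X), y, w)
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * fit$residuals^2) / sum(w * (y - ybar)^2)
}

#' Partition the explained variation between two drivers
#'
#' Decomposes the weighted R-squared of the two-driver regression into the
#' net (unique) contribution of each driver, their shared contribution, and
#' the unexplained remainder, from the three nested weighted fits
#' (temperature only, cover only, both):
#' `partial_tn = R2_both - R2_sf`, `partial_sf = R2_both - R2_tn`,
#' `shared = R2_tn + R2_sf - R2_both`, `unexplained = 1 - R2_both`.
#' Any negative component is floored at zero and the discrepancy folded into
#' the shared component so the four fractions sum to one.
#'
#' @param y response (reference-point elevations).
#' @param tn,sf predictor series (numeric, aligned with `y`).
#' @param w positive weights.
#'
#' @return List of class `deviance_partition`: `partial_tn`, `shared`,
#'   `partial_sf`, `unexplained` (fractions summing to 1), plus the raw
#'   `r2_tn`, `r2_sf`, `r2_both`.
#' @export
variation_partition <- function(y, tn, sf, w = rep(1, length(y))) {
  stopifnot(length(tn) == length(y), length(sf) == length(y),
            length(w) == length(y), all(w > 0))
  r2_tn <- weighted_r2(y, cbind(tn), w)
  r2_sf <- weighted_r2(y, cbind(sf), w)
  r2_both <- weighted_r2(y, cbind(tn, sf), w)
  p_tn <- r2_both - r2_sf
  p_sf <- r2_both - r2_tn
  shared <- r2_tn + r2_sf - r2_both
  unexpl <- 1 - r2_both
  p_tn <- max(0, p_tn); p_sf <- max(0, p_sf); unexpl <- max(0, unexpl)
  shared <- 1 - p_tn - p_sf - unexpl
  if (shared < 0) {          # pathological suppression: rescale to simplex
    shared <- 0
    tot <- p_tn + p_sf + unexpl
    p_tn <- p_tn / tot; p_sf <- p_sf / tot; unexpl <- unexpl / tot
  }
  structure(list(partial_tn = p_tn, shared = shared, partial_sf = p_sf,
                 unexplained = unexpl,
                 r2_tn = r2_tn, r2_sf = r2_sf, r2_both = r2_both),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat(sprintf(
    "<deviance_partition> tn %.3f | shared %.3f | SF %.3f | unexplained %.3f\n",
    x$partial_tn, x$shared, x$partial_sf, x$unexplained))
  invisible(x)
}

#' Averaged-order independent effects of the two drivers
#'
#' The classical hierarchical-partitioning independent effect of each driver
#' (average of its R-squared contribution over all orders of entry), which
#' for two predictors is the unique contribution plus half the shared one.
#' Provided as an alternative reading of "contributed deviance"; the default
#' pipeline reports the unique/shared decomposition of
#' [variation_partition()], the only reading under which the four printed
#' fractions sum to one.
#'
#' @inheritParams variation_partition
#' @return List: `indep_tn`, `indep_sf`, `joint` (total R-squared).
#' @export
independent_effects <- function(y, tn, sf, w = rep(1, length(y))) {
  part <- variation_partition(y, tn, sf, w)
  list(indep_tn = part$partial_tn + part$shared / 2,
       indep_sf = part$partial_sf + part$shared / 2,
       joint = part$r2_both)
}

#' Raw driver class from a deviance partition
#'
#' Threshold rules, applied in order: shared contribution above
#' `shared_thr` means the driver is not distinguishable (`nd`); both net
#' contributions at least `net_thr` means both drivers act (`tn+SF`); a
#' single net contribution at least `net_thr` names that driver; unexplained
#' variation above `unexpl_thr` means neither driver (`none`); anything left
#' falls back to `nd` (flagged as such so the finalisation step can resolve
#' it against the regression coefficients).
#'
#' @param partition a `deviance_partition` (or list with the four fractions).
#' @param shared_thr,net_thr,unexpl_thr rule thresholds (defaults 0.9, 0.1,
#'   0.9).
#'
#' @return List of class `driver_class`: `class` in
#'   `{"nd", "tn+SF", "SF", "tn", "none"}` and `rule` in
#'   `{"shared", "both", "sf", "tn", "none", "fallback"}`.
#' @export
classify_driver <- function(partition, shared_thr = 0.9, net_thr = 0.1,
                            unexpl_thr = 0.9) {
  p <- partition
  out <- if (p$shared > shared_thr) list(class = "nd", rule = "shared")
  else if (p$partial_tn >= net_thr && p$partial_sf >= net_thr)
    list(class = "tn+SF", rule = "both")
  else if (p$partial_sf >= net_thr) list(class = "SF", rule = "sf")
  else if (p$partial_tn >= net_thr) list(class = "tn", rule = "tn")
  else if (p$unexplained > unexpl_thr) list(class = "none", rule = "none")
  else list(class = "nd", rule = "fallback")
  structure(out, class = "driver_class")
}

#' Final driver call with overrides and density-dependent-effect flag
#'
#' Resolves a raw `nd` call against the regression evidence and attaches the
#' density-dependent-effect (dde) relabel:
#'
#' 1. a raw `nd` where the temperature coefficient is individually
#'    significant and the cover coefficient is not becomes `tn` (the
#'    high-collinearity analogue of a pure temperature signal);
#' 2. a raw `nd` reached through the fallback rule (no component crossed a
#'    threshold) where at least one coefficient is individually significant
#'    becomes the significant driver with the larger net contribution;
#' 3. otherwise the raw class stands.
#'
#' Finally, an upper landmark (CBR or OBR) whose cover coefficient is
#' negative while the final class is `SF` or `nd` is flagged as a
#' density-dependent effect — cover cannot push an upper boundary up by
#' decreasing, so the habitat signal is read as spillover of dense
#' lower-elevation populations — and labelled `dde(SF)` / `dde(nd)`.
#'
#' @param raw a `driver_class` from [classify_driver()].
#' @param regression a `driver_regression` (needs `beta_sf`, `p_tn`,
#'   `p_sf`).
#' @param partition the `deviance_partition` used for the raw call.
#' @param landmark landmark kind, one of `"OBL"`, `"CBL"`, `"OPT"`, `"CBR"`,
#'   `"OBR"`.
#' @param alpha significance level for the coefficient tests.
#'
#' @return List of class `driver_call`: `raw`, `final` (underlying class),
#'   `dde` (logical), `label` (e.g. `"SF"`, `"tn"`, `"dde(SF)"`).
#' @export
finalize_driver_call <- function(raw, regression, partition, landmark,
                                 alpha = 0.05) {
  final <- raw$class
  if (raw$class == "nd") {
    sig_tn <- !is.na(regression$p_tn) && regression$p_tn <= alpha
    sig_sf <- !is.na(regression$p_sf) && regression$p_sf <= alpha
    if (sig_tn && !sig_sf) {
      final <- "tn"
    } else if (identical(raw$rule, "fallback") && (sig_tn || sig_sf)) {
      cand <- c("tn", "SF")[c(sig_tn, sig_sf)]
      nets <- c(tn = partition$partial_tn, SF = partition$partial_sf)[cand]
      final <- cand[which.max(nets)]
    }
  }
  dde <- landmark %in% c("CBR", "OBR") &&
    !is.na(regression$beta_sf) && regression$beta_sf < 0 &&
    final %in% c("SF", "nd")
  label <- if (dde) sprintf("dde(%s)", final) else final
  structure(list(raw = raw$class, final = final, dde = dde, label = label),
            class = "driver_call")
}

#' @export
print.driver_call <- function(x, ...) {
  cat(sprintf("<driver_call> %s (raw %s)\n", x$label, x$raw))
  invisible(x)
}
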