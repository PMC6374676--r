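#' Elevational belt of a reference-point series
#'
#' The belt over which covariates are aggregated for a reference point is the
#' `[min, max]` interval of the elevations the point occupied across its
#' (reliable) time series.
#'
#' @param series data frame with an `elevation` column (one reference-point
#'   series as built by [build_series()]).
#' @return Numeric length-2 `c(lower, upper)` (m asl).
#' @export
reference_belt <- function(series) {
  if (nrow(series) == 0) stop("empty reference-point series")
  r <- range(series$elevation)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)    # degenerate one-value belt
  r
}

#' Downscale coarse daily temperature grids with the climatology-delta method
#'
#' Each fine-grid cell receives its own climatology plus the daily anomaly of
#' the enclosing coarse cell:
#' `fine(day) = fine_clim + (coarse(day) - coarse_clim)`.
#' The coarse terms are taken from the coarse cell containing the fine cell's
#' center; a fine cell outside the coarse coverage is an error.
#'
#' @param coarse_daily list (by year) of matrices `[coarse cell, day]` of
#'   daily minimum temperatures (coarse cells in column-major grid order).
#' @param coarse_clim [grid_raster] of the coarse climatology.
#' @param fine_clim [grid_raster] of the fine climatology.
#'
#' @return List (by year) of matrices `[fine cell, day]`.
#' @export
downscale_temperature <- function(coarse_daily, coarse_clim, fine_clim) {
  ctr <- grid_centers(fine_clim)
  idx <- grid_cell_index(coarse_clim, ctr$easting, ctr$northing)
  if (anyNA(idx)) stop("fine grid extends beyond coarse coverage")
  fc <- as.vector(fine_clim$values)
  cc <- as.vector(coarse_clim$values)
  lapply(coarse_daily, function(day_mat) {
    fc + day_mat[idx, , drop = FALSE] - cc[idx]
  })
}

#' Yearly May--June minimum-temperature series within an elevational belt
#'
#' For each year, averages the daily minimum temperature over all window
#' days (May 1 -- June 30 by construction of the daily grids) and all fine
#' cells whose center elevation falls inside the belt (inclusive bounds).
#'
#' @param fine_daily list (by year) of `[fine cell, day]` matrices, e.g. from
#'   [downscale_temperature()].
#' @param fine_elev [grid_raster] of fine-cell elevations (m asl).
#' @param belt numeric length-2 `c(lower, upper)` elevational belt (m asl).
#'
#' @return Data frame `year`, `tn` (°C).
#' @export
belt_temperature_series <- function(fine_daily, fine_elev, belt) {
  if (belt[1] >= belt[2]) stop("'belt' must be increasing")
  ev <- as.vector(fine_elev$values)
  cells <- which(ev >= belt[1] & ev <= belt[2])
  if (length(cells) == 0) stop("empty elevational belt")
  tn <- vapply(fine_daily, function(m) mean(m[cells, , drop = FALSE]),
               numeric(1))
  data.frame(year = as.integer(names(fine_daily)), tn = unname(tn))
}

#' Interpolate sparse habitat surveys into a yearly cover series
#'
#' Shrub-and-forest cover is surveyed only in a handful of cartography
#' years; the yearly series is obtained by smoothing cover over year with a
#' penalized thin plate regression spline whose effective degrees of freedom
#' are capped at `max_df` (default 4) and at the number of surveys, then
#' predicting every target year. Predictions are floored at zero.
#'
#' @param surveys data frame `year`, `sf_km2` (one row per survey year).
#' @param target_years years at which to predict.
#' @param max_df effective-df ceiling of the year smooth.
#'
#' @return Data frame `year`, `sf` (km^2).
#' @export
interpolate_habitat_cover <- function(surveys, target_years, max_df = 4) {
  if (nrow(surveys) < 2) stop("at least two habitat surveys are required")
  surveys <- surveys[order(surveys$year), ]
  n <- nrow(surveys)
  if (n == 2 || length(unique(surveys$sf_km2)) == 1L) {
    fit <- stats::lm(sf_km2 ~ year, data = surveys)
    pred <- stats::predict(fit, data.frame(year = target_years))
  } else {
    k <- min(max_df + 1, n - 1)
    if (k < 3) {
      fit <- stats::lm(sf_km2 ~ year, data = surveys)
      pred <- stats::predict(fit, data.frame(year = target_years))
    } else {
      fml <- eval(substitute(sf_km2 ~ s(year, k = K), list(K = k)))
      fit <- mgcv::gam(fml, data = surveys)
      pred <- as.vector(stats::predict(fit, data.frame(year = target_years)))
    }
  }
  data.frame(year = target_years, sf = pmax(as.vector(pred), 0))
}

#' Habitat survey values within an elevational belt
#'
#' The synthetic habitat surveys report cover by broad elevation band. The
#' cover attributable to a belt is apportioned from each band by the
#' fraction of the band's elevational extent the belt overlaps (uniform
#' cover density within a band is assumed).
#'
#' @param habitat data frame `year`, `band_lo`, `band_hi`, `sf_km2`.
#' @param belt numeric length-2 elevational belt (m asl).
#' @return Data frame `year`, `sf_km2` (one row per survey year).
#' @export
belt_habitat_surveys <- function(habitat, belt) {
  ov <- pmax(0, pmin(habitat$band_hi, belt[2]) - pmax(habitat$band_lo, belt[1]))
  frac <- ov / (habitat$band_hi - habitat$band_lo)
  agg <- tapply(habitat$sf_km2 * frac, habitat$year, sum)
  data.frame(year = as.integer(names(agg)), sf_km2 = as.vector(agg))
}
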