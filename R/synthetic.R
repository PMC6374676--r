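#' True species response curves along elevation
#'
#' Defines the latent presence-probability curve of a simulated species for
#' each survey year. The curve is a split Gaussian on elevation,
#' \deqn{p(e) = p_{max} \exp\{-(e-\mu)^2 / (2\sigma^2)\},}
#' with a lower-side scale `sigma_l` used below the optimum and an upper-side
#' scale `sigma_u` above it, so asymmetric curves (and hence one-sided
#' boundary dynamics) are representable. Curve parameters drift linearly over
#' years and can additionally be tied to a yearly temperature anomaly and a
#' yearly habitat-cover series through linkage coefficients.
#'
#' @param species species identifier (length 1).
#' @param years integer vector of survey years.
#' @param p_max peak presence probability in (0, 1].
#' @param mu0 optimum elevation (m asl) in the first year.
#' @param mu_trend linear drift of the optimum (m/yr).
#' @param sigma_l,sigma_u lower/upper curve scales (m), must be positive.
#' @param sigma_l_trend,sigma_u_trend linear drift of the scales (m/yr).
#' @param temp_coef optimum shift per degree of temperature anomaly (m/°C);
#'   requires `temp_anomaly`.
#' @param temp_anomaly named numeric vector (by year) of temperature
#'   anomalies (°C) driving the optimum when `temp_coef != 0`.
#' @param habitat_coef shift of the *lower* scale per km^2 of habitat change
#'   (m/km^2): encroachment at low elevations erodes the lower tail.
#' @param habitat_series named numeric vector (by year) of shrub+forest cover
#'   (km^2), centred internally on its first value.
#'
#' @return A data frame of class `species_truth` with one row per year and
#'   columns `species`, `year`, `p_max`, `mu`, `sigma_l`, `sigma_u`.
#' @seealso [true_presence_prob()], [true_reference_points()]
#' @export
make_species_truth <- function(species, years, p_max = 0.6, mu0 = 1500,
                               mu_trend = 0, sigma_l = 250, sigma_u = 250,
                               sigma_l_trend = 0, sigma_u_trend = 0,
                               temp_coef = 0, temp_anomaly = NULL,
                               habitat_coef = 0, habitat_series = NULL) {
  if (p_max <= 0 || p_max > 1) stop("'p_max' must be in (0, 1]")
  if (sigma_l <= 0 || sigma_u <= 0) stop("curve scales must be positive")
  t <- years - years[1]
  mu <- mu0 + mu_trend * t
  sl <- sigma_l + sigma_l_trend * t
  su <- sigma_u + sigma_u_trend * t
  if (temp_coef != 0) {
    if (is.null(temp_anomaly)) stop("'temp_anomaly' required when temp_coef != 0")
    mu <- mu + temp_coef * unname(temp_anomaly[as.character(years)])
  }
  if (habitat_coef != 0) {
    if (is.null(habitat_series)) stop("'habitat_series' required when habitat_coef != 0")
    sf <- unname(habitat_series[as.character(years)])
    sl <- sl + habitat_coef * (sf - sf[1])
  }
  if (any(!is.finite(mu)) || any(sl <= 0) || any(su <= 0))
    stop("drift produced invalid curve parameters (check trends/linkages)")
  out <- data.frame(species = species, year = years, p_max = p_max,
                    mu = mu, sigma_l = sl, sigma_u = su)
  class(out) <- c("species_truth", "data.frame")
  out
}

#' Evaluate a true response curve
#'
#' @param elev elevations (m asl) at which to evaluate the curve.
#' @param p_max,mu,sigma_l,sigma_u split-Gaussian curve parameters.
#' @return Presence probabilities in `[0, 1]`.
#' @export
true_presence_prob <- function(elev, p_max, mu, sigma_l, sigma_u) {
  s <- ifelse(elev < mu, sigma_l, sigma_u)
  p_max * exp(-(elev - mu)^2 / (2 * s^2))
}

#' Analytic reference points of a true response curve
#'
#' For the split Gaussian the central borders sit exactly at one side-scale
#' from the optimum (level `p_max * exp(-0.5)`) and the outer borders at two
#' side-scales (level `p_max * exp(-2)`).
#'
#' @inheritParams true_presence_prob
#' @return Named numeric vector with elements `OBL`, `CBL`, `OPT`, `CBR`,
#'   `OBR` (m asl).
#' @export
true_reference_points <- function(mu, sigma_l, sigma_u) {
  c(OBL = mu - 2 * sigma_l, CBL = mu - sigma_l, OPT = mu,
    CBR = mu + sigma_u, OBR = mu + 2 * sigma_u)
}

#' Default survey-year layout of the study design being emulated
#'
#' 28 survey years within 1982--2017: continuous 1982--1987, then 1992 onward
#' with no surveys in 1993, 1994, 1997 and 1998.
#'
#' @return Integer vector of 28 years.
#' @export
default_survey_years <- function() {
  setdiff(1982:2017, c(1988:1991, 1993, 1994, 1997, 1998))
}

#' Draw yearly sampling effort
#'
#' Sampling effort (number of point counts per year) varies widely between
#' years in the emulated surveys (roughly 67 to 782 points). Effort is drawn
#' uniformly over that range, seeded, and is exported so it can be reused as
#' the weight vector of the downstream trend regressions.
#'
#' @param years survey years.
#' @param range length-2 integer range of yearly effort.
#' @param seed integer seed.
#' @return Named integer vector (names = years).
#' @export
draw_survey_effort <- function(years, range = c(67, 782), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- round(runif(length(years), range[1], range[2]))
  stats::setNames(as.integer(n), years)
}

#' Simulate point-count surveys from known response curves
#'
#' Places survey points on the landscape for each year (uniformly over the
#' grid extent, or stratified so that sampled elevations are approximately
#' uniform along the gradient) and draws the presence of every species
#' independently at every point as a Bernoulli trial of its true curve
#' evaluated at the point's elevation.
#'
#' @param grid a [grid_raster] of elevations.
#' @param truth a `species_truth` data frame (rows for several species may be
#'   concatenated with `rbind`).
#' @param effort named integer vector of points per year (names = years);
#'   every simulated year must have effort >= 1. Years absent from `effort`
#'   are simply not surveyed (gap years).
#' @param seed integer seed.
#' @param stratified if `TRUE`, sample elevations approximately uniformly by
#'   drawing cells from 100-m elevation bins.
#'
#' @return Data frame with columns `year`, `easting`, `northing`,
#'   `elevation`, `species`, `presence` (0/1). The effort vector is attached
#'   as attribute `"effort"`.
#' @export
simulate_surveys <- function(grid, truth, effort, seed = 1,
                             stratified = FALSE) {
  if (any(effort < 1)) stop("yearly effort must be >= 1")
  if (is.null(names(effort))) stop("'effort' must be named by year")
  years <- as.integer(names(effort))
  species <- unique(truth$species)
  for (sp in species) {
    ty <- truth$year[truth$species == sp]
    if (!all(years %in% ty))
      stop("species '", sp, "' has no truth parameters for some survey years")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  width <- nc * grid$res; height <- nr * grid$res
  ctr <- grid_centers(grid)
  ev <- as.vector(grid$values)
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    n <- effort[[i]]
    if (stratified) {
      bins <- floor(ev / 100)
      # draw bins uniformly, then a cell within the bin, then jitter
      bs <- sample(unique(bins), n, replace = TRUE)
      cell <- vapply(bs, function(b) {
        cand <- which(bins == b)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      x <- ctr$easting[cell]  + runif(n, -0.5, 0.5) * grid$res
      y <- ctr$northing[cell] + runif(n, -0.5, 0.5) * grid$res
    } else {
      x <- runif(n, 0, width) + grid$xmin
      y <- runif(n, 0, height) + grid$ymin
    }
    e <- grid_lookup(grid, x, y)
    blocks <- lapply(species, function(sp) {
      pr <- truth[truth$species == sp & truth$year == years[i], ]
      p <- true_presence_prob(e, pr$p_max, pr$mu, pr$sigma_l, pr$sigma_u)
      data.frame(year = years[i], easting = x, northing = y, elevation = e,
                 species = sp, presence = rbinom(n, 1, p))
    })
    out[[i]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "effort") <- effort
  res
}

#' Generate the true covariate world: daily temperature grids and habitat
#' surveys
#'
#' Simulates (a) daily minimum temperatures for a May 1 -- June 30 window on a
#' coarse grid, as climatology + within-season ramp + yearly anomaly + noise,
#' where the yearly anomaly follows a linear warming trend; and (b) a sparse
#' habitat survey table of shrub-and-forest cover by elevation band, with
#' cover increasing linearly between the first and last survey year and a
#' larger increase below a configurable elevation threshold.
#'
#' Defaults emulate the study conditions this package targets: a warming
#' trend of 0.046 °C/yr (about 0.46 °C per decade) and a shrub+forest cover
#' moving from 4140 km^2 in 1980 to 4364 km^2 in 2015, with most of the gain
#' below 1200 m asl.
#'
#' @param years survey years for which daily grids are generated.
#' @param fine_elev [grid_raster] of elevations for the fine (target) grid.
#' @param trend temperature trend (°C/yr) of the yearly anomaly.
#' @param t_low May--June mean daily-minimum temperature (°C) at the lower
#'   elevation bound of the study design (600 m).
#' @param lapse temperature lapse rate (°C per km of elevation).
#' @param season_amp amplitude (°C) of the linear within-season warming ramp
#'   across the 61-day window (mean 0 by construction).
#' @param sd_year,sd_day,sd_cell standard deviations (°C) of the yearly
#'   anomaly noise, the shared day-to-day noise, and the independent
#'   cell-by-day noise.
#' @param coarse_factor integer block size aggregating the fine grid into the
#'   coarse grid on which daily values are generated.
#' @param habitat_years years of the sparse habitat surveys.
#' @param habitat_total length-2: total shrub+forest cover (km^2) at the
#'   first and last habitat survey year.
#' @param habitat_split fraction of the total cover gain occurring in the low
#'   band.
#' @param habitat_bands length-3 numeric: band limits (m) `c(lo, mid, hi)`
#'   splitting the study range into a low and a high band.
#' @param habitat_low_start cover (km^2) of the low band at the first survey.
#' @param seed integer seed.
#'
#' @return A list of class `covariate_truth` with elements `fine_elev`,
#'   `fine_clim`, `coarse_elev`, `coarse_clim` (all [grid_raster]),
#'   `coarse_daily` (list by year of cell x day matrices), `anomaly` (named
#'   yearly anomaly, °C), `habitat` (data frame `year`, `band_lo`, `band_hi`,
#'   `sf_km2`), `window_days` and the generating parameters.
#' @export
generate_covariate_truth <- function(years,
                                     fine_elev = generate_landscape(seed = 1),
                                     trend = 0.046, t_low = 11.5, lapse = 6.5,
                                     season_amp = 3, sd_year = 0.25,
                                     sd_day = 1.5, sd_cell = 0.1,
                                     coarse_factor = 5,
                                     habitat_years = c(1980, 1999, 2007, 2009,
                                                       2012, 2015),
                                     habitat_total = c(4140, 4364),
                                     habitat_split = 0.85,
                                     habitat_bands = c(600, 1200, 2700),
                                     habitat_low_start = 2500,
                                     seed = 1) {
  if (length(years) == 0) stop("'years' must be non-empty")
  if (!is.finite(trend)) stop("'trend' must be finite")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  clim_of <- function(e) t_low - lapse * (e - 600) / 1000
  fine_clim <- grid_raster(clim_of(fine_elev$values), fine_elev$res,
                           fine_elev$xmin, fine_elev$ymin)
  coarse_elev <- grid_aggregate(fine_elev, coarse_factor)
  coarse_clim <- grid_raster(clim_of(coarse_elev$values), coarse_elev$res,
                             coarse_elev$xmin, coarse_elev$ymin)
  nday <- 61L                                   # May 1 .. June 30
  season <- season_amp * (seq_len(nday) - (nday + 1) / 2) / nday
  anomaly <- trend * (years - years[1]) + rnorm(length(years), 0, sd_year)
  names(anomaly) <- years
  ncell <- length(coarse_clim$values)
  coarse_daily <- lapply(seq_along(years), function(i) {
    day_eff <- rnorm(nday, 0, sd_day)
    base <- outer(as.vector(coarse_clim$values), season + day_eff + anomaly[i],
                  "+")
    base + matrix(rnorm(ncell * nday, 0, sd_cell), ncell, nday)
  })
  names(coarse_daily) <- years

  # habitat: two elevation bands, linear encroachment between first and last
  # survey year, with `habitat_split` of the total gain in the low band
  gain <- habitat_total[2] - habitat_total[1]
  span <- habitat_years - habitat_years[1]
  frac <- span / max(span)
  low  <- habitat_low_start + habitat_split * gain * frac
  high <- (habitat_total[1] - habitat_low_start) +
    (1 - habitat_split) * gain * frac
  habitat <- data.frame(
    year = rep(habitat_years, 2),
    band_lo = rep(habitat_bands[c(1, 2)], each = length(habitat_years)),
    band_hi = rep(habitat_bands[c(2, 3)], each = length(habitat_years)),
    sf_km2 = c(low, high))
  structure(list(fine_elev = fine_elev, fine_clim = fine_clim,
                 coarse_elev = coarse_elev, coarse_clim = coarse_clim,
                 coarse_daily = coarse_daily, anomaly = anomaly,
                 habitat = habitat, window_days = nday,
                 params = list(trend = trend, t_low = t_low, lapse = lapse,
                               season_amp = season_amp, sd_year = sd_year,
                               sd_day = sd_day, sd_cell = sd_cell,
                               coarse_factor = coarse_factor, seed = seed)),
            class = "covariate_truth")
}

#' @export
print.covariate_truth <- function(x, ...) {
  cat(sprintf("<covariate_truth> %d years, %d-day window, trend %g degC/yr\n",
              length(x$coarse_daily), x$window_days, x$params$trend))
  cat(sprintf("  habitat surveys: %s\n",
              paste(unique(x$habitat$year), collapse = ", ")))
  invisible(x)
}
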