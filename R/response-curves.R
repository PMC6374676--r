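#' Settings for yearly response-curve estimation
#'
#' Collects every tunable of the curve-fitting stage. The degree-of-freedom
#' ceilings keep the elevation smooth unimodal-or-monotone (max 3 effective
#' df) and bound the spatial smooth (max 15 effective df); both are enforced
#' through the basis dimension of penalized thin plate regression splines.
#'
#' @param elev_df maximum effective degrees of freedom of the elevation
#'   smooth (default 3).
#' @param spatial_df maximum effective degrees of freedom of the
#'   easting/northing smooth (default 15).
#' @param n_boot bootstrap replicates per species x year (default 200).
#' @param bounds surveyed elevation window (m asl), default `c(600, 2700)`.
#' @param step prediction grid step (m), default 1.
#' @param min_rows minimum point-count rows required to attempt a fit.
#' @param reliability minimum bootstrap success fraction for a reference
#'   point to be considered reliable (default 0.5).
#' @param min_years minimum reliable years for a reference-point series to
#'   be informative (default 10).
#' @param alpha significance level used downstream.
#' @param max_knots knot ceiling for the spatial thin plate basis (speed
#'   control only; does not change the df ceiling).
#' @param refit_sp smoothing parameters for bootstrap refits: `"fixed"`
#'   reuses the full-data fit's smoothing parameters (fast), `"free"` re-runs
#'   full smoothness selection per replicate.
#'
#' @return A list of class `curve_settings`.
#' @export
curve_settings <- function(elev_df = 3, spatial_df = 15, n_boot = 200,
                           bounds = c(600, 2700), step = 1, min_rows = 30,
                           reliability = 0.5, min_years = 10, alpha = 0.05,
                           max_knots = 60, refit_sp = c("fixed", "free")) {
  if (elev_df < 1 || spatial_df < 1) stop("df ceilings must be >= 1")
  if (n_boot < 1) stop("'n_boot' must be >= 1")
  if (bounds[1] >= bounds[2]) stop("'bounds' must be increasing")
  if (step <= 0) stop("'step' must be positive")
  if (reliability <= 0 || reliability > 1) stop("'reliability' must be in (0, 1]")
  structure(list(elev_df = elev_df, spatial_df = spatial_df, n_boot = n_boot,
                 bounds = bounds, step = step, min_rows = min_rows,
                 reliability = reliability, min_years = min_years,
                 alpha = alpha, max_knots = max_knots,
                 refit_sp = match.arg(refit_sp)),
            class = "curve_settings")
}

# empty curve object used for degenerate / failed fits
failed_curve <- function(species, year, settings, reason) {
  structure(list(species = species, year = year, converged = FALSE,
                 reason = reason, grid = NULL, prob = NULL, model = NULL,
                 settings = settings),
            class = "fitted_curve")
}

#' Fit the yearly presence-probability curve of one species
#'
#' Fits a binomial additive model with logit link,
#' `presence ~ s(elevation) + s(easting, northing)`, with penalized thin
#' plate regression splines whose basis dimensions cap the effective degrees
#' of freedom at `elev_df` and `spatial_df`. The presence-probability curve is
#' reported along an elevation grid with the spatial term held at its average
#' over the year's survey locations, which makes curves comparable across
#' years with different spatial coverage.
#'
#' Degenerate inputs (all presences or all absences, or fewer than
#' `min_rows` rows) and non-convergent fits are flagged, never raised.
#'
#' @param rows data frame of one species x one year: columns `elevation`,
#'   `easting`, `northing`, `presence` (0/1).
#' @param settings a [curve_settings] object.
#'
#' @return An object of class `fitted_curve`: list with `species`, `year`,
#'   `grid` (elevations), `prob` (predicted presence probability),
#'   `converged`, `reason` (for failures), the fitted `model`, and internal
#'   prediction matrices used by [bootstrap_reliability()].
#' @export
fit_year_curve <- function(rows, settings = curve_settings()) {
  sp <- if (nrow(rows)) as.character(rows$species[1]) else NA_character_
  yr <- if (nrow(rows)) rows$year[1] else NA_integer_
  if (nrow(rows) < settings$min_rows)
    return(failed_curve(sp, yr, settings, "too few rows"))
  y <- rows$presence
  if (all(y == 0) || all(y == 1))
    return(failed_curve(sp, yr, settings, "degenerate response"))
  k_e <- settings$elev_df + 1L
  k_s <- settings$spatial_df + 1L
  fml <- stats::as.formula(sprintf(
    "presence ~ s(elevation, k = %d) + s(easting, northing, k = %d, xt = list(max.knots = %d))",
    k_e, k_s, settings$max_knots), env = environment())
  g <- tryCatch(
    suppressWarnings(mgcv::gam(fml, family = stats::binomial(), data = rows,
                               method = "GCV.Cp")),
    error = function(e) NULL)
  if (is.null(g) || !g$converged || anyNA(stats::coef(g)))
    return(failed_curve(sp, yr, settings, "fit did not converge"))
  grid <- seq(settings$bounds[1], settings$bounds[2], by = settings$step)
  X <- stats::predict(g, type = "lpmatrix")
  Cpred <- curve_lpmatrix(g, X, grid, rows)
  prob <- as.vector(stats::plogis(Cpred %*% stats::coef(g)))
  structure(list(species = sp, year = yr, grid = grid, prob = prob,
                 converged = TRUE, reason = NULL, model = g, X = X,
                 Cpred = Cpred, settings = settings),
            class = "fitted_curve")
}

# linear-predictor matrix for the elevation grid with the spatial columns
# replaced by their average over the year's survey locations
curve_lpmatrix <- function(g, X, grid, rows) {
  nd <- data.frame(elevation = grid,
                   easting = mean(rows$easting), northing = mean(rows$northing))
  Cp <- stats::predict(g, newdata = nd, type = "lpmatrix")
  spat <- g$smooth[[2]]
  cols <- spat$first.para:spat$last.para
  Cp[, cols] <- matrix(colMeans(X[, cols, drop = FALSE]),
                       nrow(Cp), length(cols), byrow = TRUE)
  Cp
}

#' @export
print.fitted_curve <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<fitted_curve> %s %s: max p = %.3f at %g m\n",
                x$species, x$year, max(x$prob), x$grid[which.max(x$prob)]))
  } else {
    cat(sprintf("<fitted_curve> %s %s: not converged (%s)\n",
                x$species, x$year, x$reason))
  }
  invisible(x)
}

#' Extract the five reference points of a fitted response curve
#'
#' Locates the curve's interior maximum (OPT) and, walking outward from it,
#' the nearest crossings of the levels `p_max * exp(-0.5)` (central borders
#' CBL/CBR) and `p_max * exp(-2)` (outer borders OBL/OBR), with crossings
#' placed by linear interpolation between grid points. A landmark whose
#' defining feature lies at or beyond the surveyed window is reported as
#' truncated. When the maximum itself sits at a window edge (within one grid
#' step) the curve is monotone over the window: the optimum and the landmarks
#' on that side are truncated, while crossings on the interior side are still
#' reported relative to the observed maximum.
#'
#' @param curve a convergent `fitted_curve`, or a list with elements `grid`
#'   and `prob` (any tabulated curve).
#' @param bounds elevation window; defaults to the range of `curve$grid`.
#'
#' @return Data frame of class `reference_points` with one row per landmark
#'   (`OBL`, `CBL`, `OPT`, `CBR`, `OBR`): columns `landmark`, `elevation`
#'   (NA when truncated), `status` (`"ok"` or `"truncated"`).
#' @export
extract_reference_points <- function(curve, bounds = NULL) {
  if (inherits(curve, "fitted_curve") && !curve$converged)
    stop("cannot extract reference points from a non-convergent curve")
  grid <- curve$grid; prob <- curve$prob
  if (is.null(bounds)) bounds <- range(grid)
  step <- grid[2] - grid[1]
  i_max <- which.max(prob)              # first index on ties (lowest elev)
  p_max <- prob[i_max]
  lm <- c("OBL", "CBL", "OPT", "CBR", "OBR")
  out <- data.frame(landmark = lm, elevation = NA_real_,
                    status = "truncated", stringsAsFactors = FALSE)
  at_left  <- grid[i_max] <= bounds[1] + step
  at_right <- grid[i_max] >= bounds[2] - step
  if (!at_left && !at_right) {
    out$elevation[out$landmark == "OPT"] <- grid[i_max]
    out$status[out$landmark == "OPT"] <- "ok"
  }
  levels <- c(central = p_max * exp(-0.5), outer = p_max * exp(-2))
  put <- function(name, value) {
    out$elevation[out$landmark == name] <<- value
    out$status[out$landmark == name] <<- "ok"
  }
  # walk left unless the maximum is pinned to the left edge
  if (!at_left) {
    cbl <- cross_left(grid, prob, i_max, levels["central"])
    obl <- cross_left(grid, prob, i_max, levels["outer"])
    if (!is.na(cbl) && cbl >= bounds[1]) put("CBL", cbl)
    if (!is.na(obl) && obl >= bounds[1]) put("OBL", obl)
  }
  if (!at_right) {
    cbr <- cross_right(grid, prob, i_max, levels["central"])
    obr <- cross_right(grid, prob, i_max, levels["outer"])
    if (!is.na(cbr) && cbr <= bounds[2]) put("CBR", cbr)
    if (!is.na(obr) && obr <= bounds[2]) put("OBR", obr)
  }
  class(out) <- c("reference_points", "data.frame")
  out
}

# first downward crossing of `level` left of index i0 (linear interpolation)
cross_left <- function(grid, prob, i0, level) {
  if (i0 == 1L) return(NA_real_)
  below <- which(prob[seq_len(i0 - 1L)] < level)
  if (!length(below)) return(NA_real_)
  i <- below[length(below)]           # nearest to the maximum
  f <- (level - prob[i]) / (prob[i + 1L] - prob[i])
  grid[i] + f * (grid[i + 1L] - grid[i])
}

cross_right <- function(grid, prob, i0, level) {
  n <- length(prob)
  if (i0 == n) return(NA_real_)
  below <- which(prob[seq.int(i0 + 1L, n)] < level)
  if (!length(below)) return(NA_real_)
  i <- i0 + below[1L]
  f <- (prob[i - 1L] - level) / (prob[i - 1L] - prob[i])
  grid[i - 1L] + f * (grid[i] - grid[i - 1L])
}

# ---- fast penalized IRLS refit on a precomputed model matrix ---------------

# total penalty matrix sum_j sp[j] * S_j embedded at the right coefficients
assemble_penalty <- function(g, sp = g$sp) {
  p <- length(stats::coef(g))
  St <- matrix(0, p, p)
  m <- 1L
  for (sm in g$smooth) {
    idx <- sm$first.para:sm$last.para
    for (k in seq_along(sm$S)) {
      St[idx, idx] <- St[idx, idx] + sp[m] * sm$S[[k]]
      m <- m + 1L
    }
  }
  St
}

# binomial penalized IRLS with fixed penalty; returns beta + convergence flag
pirls_binomial <- function(X, y, St, beta0 = NULL, maxit = 50, tol = 1e-8) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    Xw <- X * w
    H <- crossprod(Xw, X) + St
    beta_new <- tryCatch(solve(H + diag(1e-10, p), crossprod(Xw, z)),
                         error = function(e) NULL)
    if (is.null(beta_new) || anyNA(beta_new) || any(!is.finite(beta_new)))
      return(list(beta = beta, converged = FALSE))
    beta <- as.vector(beta_new)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (!is.finite(dev)) return(list(beta = beta, converged = FALSE))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1))
      return(list(beta = beta, converged = TRUE))
    dev_old <- dev
  }
  list(beta = beta, converged = FALSE)
}

#' Bootstrap reliability of the reference points of one species x year
#'
#' Resamples the year's point-count rows with replacement, refits the curve,
#' and re-extracts the reference points `n_boot` times. A replicate counts as
#' a success for a landmark when the refit converged and the landmark lies
#' inside the surveyed window. A landmark is reliable when its success
#' fraction reaches the `reliability` threshold (default at least 50%). The
#' reported elevations are those of the full-data fit, not bootstrap
#' aggregates.
#'
#' With `refit_sp = "fixed"` (default) bootstrap refits reuse the full-data
#' fit's spline bases and smoothing parameters and re-estimate only the
#' coefficients, via penalized IRLS on the resampled rows of the precomputed
#' model matrix. `refit_sp = "free"` repeats full smoothness selection per
#' replicate.
#'
#' @inheritParams fit_year_curve
#' @param seed integer seed (required; one seed per species x year makes the
#'   pipeline reproducible).
#'
#' @return A `reference_points` data frame as from
#'   [extract_reference_points()], with additional columns `success_frac`
#'   and `reliable`, plus attributes `n_boot` and `converged` (full-data
#'   fit). When the full-data fit fails, all landmarks have success 0.
#' @export
bootstrap_reliability <- function(rows, settings = curve_settings(), seed) {
  if (missing(seed)) stop("'seed' is required")
  full <- fit_year_curve(rows, settings)
  empty <- data.frame(landmark = c("OBL", "CBL", "OPT", "CBR", "OBR"),
                      elevation = NA_real_, status = "failed",
                      success_frac = 0, reliable = FALSE,
                      stringsAsFactors = FALSE)
  if (!full$converged) {
    class(empty) <- c("reference_points", "data.frame")
    attr(empty, "n_boot") <- settings$n_boot
    attr(empty, "converged") <- FALSE
    return(empty)
  }
  rp <- extract_reference_points(full, settings$bounds)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(rows)
  succ <- stats::setNames(numeric(5), rp$landmark)
  g <- full$model
  St <- assemble_penalty(g)
  beta_full <- stats::coef(g)
  y <- rows$presence
  for (b in seq_len(settings$n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (settings$refit_sp == "fixed") {
      yb <- y[idx]
      if (all(yb == 0) || all(yb == 1)) next
      fit <- pirls_binomial(full$X[idx, , drop = FALSE], yb, St,
                            beta0 = beta_full)
      if (!fit$converged) next
      prob_b <- as.vector(stats::plogis(full$Cpred %*% fit$beta))
      curve_b <- list(grid = full$grid, prob = prob_b)
    } else {
      fb <- fit_year_curve(rows[idx, , drop = FALSE], settings)
      if (!fb$converged) next
      curve_b <- fb
    }
    rp_b <- extract_reference_points(curve_b, settings$bounds)
    ok <- rp_b$status == "ok"
    succ[rp_b$landmark[ok]] <- succ[rp_b$landmark[ok]] + 1
  }
  rp$success_frac <- as.numeric(succ[rp$landmark]) / settings$n_boot
  rp$reliable <- rp$status == "ok" & rp$success_frac >= settings$reliability
  attr(rp, "n_boot") <- settings$n_boot
  attr(rp, "converged") <- TRUE
  rp
}

#' Assemble reference-point time series
#'
#' Stacks per-year reference points into one time series per landmark,
#' keeping only reliable year values and pairing each with that year's
#' sampling effort (the weight of the downstream trend regression). A series
#' is informative when it has at least `min_years` reliable values;
#' non-informative series are excluded from the long-term analysis.
#'
#' @param points_by_year named list (by year) of `reference_points` data
#'   frames as returned by [bootstrap_reliability()].
#' @param effort named vector of yearly sampling effort.
#' @param min_years informative-series threshold (default 10).
#'
#' @return Named list (by landmark) of data frames `year`, `elevation`,
#'   `n_y`, each with attribute `informative` (logical). Landmarks with no
#'   reliable years yield empty, non-informative series.
#' @export
build_series <- function(points_by_year, effort, min_years = 10) {
  if (length(points_by_year) == 0) stop("at least one year must be supplied")
  years <- as.integer(names(points_by_year))
  landmarks <- c("OBL", "CBL", "OPT", "CBR", "OBR")
  out <- lapply(landmarks, function(lm) {
    rows <- lapply(seq_along(years), function(i) {
      rp <- points_by_year[[i]]
      r <- rp[rp$landmark == lm, ]
      if (nrow(r) == 1 && isTRUE(r$reliable))
        data.frame(year = years[i], elevation = r$elevation,
                   n_y = unname(effort[as.character(years[i])]))
      else NULL
    })
    s <- do.call(rbind, rows)
    if (is.null(s)) s <- data.frame(year = integer(), elevation = numeric(),
                                    n_y = numeric())
    attr(s, "informative") <- nrow(s) >= min_years
    s
  })
  stats::setNames(out, landmarks)
}
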