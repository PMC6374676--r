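#' Expand driver calls into contingency records
#'
#' Chooses the counting unit for the pattern x habitat x migration x driver
#' cross-tabulation. A species has a single pattern but may carry several
#' per-landmark driver calls, so the unit is configurable: one record per
#' species x distinct final driver class (default), or one record per
#' significant reference point. The two dde relabels collapse into a single
#' `dde` driver level.
#'
#' @param calls data frame with one row per significant reference point:
#'   columns `species`, `habitat`, `migration`, `pattern`, `label` (driver
#'   label as from [finalize_driver_call()]).
#' @param mode counting unit, `"species_driver"` or `"reference_point"`.
#'
#' @return Data frame `species`, `pattern`, `habitat`, `migration`,
#'   `driver` (factor levels `tn`, `SF`, `tn+SF`, `nd`, `dde`).
#' @export
driver_records <- function(calls, mode = c("species_driver",
                                           "reference_point")) {
  mode <- match.arg(mode)
  drv <- ifelse(grepl("^dde", calls$label), "dde", calls$label)
  rec <- data.frame(species = calls$species, pattern = calls$pattern,
                    habitat = calls$habitat, migration = calls$migration,
                    driver = drv, stringsAsFactors = FALSE)
  if (mode == "species_driver") rec <- unique(rec)
  rownames(rec) <- NULL
  rec
}

#' Build the 4-way contingency table
#'
#' Crosses pattern of elevational range change (3 levels), breeding habitat
#' (3), migration habit (3) and range-change driver (5, with `dde` as its
#' own level) into a complete 3 x 3 x 3 x 5 = 135-cell count table; absent
#' combinations count zero.
#'
#' @param records data frame from [driver_records()] (columns `pattern`,
#'   `habitat`, `migration`, `driver`).
#' @return A 4-dimensional `table`.
#' @export
build_contingency <- function(records) {
  lv <- list(
    pattern = c("lower boundary contraction", "upward shift",
                "upper boundary expansion"),
    habitat = c("open", "edge", "forest"),
    migration = c("ldm", "sdm", "res"),
    driver = c("tn", "SF", "tn+SF", "nd", "dde"))
  for (v in names(lv)) {
    bad <- setdiff(unique(records[[v]]), lv[[v]])
    if (length(bad))
      stop("unknown ", v, " level(s): ", paste(bad, collapse = ", "))
  }
  table(pattern = factor(records$pattern, lv$pattern),
        habitat = factor(records$habitat, lv$habitat),
        migration = factor(records$migration, lv$migration),
        driver = factor(records$driver, lv$driver))
}

#' Sequential Poisson log-linear deviance table
#'
#' Fits a nested sequence of Poisson log-linear models to the cell counts,
#' starting from the intercept-only (null) model, and reports for each added
#' term its degrees of freedom, the deviance it removes, the residual
#' degrees of freedom and deviance, and a chi-squared p-value for the
#' deviance drop. The default sequence is the four main effects followed by
#' the three pattern interactions.
#'
#' @param tab 4-way contingency `table` from [build_contingency()].
#' @param terms character vector of model terms added one at a time, in
#'   order (must yield a nested sequence).
#'
#' @return Data frame of class `deviance_table`: `term`, `df`, `deviance`,
#'   `resid_df`, `resid_deviance`, `p` (first row is the null model with NA
#'   `df`, `deviance`, `p`).
#' @export
loglinear_deviance_table <- function(tab,
                                     terms = c("pattern", "habitat",
                                               "migration", "driver",
                                               "pattern:habitat",
                                               "pattern:migration",
                                               "pattern:driver")) {
  df <- as.data.frame(tab, stringsAsFactors = TRUE)
  names(df)[names(df) == "Freq"] <- "count"
  # sparse tables are expected (most of the 135 cells are empty); glm's
  # zero-rate warnings are part of normal Poisson fitting here
  fits <- list(stats::glm(count ~ 1, family = stats::poisson(), data = df))
  rhs <- "1"
  for (tm in terms) {
    rhs <- paste(rhs, "+", tm)
    fits <- c(fits, list(suppressWarnings(
      stats::glm(stats::as.formula(paste("count ~", rhs)),
                 family = stats::poisson(), data = df))))
  }
  rd <- vapply(fits, function(f) f$df.residual, numeric(1))
  dev <- vapply(fits, stats::deviance, numeric(1))
  if (any(diff(rd) > 0)) stop("term sequence is not nested")
  drop_df <- -diff(rd)
  drop_dev <- -diff(dev)
  if (any(drop_dev < -1e-8)) stop("deviance increased along the sequence")
  out <- data.frame(
    term = c("null", terms),
    df = c(NA, drop_df),
    deviance = c(NA, drop_dev),
    resid_df = rd,
    resid_deviance = dev,
    p = c(NA, ifelse(drop_df > 0,
                     stats::pchisq(pmax(drop_dev, 0), drop_df,
                                   lower.tail = FALSE), NA)))
  class(out) <- c("deviance_table", "data.frame")
  out
}

#' Residual deviance of the saturated log-linear model
#'
#' Convenience check: the model with the full four-way interaction
#' reproduces every cell exactly (residual deviance zero).
#'
#' @param tab contingency table.
#' @return Residual deviance (numeric).
#' @export
saturated_residual_deviance <- function(tab) {
  df <- as.data.frame(tab, stringsAsFactors = TRUE)
  names(df)[names(df) == "Freq"] <- "count"
  fit <- suppressWarnings(
    stats::glm(count ~ pattern * habitat * migration * driver,
               family = stats::poisson(), data = df))
  stats::deviance(fit)
}
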