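test_that("degenerate and undersized inputs are flagged, never raised", {
  rows <- data.frame(year = 2000, easting = runif(100, 0, 1e4),
                     northing = runif(100, 0, 1e4),
                     elevation = runif(100, 600, 2700),
                     species = "sp", presence = 0)
  fc <- fit_year_curve(rows)
  expect_false(fc$converged)
  expect_equal(fc$reason, "degenerate response")
  expect_error(extract_reference_points(fc), "non-convergent")

  tiny <- rows[1:10, ]
  tiny$presence <- rep(c(0, 1), 5)
  expect_equal(fit_year_curve(tiny)$reason, "too few rows")
})

test_that("analytic split-Gaussian landmarks sit at mu +/- sigma multiples", {
  cur <- analytic_curve(1500, 200, 200)
  rp <- extract_reference_points(cur)
  got <- setNames(rp$elevation, rp$landmark)
  expect_equal(unname(got[c("OBL", "CBL", "OPT", "CBR", "OBR")]),
               c(1100, 1300, 1500, 1700, 1900), tolerance = 1.01)

  # truncated left side: crossings below the 600 m bound are missing
  cur2 <- analytic_curve(700, 200, 200)
  rp2 <- extract_reference_points(cur2)
  g2 <- setNames(rp2$elevation, rp2$landmark)
  s2 <- setNames(rp2$status, rp2$landmark)
  expect_equal(unname(g2["OPT"]), 700, tolerance = 1.01)
  expect_equal(unname(g2["CBR"]), 900, tolerance = 1.01)
  expect_equal(unname(g2["OBR"]), 1100, tolerance = 1.01)
  expect_true(all(s2[c("CBL", "OBL")] == "truncated"))

  # maximum pinned to the window edge: monotone curve, optimum truncated
  cur3 <- analytic_curve(550, 200, 200)
  rp3 <- extract_reference_points(cur3)
  s3 <- setNames(rp3$status, rp3$landmark)
  expect_true(all(s3[c("OPT", "CBL", "OBL")] == "truncated"))
})

test_that("extraction matches the dense-grid scan oracle on random curves", {
  set.seed(42)
  for (i in 1:100) {
    mu <- runif(1, 700, 2600)
    sl <- runif(1, 80, 500)
    su <- runif(1, 80, 500)
    pm <- runif(1, 0.1, 0.95)
    cur <- analytic_curve(mu, sl, su, pm)
    rp <- extract_reference_points(cur)
    got <- setNames(rp$elevation, rp$landmark)
    oracle <- scan_reference_points(function(e)
      true_presence_prob(e, pm, mu, sl, su))
    for (lm in names(oracle)) {
      if (is.na(oracle[lm])) {
        expect_true(is.na(got[lm]),
                    label = sprintf("curve %d %s truncated", i, lm))
      } else {
        expect_lt(abs(got[lm] - oracle[lm]), 1.01,
                  label = sprintf("curve %d %s", i, lm))
      }
    }
    # ordering invariant whenever all five are present
    if (!anyNA(got))
      expect_true(all(diff(got[c("OBL", "CBL", "OPT", "CBR", "OBR")]) >= 0))
  }
})

test_that("the fitted curve recovers the generating optimum", {
  g <- generate_landscape(seed = 5)
  tr <- make_species_truth("sp", 2000L, p_max = 0.6, mu0 = 1500,
                           sigma_l = 200, sigma_u = 200)
  sv <- simulate_surveys(g, tr, c("2000" = 5000L), seed = 21)
  fc <- fit_year_curve(sv)
  expect_true(fc$converged)
  expect_lt(abs(fc$grid[which.max(fc$prob)] - 1500), 50)
  expect_true(all(fc$prob >= 0 & fc$prob <= 1))

  # flat truth: fitted curves stay flat (median wiggle over replicate
  # surveys, since any single fit carries sampling noise)
  flat <- make_species_truth("fl", 2000L, p_max = 0.5, sigma_l = 1e9,
                             sigma_u = 1e9)
  wiggle <- vapply(1:3, function(s) {
    svf <- simulate_surveys(g, flat, c("2000" = 5000L), seed = 21 + s)
    fcf <- fit_year_curve(svf)
    expect_true(fcf$converged)
    max(fcf$prob) - min(fcf$prob)
  }, numeric(1))
  expect_lt(stats::median(wiggle), 0.1)
})

test_that("reference points are invariant to translating the coordinates", {
  g <- generate_landscape(seed = 6)
  tr <- make_species_truth("sp", 2000L, p_max = 0.6, mu0 = 1400,
                           sigma_l = 250, sigma_u = 250)
  sv <- simulate_surveys(g, tr, c("2000" = 2000L), seed = 31)
  fc1 <- fit_year_curve(sv)
  sv2 <- sv
  sv2$easting <- sv2$easting + 50000
  sv2$northing <- sv2$northing + 80000
  fc2 <- fit_year_curve(sv2)
  rp1 <- extract_reference_points(fc1)
  rp2 <- extract_reference_points(fc2)
  expect_equal(rp1$elevation, rp2$elevation, tolerance = 5)
})

test_that("bootstrap reliability counts successes and applies the threshold", {
  g <- generate_landscape(seed = 7)
  yrs <- 2000L
  # absent species: full fit degenerate, zero success everywhere
  absent <- data.frame(year = 2000, easting = runif(200, 0, 1e4),
                       northing = runif(200, 0, 1e4),
                       elevation = runif(200, 600, 2700),
                       species = "none", presence = 0)
  st <- curve_settings(n_boot = 20, step = 5)
  rp0 <- bootstrap_reliability(absent, st, seed = 1)
  expect_true(all(rp0$success_frac == 0))
  expect_true(all(!rp0$reliable))
  expect_false(attr(rp0, "converged"))

  # strong signal: optimum succeeds in nearly every replicate
  tr <- make_species_truth("sp", yrs, p_max = 0.7, mu0 = 1500,
                           sigma_l = 250, sigma_u = 250)
  sv <- simulate_surveys(g, tr, c("2000" = 500L), seed = 41)
  st2 <- curve_settings(n_boot = 50, step = 5)
  rp <- bootstrap_reliability(sv, st2, seed = 42)
  expect_gte(rp$success_frac[rp$landmark == "OPT"], 0.9)
  expect_true(all(rp$success_frac >= 0 & rp$success_frac <= 1))
  # reliability is exactly the thresholded success fraction
  expect_identical(rp$reliable,
                   rp$status == "ok" & rp$success_frac >= st2$reliability)
  expect_error(bootstrap_reliability(sv, st2), "seed")
})

test_that("series assembly enforces the informative-years threshold", {
  mk <- function(ok) {
    data.frame(landmark = c("OBL", "CBL", "OPT", "CBR", "OBR"),
               elevation = c(1100, 1300, 1500, 1700, 1900),
               status = "ok", success_frac = 1,
               reliable = c(ok, TRUE, TRUE, TRUE, FALSE))
  }
  years <- 1990:2003
  eff <- setNames(rep(100, 14), years)
  pts <- setNames(lapply(seq_along(years), function(i) mk(i <= 10)), years)
  ser <- build_series(pts, eff, min_years = 10)
  expect_true(attr(ser$OBL, "informative"))    # exactly 10 reliable years
  expect_equal(nrow(ser$OBL), 10)
  expect_true(attr(ser$OPT, "informative"))
  expect_false(attr(ser$OBR, "informative"))   # 0 reliable years
  expect_equal(nrow(ser$OBR), 0)
  pts9 <- setNames(lapply(seq_along(years), function(i) mk(i <= 9)), years)
  expect_false(attr(build_series(pts9, eff)$OBL, "informative"))  # 9 < 10
  # efforts ride along as the future regression weights
  expect_equal(ser$OPT$n_y, rep(100, 14))
  expect_error(build_series(list(), eff), "at least one")
})
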