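mk_series <- function(y, w = rep(100, length(y)), years = NULL) {
  if (is.null(years)) years <- seq(1990, length.out = length(y))
  data.frame(year = years, elevation = y, n_y = w)
}

test_that("driver regression recovers exact and noisy coefficients", {
  set.seed(5)
  n <- 28
  tn <- data.frame(year = 1990:(1989 + n), tn = 5 + 0.05 * (1:n) + rnorm(n, 0, 0.3))
  sf <- data.frame(year = 1990:(1989 + n), sf = 100 + 2 * (1:n) + rnorm(n, 0, 3))
  y <- 2 * tn$tn
  # exact fit by construction; lm warns that its summary is degenerate
  reg <- suppressWarnings(
    fit_driver_regression(mk_series(y, years = tn$year), tn, sf))
  expect_equal(reg$beta_tn, 2, tolerance = 1e-8)
  expect_equal(reg$beta_sf, 0, tolerance = 1e-8)
  expect_gt(reg$r2_adj, 0.999)
  expect_gte(reg$r2, reg$r2_adj)

  sf0 <- sf; sf0$sf <- 150
  expect_error(fit_driver_regression(mk_series(y, years = tn$year), tn, sf0),
               "zero-variance")
  short <- tn[1:10, ]
  expect_error(fit_driver_regression(mk_series(y, years = tn$year), short, sf),
               "do not cover")
})

test_that("coefficient estimates are unbiased at the simulated effect sizes", {
  set.seed(31)
  reps <- 200; n <- 28
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    tnv <- 5 + 0.05 * (1:n) + rnorm(n, 0, 0.3)
    sfv <- 100 + 2 * (1:n) + rnorm(n, 0, 3)
    y <- 1000 + 10 * tnv + 50 * sfv + rnorm(n, 0, 40)
    tn <- data.frame(year = 1:n, tn = tnv)
    sf <- data.frame(year = 1:n, sf = sfv)
    reg <- fit_driver_regression(mk_series(y, years = 1:n), tn, sf)
    est[r, ] <- c(reg$beta_tn, reg$beta_sf)
  }
  mc_se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 10), 2 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - 50), 2 * mc_se[2])
})

test_that("variation partition handles orthogonal and collinear predictors", {
  # exactly orthogonal centred predictors
  tn <- c(-1, 1, -1, 1, -1, 1)
  sf <- c(-1, -1, 1, 1, -1, 1) # not orthogonal; build orthogonal instead
  sf <- c(1, 1, -1, -1, 1, -1) * c(1, -1, 1, -1, 1, -1)
  tn <- rep(c(-1, 1), 3)
  sf <- rep(c(-1, 1), each = 3)[c(1, 4, 2, 5, 3, 6)]
  # guarantee orthogonality numerically
  sf <- sf - sum(sf * tn) / sum(tn * tn) * tn
  y <- 2 * tn + 3 * sf + c(0.1, -0.2, 0.05, 0.15, -0.1, 0)
  w <- rep(1, 6)
  part <- variation_partition(y, tn, sf, w)
  expect_equal(part$shared, 0, tolerance = 1e-9)
  expect_equal(part$partial_tn, part$r2_tn, tolerance = 1e-9)
  expect_equal(part$partial_sf, part$r2_sf, tolerance = 1e-9)

  # perfectly duplicated predictor: everything is shared
  set.seed(8)
  x <- rnorm(12); yy <- 3 * x + rnorm(12, 0, 0.5)
  p2 <- variation_partition(yy, x, x)
  expect_equal(p2$partial_tn, 0, tolerance = 1e-9)
  expect_equal(p2$partial_sf, 0, tolerance = 1e-9)
  expect_equal(p2$shared, p2$r2_both, tolerance = 1e-9)
})

test_that("partition equals the three-model oracle and sums to one", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    tn <- rnorm(n); sf <- 0.6 * tn + rnorm(n)
    y <- rnorm(n, 2 * tn + sf)
    w <- runif(n, 0.5, 3)
    part <- variation_partition(y, tn, sf, w)
    or <- oracle_partition(y, tn, sf, w)
    # raw components agree with the brute-force fits before flooring
    expect_equal(part$r2_both - part$r2_sf, unname(or["partial_tn"]),
                 tolerance = 1e-10)
    expect_equal(part$r2_both - part$r2_tn, unname(or["partial_sf"]),
                 tolerance = 1e-10)
    expect_equal(1 - part$r2_both, unname(or["unexplained"]),
                 tolerance = 1e-10)
    total <- part$partial_tn + part$shared + part$partial_sf +
      part$unexplained
    expect_equal(total, 1, tolerance = 1e-9)
    expect_true(all(c(part$partial_tn, part$shared, part$partial_sf,
                      part$unexplained) >= 0))
  }
})

test_that("independent effects split the shared component evenly", {
  set.seed(3)
  tn <- rnorm(20); sf <- 0.5 * tn + rnorm(20); y <- tn + sf + rnorm(20)
  part <- variation_partition(y, tn, sf)
  ie <- independent_effects(y, tn, sf)
  expect_equal(ie$indep_tn + ie$indep_sf, part$r2_both, tolerance = 1e-9)
  expect_equal(ie$indep_tn - ie$indep_sf,
               part$partial_tn - part$partial_sf, tolerance = 1e-9)
})

test_that("driver classification applies the threshold rules in order", {
  cls <- function(ptn, sh, psf, un)
    classify_driver(list(partial_tn = ptn, shared = sh, partial_sf = psf,
                         unexplained = un))
  expect_equal(cls(0.042, 0.414, 0.307, 0.237)$class, "SF")
  expect_equal(cls(0.000, 0.946, 0.049, 0.003)$class, "nd")
  expect_equal(cls(0.109, 0.182, 0.526, 0.183)$class, "tn+SF")
  expect_equal(cls(0.253, 0.484, 0.048, 0.215)$class, "tn")
  fb <- cls(0.099, 0.783, 0.040, 0.078)
  expect_equal(fb$class, "nd")
  expect_equal(fb$rule, "fallback")
  expect_equal(cls(0.01, 0.03, 0.02, 0.94)$class, "none")
})

test_that("finalisation resolves nd calls and flags density-dependent effects", {
  part_sh <- list(partial_tn = 0.038, shared = 0.954, partial_sf = 0.003,
                  unexplained = 0.004)
  raw_sh <- classify_driver(part_sh)
  # temperature individually significant, cover not: nd becomes tn
  call <- finalize_driver_call(raw_sh, list(beta_sf = -50.28, p_tn = 0.005,
                                            p_sf = 0.131), part_sh, "OBR")
  expect_equal(call$final, "tn")
  expect_false(call$dde)    # tn is exempt from the dde relabel

  # cover-only significance under a dominant shared component stays nd
  part_nd <- list(partial_tn = 0.002, shared = 0.946, partial_sf = 0.049,
                  unexplained = 0.003)
  call2 <- finalize_driver_call(classify_driver(part_nd),
                                list(beta_sf = 103.8, p_tn = 0.116,
                                     p_sf = 0.001), part_nd, "OBL")
  expect_equal(call2$final, "nd")
  expect_false(call2$dde)

  # fallback nd with both coefficients significant: larger net contribution
  part_fb <- list(partial_tn = 0.094, shared = 0.823, partial_sf = 0.038,
                  unexplained = 0.045)
  call3 <- finalize_driver_call(classify_driver(part_fb),
                                list(beta_sf = 47.46, p_tn = 0.001,
                                     p_sf = 0.009), part_fb, "CBR")
  expect_equal(call3$final, "tn")
  part_fb2 <- list(partial_tn = 0.038, shared = 0.824, partial_sf = 0.089,
                   unexplained = 0.048)
  call4 <- finalize_driver_call(classify_driver(part_fb2),
                                list(beta_sf = 68.61, p_tn = 0.035,
                                     p_sf = 0.006), part_fb2, "OBR")
  expect_equal(call4$final, "SF")
  expect_false(call4$dde)   # positive cover effect

  # negative cover effect at an upper landmark relabels SF and nd calls
  part_sf <- list(partial_tn = 0, shared = 0.541, partial_sf = 0.439,
                  unexplained = 0.02)
  call5 <- finalize_driver_call(classify_driver(part_sf),
                                list(beta_sf = -112.1, p_tn = 0.912,
                                     p_sf = 0.0005), part_sf, "OBR")
  expect_true(call5$dde)
  expect_equal(call5$label, "dde(SF)")
  part_nd2 <- list(partial_tn = 0, shared = 0.993, partial_sf = 0.007,
                   unexplained = 0)
  call6 <- finalize_driver_call(classify_driver(part_nd2),
                                list(beta_sf = -153.9, p_tn = 0.506,
                                     p_sf = 0.006), part_nd2, "OBR")
  expect_equal(call6$label, "dde(nd)")

  # lower landmark with positive cover effect: plain SF, never dde
  part_lo <- list(partial_tn = 0, shared = 0.445, partial_sf = 0.521,
                  unexplained = 0.034)
  call7 <- finalize_driver_call(classify_driver(part_lo),
                                list(beta_sf = 96.46, p_tn = 0.767,
                                     p_sf = 0.0005), part_lo, "CBL")
  expect_equal(call7$label, "SF")
})

test_that("temperature-only worlds are never attributed to cover", {
  set.seed(77)
  reps <- 200; ok <- 0; n <- 28
  for (r in seq_len(reps)) {
    tnv <- 5 + 0.046 * (1:n) + rnorm(n, 0, 0.3)
    sfv <- 150 + rnorm(n, 0, 2)          # flat habitat, noise only
    y <- 1000 + 60 * tnv + rnorm(n, 0, 25)
    tn <- data.frame(year = 1:n, tn = tnv)
    sf <- data.frame(year = 1:n, sf = sfv)
    reg <- fit_driver_regression(mk_series(y, years = 1:n), tn, sf)
    part <- variation_partition(reg$data$elevation, reg$data$tn, reg$data$sf,
                                reg$data$n_y)
    call <- finalize_driver_call(classify_driver(part), reg, part, "OPT")
    if (call$final %in% c("tn", "nd")) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})
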