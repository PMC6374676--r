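# tabulated split-Gaussian curve for extraction tests
analytic_curve <- function(mu, sigma_l, sigma_u, p_max = 0.6,
                           bounds = c(600, 2700), step = 1) {
  grid <- seq(bounds[1], bounds[2], by = step)
  list(grid = grid,
       prob = true_presence_prob(grid, p_max, mu, sigma_l, sigma_u))
}

# independent dense-grid scan oracle: landmarks from a raw function of
# elevation, located on a 0.1-m grid with no interpolation
scan_reference_points <- function(f, bounds = c(600, 2700)) {
  g <- seq(bounds[1], bounds[2], by = 0.1)
  p <- f(g)
  i0 <- which.max(p)
  pm <- p[i0]
  out <- c(OBL = NA, CBL = NA, OPT = NA, CBR = NA, OBR = NA)
  if (i0 > 1 && i0 < length(g)) out["OPT"] <- g[i0]
  for (side in c("L", "R")) {
    for (lv in c(CB = exp(-0.5), OB = exp(-2))) {
      nm <- paste0(names(which(c(CB = exp(-0.5), OB = exp(-2)) == lv)), side)
      idx <- if (side == "L") rev(seq_len(i0 - 1)) else seq(i0 + 1, length(g))
      hit <- idx[p[idx] < pm * lv][1]
      if (!is.na(hit) && i0 > 1 && i0 < length(g)) out[nm] <- g[hit]
    }
  }
  out
}

# weighted R^2 through an independent code path (explicit normal equations)
oracle_weighted_r2 <- function(y, X, w) {
  X1 <- cbind(1, X)
  b <- solve(crossprod(X1 * w, X1), crossprod(X1 * w, y))
  e <- y - X1 %*% b
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * e^2) / sum(w * (y - ybar)^2)
}

# brute-force three-model partition oracle
oracle_partition <- function(y, tn, sf, w) {
  r2t <- oracle_weighted_r2(y, cbind(tn), w)
  r2s <- oracle_weighted_r2(y, cbind(sf), w)
  r2b <- oracle_weighted_r2(y, cbind(tn, sf), w)
  c(partial_tn = r2b - r2s, shared = r2t + r2s - r2b,
    partial_sf = r2b - r2t, unexplained = 1 - r2b)
}

# a small ready-made reference-point series
toy_series <- function(slope = 5, n = 15, sd = 0, seed = 1,
                       weights = rep(100, n)) {
  set.seed(seed)
  year <- seq(1990, length.out = n)
  data.frame(year = year,
             elevation = 1000 + slope * (year - year[1]) + rnorm(n, 0, sd),
             n_y = weights)
}
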