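# Independent oracles, written from the definitions, never from package
# internals. Each is a deliberately naive implementation used to freeze
# expected values.

# brute-force RGB (0-255) -> HSV, scalar, straight from the hexcone
# definition
oracle_hsv <- function(R, G, B) {
  r <- R / 255; g <- G / 255; b <- B / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  if (d == 0) {
    h <- 0
  } else if (mx == r) {
    h <- 60 * ((g - b) / d)
  } else if (mx == g) {
    h <- 60 * (2 + (b - r) / d)
  } else {
    h <- 60 * (4 + (r - g) / d)
  }
  if (h < 0) h <- h + 360
  c(h = h, s = if (mx > 0) d / mx else 0, v = mx)
}

# one-line index formulas on proportions
oracle_index <- function(name, R, G, B) {
  r <- R / 255; g <- G / 255; b <- B / 255
  switch(name,
    gmr = g - r,
    gdr = if (r == 0) NA_real_ else g / r,
    ngrdi = if (g + r == 0) NA_real_ else (g - r) / (g + r),
    vari = if (g + r - b == 0) NA_real_ else (g - r) / (g + r - b),
    gli = if (2 * g + r + b == 0) NA_real_
          else (2 * g - r - b) / (2 * g + r + b),
    tgi = -0.5 * (190 * (r - g) - 120 * (r - b)),
    dgci = {
      if (max(R, G, B) == min(R, G, B)) return(NA_real_)
      hsv <- oracle_hsv(R, G, B)
      unname(((hsv["h"] - 60) / 60 + (1 - hsv["s"]) +
                (1 - hsv["v"])) / 3)
    })
}

# counting-based midranks (independent of base rank())
oracle_midrank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, numeric(1))
}

# Pearson/Spearman coefficient from first principles
oracle_cor <- function(x, y, method = "pearson") {
  if (method == "spearman") {
    x <- oracle_midrank(x); y <- oracle_midrank(y)
  }
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# classical one-way multivariate pseudo-F straight from coordinates:
# between/within sums of squared deviations from centroids
oracle_pseudo_f <- function(points, labels) {
  labels <- as.factor(labels)
  grand <- colMeans(points)
  ssw <- 0; ssb <- 0
  for (lv in levels(labels)) {
    sub <- points[labels == lv, , drop = FALSE]
    cen <- colMeans(sub)
    ssw <- ssw + sum(sweep(sub, 2, cen)^2)
    ssb <- ssb + nrow(sub) * sum((cen - grand)^2)
  }
  k <- nlevels(labels); n <- nrow(points)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# exhaustive two-group permutation p for the pseudo-F, enumerating group-A
# index sets with combn (independent of the package's permutation code)
oracle_exact_two_group_p <- function(points, labels) {
  labels <- as.factor(labels)
  lv <- levels(labels)
  n <- nrow(points)
  na <- sum(labels == lv[1])
  f_obs <- oracle_pseudo_f(points, labels)
  sets <- combn(n, na)
  fs <- apply(sets, 2, function(i) {
    lab <- rep(lv[2], n); lab[i] <- lv[1]
    oracle_pseudo_f(points, lab)
  })
  sum(fs >= f_obs - 1e-12) / ncol(sets)
}

# small deterministic experiment for scoring/stats tests
tiny_experiment <- function(n_varieties = 5, seed = 7, noise_sd = 3,
                            n_check_patches = 7, ...) {
  cfg <- sim_config(noise_sd = noise_sd,
                    n_check_patches = n_check_patches, seed = seed, ...)
  simulate_experiment(cfg, default_profiles(n_varieties), seed = seed)
}
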