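test_that("correlation anchors: perfect linear and monotone relations", {
  x <- 1:10
  r <- correlate(x, 2 * x + 1, method = "pearson")
  expect_equal(r$statistic, 1, tolerance = 1e-12)
  rho <- correlate(x, exp(x / 3), method = "spearman")
  expect_equal(rho$statistic, 1, tolerance = 1e-12)
  expect_warning(cc <- correlate(x, rep(1, 10)), "constant")
  expect_true(is.na(cc$statistic))
  expect_error(correlate(1:2, 1:2), class = "hb_domain_error")
})

test_that("correlations match first-principles oracles with ties", {
  set.seed(91)
  for (i in 1:20) {
    x <- round(runif(10, 0, 5))  # forces ties
    y <- round(runif(10, 0, 5), 1)
    for (m in c("pearson", "spearman")) {
      got <- suppressWarnings(correlate(x, y, method = m))
      if (is.na(got$statistic)) next
      expect_equal(got$statistic, oracle_cor(x, y, m), tolerance = 1e-12)
      # and against the reference implementation
      expect_equal(got$statistic, cor(x, y, method = m),
                   tolerance = 1e-12)
    }
  }
  # t-approximation p-value spot check
  set.seed(93)
  x <- rnorm(12); y <- x + rnorm(12)
  got <- correlate(x, y, method = "pearson")
  want <- cor.test(x, y)$p.value
  expect_equal(got$pValue, want, tolerance = 1e-9)
})

test_that("permanova pseudo-F equals the coordinate-space oracle", {
  set.seed(101)
  for (i in 1:10) {
    pts <- matrix(rnorm(30 * 3), ncol = 3)
    labs <- factor(rep(c("a", "b", "c"), each = 10))
    got <- permanova(pts, labs, n_perm = 99, seed = 1)
    expect_equal(got$statistic, oracle_pseudo_f(pts, labs),
                 tolerance = 1e-9)
  }
})

test_that("permanova agrees with vegan::adonis2 on the statistic", {
  skip_if_not_installed("vegan")
  set.seed(103)
  pts <- matrix(rnorm(24 * 3), ncol = 3)
  labs <- factor(rep(letters[1:3], each = 8))
  got <- permanova(pts, labs, n_perm = 199, seed = 2)
  ref <- vegan::adonis2(dist(pts) ~ labs,
                        permutations = 199)
  expect_equal(got$statistic, ref$F[1], tolerance = 1e-9)
})

test_that("separated clusters reach the minimal achievable p", {
  set.seed(107)
  pts <- rbind(matrix(rnorm(15 * 3, 0, 0.1), ncol = 3),
               matrix(rnorm(15 * 3, 50, 0.1), ncol = 3))
  labs <- factor(rep(c("lo", "hi"), each = 15))
  got <- permanova(pts, labs, n_perm = 999, seed = 3)
  expect_equal(got$pValue, 1 / 1000)
})

test_that("exact permanova matches exhaustive enumeration oracles", {
  set.seed(109)
  pts <- matrix(rnorm(6 * 3, 0, 1), ncol = 3)
  pts[4:6, ] <- pts[4:6, ] + 2
  labs <- factor(rep(c("x", "y"), each = 3))
  got <- permanova(pts, labs, exact = TRUE)
  expect_equal(got$statistic, oracle_pseudo_f(pts, labs),
               tolerance = 1e-9)
  expect_equal(got$pValue, oracle_exact_two_group_p(pts, labs),
               tolerance = 1e-12)
  # 7-point, unbalanced three-group fixture against brute statistics
  pts7 <- matrix(rnorm(7 * 3), ncol = 3)
  labs7 <- factor(c("a", "a", "b", "b", "c", "c", "c"))
  got7 <- permanova(pts7, labs7, exact = TRUE)
  expect_equal(got7$statistic, oracle_pseudo_f(pts7, labs7),
               tolerance = 1e-9)
  expect_gt(got7$pValue, 0)
})

test_that("pseudo-F is invariant under rotation and translation", {
  set.seed(113)
  pts <- matrix(rnorm(18 * 3), ncol = 3)
  labs <- factor(rep(1:3, each = 6))
  base <- permanova(pts, labs, n_perm = 99, seed = 1)$statistic
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sweep(pts %*% rot, 2, c(10, -4, 2), "+")
  expect_equal(permanova(moved, labs, n_perm = 99, seed = 1)$statistic,
               base, tolerance = 1e-9)
})

test_that("permutation p-values keep the (b+1)/(B+1) form", {
  set.seed(127)
  for (i in 1:20) {
    pts <- matrix(rnorm(12 * 3), ncol = 3)
    labs <- factor(rep(c("a", "b"), each = 6))
    res <- permanova(pts, labs, n_perm = 99, seed = i)
    expect_gt(res$pValue, 0)
    expect_lte(res$pValue, 1)
    expect_equal((res$pValue * 100) %% 1, 0, tolerance = 1e-9)
  }
})

test_that("identical seeds reproduce p; distinct seeds stay within MC error", {
  set.seed(131)
  pts <- matrix(rnorm(20 * 3), ncol = 3)
  pts[11:20, 1] <- pts[11:20, 1] + 1
  labs <- factor(rep(c("a", "b"), each = 10))
  p1 <- permanova(pts, labs, n_perm = 9999, seed = 42)$pValue
  p1b <- permanova(pts, labs, n_perm = 9999, seed = 42)$pValue
  p2 <- permanova(pts, labs, n_perm = 9999, seed = 43)$pValue
  expect_identical(p1, p1b)
  se <- sqrt(p1 * (1 - p1) / 9999)
  expect_lt(abs(p1 - p2), 5 * se + 2e-4)
})

test_that("insufficient replication and degenerate inputs error", {
  pts <- matrix(rnorm(5 * 3), ncol = 3)
  expect_error(permanova(pts, factor(c("a", "a", "a", "a", "b")),
                         n_perm = 99),
               class = "hb_insufficient_replication")
  expect_error(permanova(pts, factor(rep("a", 5)), n_perm = 99),
               class = "hb_domain_error")
})

test_that("pairwise tests cover each pair and flag separated groups", {
  set.seed(137)
  pts <- rbind(matrix(rnorm(12 * 3, 0), ncol = 3),
               matrix(rnorm(12 * 3, 30), ncol = 3),
               matrix(rnorm(12 * 3, 60), ncol = 3))
  labs <- factor(rep(c("a", "b", "c"), each = 12))
  pw <- pairwise_permanova(pts, labs, n_perm = 199, seed = 5)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$pRaw, rep(1 / 200, 3))
  expect_true(all(pw$pAdjusted >= pw$pRaw))
  expect_true(all(pw$tPairwise > 0))
})

test_that("pairwise null: a group against its own distribution is calm", {
  set.seed(139)
  hits <- replicate(200, {
    pts <- matrix(rnorm(16 * 3), ncol = 3)
    labs <- factor(rep(c("a", "b"), each = 8))
    pw <- pairwise_permanova(pts, labs, n_perm = 99)
    pw$pAdjusted[1] <= 0.05
  })
  expect_gte(mean(!hits), 0.94)
})

test_that("many-to-one flags nothing when identical to the check", {
  set.seed(149)
  chk <- rnorm(21)
  vals <- list(sameA = chk[1:3], sameB = chk[4:6])
  res <- many_to_one(vals, chk, seed = 7)
  expect_false(any(res$lessDamaged))
  expect_error(many_to_one(vals, chk[1]), class = "hb_config_error")
  expect_error(many_to_one(list(x = 1, y = 1:3), chk),
               class = "hb_domain_error")
})

test_that("many-to-one uses exact enumeration for small designs", {
  chk <- c(0.1, 0.2, 0.15, 0.12, 0.18)
  v <- list(up = c(0.9, 1.0, 0.95))
  res <- many_to_one(v, chk, seed = 11)
  expect_equal(res$nPermutations, choose(8, 3) - 1L)
  # only the observed assignment attains |diff| >= obs
  expect_equal(res$pRaw, 1 / choose(8, 3))
  expect_true(res$lessDamaged)
})

test_that("pcoa reproduces geometry and validates input", {
  expect_equal(unname(pcoa(dist(matrix(0, 4, 2)))$points),
               matrix(0, 4, 1))
  two <- pcoa(dist(matrix(c(0, 0, 3, 0), 2, byrow = TRUE)))
  expect_equal(unname(sort(two$points[, 1])), c(-1.5, 1.5), tolerance = 1e-9)
  set.seed(151)
  pts <- matrix(rnorm(10 * 3), ncol = 3)
  d <- dist(pts)
  rec <- pcoa(d)
  expect_lt(max(abs(as.matrix(dist(rec$points)) - as.matrix(d))), 1e-9)
  # double-centering oracle: coordinates match cmdscale up to sign
  ref <- cmdscale(d, k = 3)
  for (k in 1:3)
    expect_equal(abs(rec$points[, k]), abs(ref[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(bad), class = "hb_domain_error")
})
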