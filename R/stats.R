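# Permutation inference on colour triplets and index values: correlation
# tests, distance-based pseudo-F (PERMANOVA style), pairwise and
# many-to-one permutation tests, and principal coordinates ordination.
#
# Permutation p-values always take the (b + 1) / (B + 1) form, so they
# can never be zero; exhaustive enumeration is used instead of Monte
# Carlo when the permutation space is small.

#' @keywords internal
#' @noRd
hb_test <- function(statistic, kind, p_value, n_permutations = NA_integer_,
                    df_or_n = NA, method = "", comparison = "") {
  structure(list(statistic = statistic, statisticKind = kind,
                 pValue = p_value, nPermutations = n_permutations,
                 dfOrN = df_or_n, adjusted = FALSE,
                 adjustMethod = NA_character_,
                 method = method, comparison = comparison),
            class = "hb_test")
}

#' @export
print.hb_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g", x$method, x$statisticKind,
              x$statistic, x$pValue))
  if (!is.na(x$nPermutations))
    cat(sprintf(" (%d permutations)", x$nPermutations))
  if (isTRUE(x$adjusted)) cat(" [", x$adjustMethod, "-adjusted]", sep = "")
  cat("\n")
  invisible(x)
}

#' Correlation test (Pearson or Spearman)
#'
#' Pairwise deletion of missing values, midranks for Spearman ties, and a
#' t-approximation p-value `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y paired numeric vectors.
#' @param method `"spearman"` (default, for ordinal damage scores) or
#'   `"pearson"`.
#' @return An `hb_test` with `statistic` the coefficient and `dfOrN` the
#'   pair count; constant input yields an `NA` coefficient with a
#'   warning.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) hb_stop("need at least 3 complete pairs",
                     class = "hb_domain_error")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: correlation undefined", call. = FALSE)
    return(hb_test(NA_real_, if (method == "spearman") "rho" else "r",
                   NA_real_, df_or_n = n, method = method))
  }
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  hb_test(r, if (method == "spearman") "rho" else "r", p, df_or_n = n,
          method = method)
}

# sums of squares from a squared-distance matrix and a grouping
#' @keywords internal
#' @noRd
permanova_f <- function(d2, labels) {
  n <- length(labels)
  k <- nlevels(labels)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (lv in levels(labels)) {
    i <- which(labels == lv)
    ss_within <- ss_within + sum(d2[i, i]) / (2 * length(i))
  }
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# all n! permutations of seq_len(n) as a matrix (n <= 8)
#' @keywords internal
#' @noRd
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    idx <- c(i, setdiff(seq_len(n), i))
    out[r + seq_len(nrow(sub)), ] <- cbind(i, matrix(idx[-1][sub],
                                                     nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

#' Distance-based permutational MANOVA (one factor)
#'
#' Pseudo-F computed from the Euclidean distance matrix of the
#' observations (for colour work, the per-patch (meanR, meanG, meanB)
#' triplets): `F = (SS_between / df_between) / (SS_within / df_within)`,
#' with sums of squares obtained from pairwise squared distances. The
#' p-value is `(b + 1) / (B + 1)` over free permutations of the labels,
#' or exact over all `n!` relabellings when `exact = TRUE` (n <= 8).
#'
#' @param points numeric matrix, one observation per row (e.g. n x 3 RGB
#'   triplets), or a `dist` object.
#' @param labels factor of group labels; at least 2 levels with at least
#'   2 observations each.
#' @param n_perm number of Monte Carlo permutations (>= 99).
#' @param seed integer seed for the permutation draw.
#' @param exact enumerate all permutations instead of sampling.
#' @return An `hb_test` with `statistic` the observed pseudo-F.
#' @export
permanova <- function(points, labels, n_perm = 999, seed = NULL,
                      exact = FALSE) {
  d2 <- if (inherits(points, "dist")) as.matrix(points)^2
        else as.matrix(dist(points))^2
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  if (nrow(d2) != n)
    hb_stop("labels do not match points", class = "hb_domain_error")
  if (nlevels(labels) < 2L)
    hb_stop("need at least 2 groups", class = "hb_domain_error")
  if (any(table(labels) < 2L))
    hb_stop("each group needs at least 2 observations",
            class = "hb_insufficient_replication")
  f_obs <- permanova_f(d2, labels)
  if (exact) {
    if (n > 8L) hb_stop("exact enumeration limited to n <= 8",
                        class = "hb_config_error")
    perms <- all_perms(n)
    f_perm <- apply(perms, 1, function(ix) permanova_f(d2, labels[ix]))
    # identity permutation is in the enumeration, so the count is >= 1
    p <- sum(f_perm >= f_obs - 1e-12) / nrow(perms)
    nper <- nrow(perms) - 1L
  } else {
    if (n_perm < 99) hb_stop("n_perm must be >= 99",
                             class = "hb_config_error")
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    for (i in seq_len(n_perm))
      if (permanova_f(d2, sample(labels)) >= f_obs - 1e-12) b <- b + 1L
    p <- (b + 1) / (n_perm + 1)
    nper <- as.integer(n_perm)
  }
  hb_test(f_obs, "pseudoF", p, n_permutations = nper,
          df_or_n = c(df_between = nlevels(labels) - 1L,
                      df_within = n - nlevels(labels)),
          method = "permanova")
}

#' Pairwise two-group permutation tests after a PERMANOVA
#'
#' One two-level permutation test per unordered pair of factor levels;
#' the statistic is the square root of the two-group pseudo-F (a t-like
#' quantity). Raw and Holm-adjusted p-values are reported.
#'
#' @inheritParams permanova
#' @param p_adjust `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return `data.frame` with one row per pair: `groupA`, `groupB`,
#'   `tPairwise`, `pRaw`, `pAdjusted`, `nPermutations`.
#' @export
pairwise_permanova <- function(points, labels, n_perm = 999, seed = NULL,
                               p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  pts <- if (inherits(points, "dist")) as.matrix(points) else points
  labels <- droplevels(as.factor(labels))
  lv <- levels(labels)
  if (length(lv) < 2L) hb_stop("need at least 2 groups",
                               class = "hb_domain_error")
  pairs <- combn(lv, 2)
  if (!is.null(seed)) set.seed(derive_seed(seed, "perm"))
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    sel <- labels %in% pairs[, j]
    sub <- if (inherits(points, "dist")) stats::as.dist(pts[sel, sel])
           else pts[sel, , drop = FALSE]
    res <- permanova(sub, labels[sel], n_perm = n_perm)
    data.frame(groupA = pairs[1, j], groupB = pairs[2, j],
               tPairwise = sqrt(res$statistic), pRaw = res$pValue,
               nPermutations = res$nPermutations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- stats::p.adjust(out$pRaw, method = p_adjust)
  out
}

#' Many-to-one permutation comparisons against the susceptible check
#'
#' For each variety, a two-sample permutation test of the mean index
#' difference from the check (two-sided, exhaustive over group
#' assignments when the assignment space is small, Monte Carlo
#' otherwise), followed by Holm adjustment across varieties. A variety is
#' flagged as less damaged than the check when its adjusted p-value is at
#' or below `alpha` and its mean lies on the better-condition side.
#'
#' @param values named list of numeric vectors, one per variety
#'   (final-day index values across replicates).
#' @param check_values numeric vector for the check (>= 2 values).
#' @param n_perm Monte Carlo permutation count when enumeration is
#'   infeasible.
#' @param seed integer seed.
#' @param alpha familywise significance level for flagging.
#' @param higher_is_better direction in which the index signals better
#'   condition (`TRUE` for greenness indices such as GLI).
#' @param p_adjust `"holm"` (default), `"bonferroni"` or `"none"`.
#' @param max_exact enumerate exhaustively when `choose(n1 + n2, n1)` is
#'   at most this.
#' @return `data.frame`: `variety`, `meanDiff`, `pRaw`, `pAdjusted`,
#'   `nPermutations`, `lessDamaged`.
#' @export
many_to_one <- function(values, check_values, n_perm = 999, seed = NULL,
                        alpha = 0.05, higher_is_better = TRUE,
                        p_adjust = c("holm", "bonferroni", "none"),
                        max_exact = 20000) {
  p_adjust <- match.arg(p_adjust)
  if (length(check_values) < 2L)
    hb_stop("check needs at least 2 replicate values",
            class = "hb_config_error")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    hb_stop("values must be a named list", class = "hb_config_error")
  if (any(vapply(values, length, 1L) < 2L))
    hb_stop("each variety needs at least 2 replicate values",
            class = "hb_domain_error")
  if (!is.null(seed)) set.seed(derive_seed(seed, "perm"))
  one <- function(v) {
    pool <- c(v, check_values)
    n1 <- length(v); n <- length(pool)
    obs <- mean(v) - mean(check_values)
    n_comb <- choose(n, n1)
    tot <- sum(pool)
    if (n_comb <= max_exact) {
      idx <- combn(n, n1)
      s1 <- colSums(matrix(pool[idx], nrow = n1))
      diffs <- s1 / n1 - (tot - s1) / (n - n1)
      # enumeration includes the observed assignment
      p <- sum(abs(diffs) >= abs(obs) - 1e-12) / n_comb
      nper <- as.integer(n_comb - 1L)
    } else {
      idx <- replicate(n_perm, sample.int(n, n1))
      s1 <- colSums(matrix(pool[idx], nrow = n1))
      diffs <- s1 / n1 - (tot - s1) / (n - n1)
      b <- sum(abs(diffs) >= abs(obs) - 1e-12)
      p <- (b + 1) / (n_perm + 1)
      nper <- as.integer(n_perm)
    }
    c(diff = obs, p = p, nper = nper)
  }
  res <- t(vapply(values, one, c(diff = 0, p = 0, nper = 0)))
  out <- data.frame(variety = names(values), meanDiff = res[, "diff"],
                    pRaw = res[, "p"],
                    pAdjusted = stats::p.adjust(res[, "p"],
                                                method = p_adjust),
                    nPermutations = as.integer(res[, "nper"]),
                    stringsAsFactors = FALSE)
  better <- if (higher_is_better) out$meanDiff > 0 else out$meanDiff < 0
  out$lessDamaged <- out$pAdjusted <= alpha & better
  rownames(out) <- NULL
  out
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared distance matrix, eigendecomposes it and
#' returns coordinates on the axes with positive eigenvalues, ordered by
#' eigenvalue. With a Euclidean input the pairwise distances of the
#' coordinates reproduce the input exactly (up to numerical noise);
#' negative eigenvalues (non-Euclidean input) are dropped and reported.
#'
#' @param d a `dist` object or symmetric zero-diagonal distance matrix.
#' @return List of class `"hb_pcoa"`: `points` (n x k coordinate
#'   matrix), `eigenvalues`, `negative` (count of dropped negative
#'   eigenvalues).
#' @export
pcoa <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8) ||
      any(abs(diag(m)) > 1e-8))
    hb_stop("need a symmetric zero-diagonal distance matrix",
            class = "hb_domain_error")
  n <- nrow(m)
  a <- -0.5 * m^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9 + 1e-12
  pos <- e$values > tol
  pts <- if (any(pos))
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                            sum(pos))
  else matrix(0, n, 1)
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts, eigenvalues = e$values,
                 negative = sum(e$values < -tol)),
            class = "hb_pcoa")
}
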