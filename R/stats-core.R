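# Elementary statistics implemented in the package itself. These are the
# primitives every pipeline stage leans on, so they are written out from the
# defining formulas; base R equivalents (cor, t.test, aov, p.adjust) are used
# only as independent cross-checks in the test suite.

#' Midranks of a numeric vector
#'
#' Ranks with ties replaced by the average of the positions they occupy
#' (fractional "midranks"). Computed from a single sort pass rather than via
#' [base::rank()] so the Spearman implementation is self-contained.
#'
#' @param x Numeric vector without missing values.
#' @return Numeric vector of midranks, same length as `x`.
#' @keywords internal
midrank <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && xs[j + 1L] == xs[i]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

pearson_cor <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of the two vectors after replacing values by their
#' midranks (average ranks for ties). This is the coexpression measure used
#' throughout gene ranking.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with at
#'   least two distinct values.
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10)) # exactly 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (length(x) < 3) stop_param("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_param("missing values are not allowed")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop_degenerate("correlation undefined for a constant vector")
  }
  pearson_cor(midrank(x), midrank(y))
}

# Vectorised Spearman of every row of `mat` against `y`. Rows constant in
# the given samples yield NA (the caller decides how to treat them).
# Row ranking delegates to base rank() (identical to midrank(), which the
# scalar path uses; the equivalence is covered by tests) for speed.
spearman_rows <- function(mat, y) {
  stopifnot(ncol(mat) == length(y))
  ry <- midrank(y)
  rmat <- t(apply(mat, 1L, rank, ties.method = "average"))
  rc <- rmat - rowMeans(rmat)
  yc <- ry - mean(ry)
  den <- sqrt(rowSums(rc^2) * sum(yc^2))
  out <- as.vector(rc %*% yc) / den
  out[den == 0] <- NA_real_
  names(out) <- rownames(mat)
  out
}

new_test_result <- function(statistic, df, p_value, method, ...) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         method = method, ...),
    class = "sighub_test"
  )
}

#' @export
print.sighub_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic, digits = 5),
      ", df = ", paste(format(x$df, digits = 5), collapse = ", "),
      ", p = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sighub_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df[[1]],
    df2 = if (length(x$df) > 1) x$df[[2]] else NA_real_,
    p.value = x$p_value,
    method = x$method
  )
}

#' Welch's two-sample t-test
#'
#' Unpaired t-test with Welch's correction: unequal variances, with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric vectors with at least two observations each.
#' @return A `sighub_test` with `statistic` (positive when `mean(a) >
#'   mean(b)`), fractional `df`, `p_value`, and per-group means/sizes.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_param("each group needs n >= 2")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop_degenerate("zero variance in both groups")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(stat), df)
  new_test_result(stat, df, p, "Welch two-sample t-test",
                  mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb)
}

#' One-way analysis of variance
#'
#' Ordinary (equal-variance) one-way ANOVA F-test across `k >= 2` groups.
#' When every observation is identical the statistic is 0 with p = 1.
#'
#' @param groups List of numeric vectors, each with at least two values.
#' @return A `sighub_test` with the F `statistic` and `df = c(k - 1, N - k)`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_param("need a list of at least 2 groups")
  }
  if (any(lengths(groups) < 2)) stop_param("each group needs n >= 2")
  k <- length(groups)
  n_i <- lengths(groups)
  N <- sum(n_i)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) {
      return(new_test_result(0, c(df1, df2), 1, "One-way ANOVA"))
    }
    return(new_test_result(Inf, c(df1, df2), 0, "One-way ANOVA"))
  }
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  new_test_result(f, c(df1, df2), p, "One-way ANOVA")
}

check_pvec <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_param("p-values must lie in [0, 1]")
  }
}

#' Holm step-down adjustment
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order, each `>=` its raw value.
#' @export
holm_adjust <- function(p) {
  check_pvec(p)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return q-values (adjusted p) in the input order.
#' @export
bh_adjust <- function(p) {
  check_pvec(p)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, m / (m - seq_len(m) + 1) * p[o])
  adj <- cummin(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise Welch tests with Holm adjustment
#'
#' Post-hoc companion to [one_way_anova()]: every pair of groups is compared
#' by [welch_t()] and the p-values are Holm-adjusted.
#'
#' @param groups Named list of numeric vectors.
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `df`, `p.value`, `p.adjusted`.
#' @export
pairwise_welch <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_param("need a list of at least 2 groups")
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    w <- welch_t(groups[[i1]], groups[[i2]])
    tibble(group1 = nm[i1], group2 = nm[i2],
           statistic = w$statistic, df = w$df, p.value = w$p_value)
  })
  out <- bind_rows(res)
  out$p.adjusted <- holm_adjust(out$p.value)
  out
}
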