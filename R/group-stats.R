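#' Group statistics: ANOVA, LSD post-hoc, FDR, correlations
#'
#' The statistical layer of the severity analysis: classical one-way ANOVA
#' (equal-variance, both from raw observations and from per-group summary
#' statistics, which are sufficient for the one-way decomposition), Fisher's
#' LSD post-hoc pairwise comparisons on the pooled within-group variance,
#' pooled two-sample t tests from summaries, Benjamini-Hochberg FDR control,
#' and Pearson correlations. Equal-variance (pooled) forms are used
#' throughout; Welch variants are deliberately not provided.
#'
#' @name group-stats
NULL

.anova_result <- function(F, df_b, df_w, p, means, sds, ns) {
  structure(list(F = F, df_between = df_b, df_within = df_w, p = p,
                 group_means = means, group_sds = sds, group_ns = ns),
            class = "tbiconn_anova")
}

#' @export
print.tbiconn_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.3f, p = %.3f\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' One-way ANOVA from raw observations
#'
#' Classical equal-variance one-way analysis of variance across `k` groups.
#' The F statistic and p-value are obtained from [stats::oneway.test()] with
#' `var.equal = TRUE`; group summaries are attached to the result.
#'
#' @param groups named list of numeric vectors, one per group.
#' @return a `tbiconn_anova` object: F, df_between (= k-1), df_within
#'   (= N-k), p, and per-group means/sds/ns.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  gm <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0 && ssb == 0)
    stop("undefined F: no variance between or within groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  .anova_result(unname(fit$statistic), length(groups) - 1L,
                sum(ns) - length(groups), unname(fit$p.value),
                means, sds, ns)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Per-group means, standard deviations and sizes are sufficient statistics
#' for the one-way decomposition, so this reproduces `anova_oneway` on the
#' raw data exactly: `SS_between = sum n_g (m_g - m)^2`, `SS_within =
#' sum (n_g - 1) sd_g^2`, `F = MS_between / MS_within` on `(k-1, N-k)`
#' degrees of freedom. This is how printed group-summary tables are
#' re-analyzed when raw data are unavailable.
#'
#' @param means,sds,ns per-group sample means, SDs and sizes.
#' @return a `tbiconn_anova` object.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, length(ns) == k)
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(sds < 0)) stop("standard deviations must be nonnegative")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df_b <- k - 1L
  df_w <- as.integer(N - k)
  msw <- ssw / df_w
  if (msw == 0) stop("undefined F: pooled within-group variance is zero")
  F <- (ssb / df_b) / msw
  p <- stats::pf(F, df_b, df_w, lower.tail = FALSE)
  .anova_result(F, df_b, df_w, p, means, sds, ns)
}

#' Pooled two-sample t test from summary statistics
#'
#' Equal-variance two-sample t on `n1 + n2 - 2` degrees of freedom, two
#' tailed, from group means, SDs and sizes.
#'
#' @param m1,sd1,n1 summary statistics of the first group.
#' @param m2,sd2,n2 summary statistics of the second group.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_two_sample <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (m1 == m2) stop("undefined t: zero pooled variance and equal means")
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0))
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Fisher's LSD post-hoc pairwise comparisons
#'
#' For every pair of groups, `t = (m_a - m_b) / sqrt(MS_within (1/n_a +
#' 1/n_b))` with the ANOVA pooled within-group mean square and its
#' `N - k` degrees of freedom. LSD applies no multiplicity adjustment by
#' construction.
#'
#' @param groups named list of numeric vectors, one per group.
#' @return data.frame: group1, group2, diff, t, df, p.
#' @export
lsd_posthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  df_w <- sum(ns) - length(groups)
  msw <- sum((ns - 1) * vars) / df_w
  if (msw == 0) stop("undefined post-hoc t: pooled within-group variance is zero")
  pairs <- utils::combn(seq_along(groups), 2)
  d <- unname(means[pairs[1, ]] - means[pairs[2, ]])
  t <- d / sqrt(msw * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  t <- unname(t)
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             diff = d, t = t, df = df_w,
             p = 2 * stats::pt(-abs(t), df_w), row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `alpha`: sort the `m` p-values ascending, find
#' the largest `i` with `p_(i) <= (i/m) alpha`, and flag every test with
#' p-value at or below that cutoff. Adjusted q-values are the standard BH
#' adjustment (via [stats::p.adjust()]); a test is flagged exactly when its
#' q-value is at most `alpha`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `p` (input), `q` (BH-adjusted), `significant` (logical
#'   flags), `alpha`, `m`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  q <- stats::p.adjust(pvals, method = "BH")
  # explicit step-up rule (independent of p.adjust, used for the flags)
  o <- order(pvals)
  ok <- which(pvals[o] <= seq_len(m) / m * alpha)
  flags <- if (length(ok)) pvals <= pvals[o][max(ok)] else rep(FALSE, m)
  list(p = pvals, q = q, significant = flags, alpha = alpha, m = m)
}

#' Pearson correlation with two-tailed test
#'
#' Sample Pearson r and the two-tailed p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values are
#'   dropped).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = n)
}
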