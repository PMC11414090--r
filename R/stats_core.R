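#' Per-group trait summaries
#'
#' Computes, for every (group, trait) cell, the number of non-missing
#' values, their mean, and the sample standard deviation (n - 1
#' denominator). Cells with a single observation carry `sd = NA`; cells
#' with no observations are omitted with a warning.
#'
#' @param flat A flat trait data.frame (one column per canonical trait), as
#'   produced by [flatten_traits()] or [generate_traits()].
#' @param by Name of the grouping column (default `"Taxon"`).
#' @param traits Trait columns to summarize (default all 13).
#' @return A data.frame with columns `group`, `trait`, `n`, `mean`, `sd`.
#' @export
summarize_traits <- function(flat, by = "Taxon", traits = trait_names()) {
  stopifnot(by %in% names(flat), all(traits %in% names(flat)))
  groups <- sort(unique(flat[[by]]))
  rows <- list()
  for (g in groups) {
    sub <- flat[flat[[by]] == g, , drop = FALSE]
    for (tr in traits) {
      v <- sub[[tr]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        warning(sprintf("group %s has no values for trait %s; omitted", g, tr))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, trait = tr, n = length(v), mean = mean(v),
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: fetch one (group, trait) summary row as a list
.get_summary <- function(summaries, group, trait) {
  i <- which(summaries$group == group & summaries$trait == trait)
  if (length(i) != 1L) {
    stop("missing summary for group ", group, ", trait ", trait)
  }
  as.list(summaries[i, c("n", "mean", "sd")])
}

.check_summaries <- function(...) {
  for (s in list(...)) {
    if (s$n < 2L) stop("group summaries need n >= 2")
    if (!is.finite(s$sd) || s$sd <= 0) stop("group summaries need sd > 0")
  }
}

.test_result <- function(statistic, df1, df2, p, test, groups = NULL) {
  structure(list(statistic = statistic, df1 = df1, df2 = df2,
                 p_value = p, test_name = test, groups = groups),
            class = "callimorph_test")
}

#' @export
print.callimorph_test <- function(x, ...) {
  dfs <- if (is.null(x$df2) || is.na(x$df2)) sprintf("df = %.4g", x$df1)
         else sprintf("df1 = %.4g, df2 = %.4g", x$df1, x$df2)
  cat(sprintf("%s: statistic = %.6g, %s, p = %.4g\n",
              x$test_name, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' Levene / Brown-Forsythe test for homogeneity of variances
#'
#' One-way ANOVA F on absolute deviations of each observation from its
#' group center. The default center is the group median (Brown-Forsythe
#' variant); mean-centering is available by flag.
#'
#' @param values A list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @param center `"median"` (default) or `"mean"`.
#' @return A test result with the F statistic, df1 = k - 1, df2 = N - k,
#'   and the p-value from the F distribution.
#' @export
levene_test <- function(values, center = c("median", "mean")) {
  center <- match.arg(center)
  values <- lapply(values, function(v) v[!is.na(v)])
  k <- length(values)
  if (k < 2L) stop("need >= 2 groups")
  if (any(vapply(values, length, 1L) < 2L)) stop("each group needs >= 2 values")
  cfun <- if (center == "median") stats::median else mean
  z <- lapply(values, function(v) abs(v - cfun(v)))
  N <- sum(lengths(z))
  zbar <- mean(unlist(z))
  zmeans <- vapply(z, mean, 1)
  ss_between <- sum(lengths(z) * (zmeans - zbar)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(j) sum((z[[j]] - zmeans[j])^2), 1))
  if (ss_within == 0) {
    stop("Levene statistic undefined: all within-group deviations are zero")
  }
  f <- (ss_between / (k - 1)) / (ss_within / (N - k))
  .test_result(f, k - 1, N - k,
               stats::pf(f, k - 1, N - k, lower.tail = FALSE),
               sprintf("Levene (%s-centered)", center))
}

#' Welch's heteroscedastic one-way ANOVA from group summaries
#'
#' Welch (1951) test for equality of k group means under unequal variances,
#' computable from (n, mean, sd) alone. With weights w_j = n_j / s_j^2 and
#' weighted grand mean m_w, the statistic is
#' F* = \[sum w_j (m_j - m_w)^2 / (k-1)\] / \[1 + 2(k-2)/(k^2-1) L\]
#' with L = sum (1 - w_j / sum w)^2 / (n_j - 1), df1 = k - 1, and
#' df2 = (k^2 - 1) / (3 L).
#'
#' @param summaries A summary data.frame (columns `group`, `n`, `mean`,
#'   `sd`) for a single trait; every group needs n >= 2 and sd > 0.
#' @return A test result with F*, df1, df2 and the F-distribution p-value.
#' @export
welch_anova <- function(summaries) {
  k <- nrow(summaries)
  if (k < 2L) stop("need >= 2 groups")
  if (any(summaries$n < 2L)) stop("each group needs n >= 2")
  if (any(!is.finite(summaries$sd) | summaries$sd <= 0)) {
    stop("weights undefined: every group needs sd > 0")
  }
  w <- summaries$n / summaries$sd^2
  sw <- sum(w)
  mw <- sum(w * summaries$mean) / sw
  lambda <- sum((1 - w / sw)^2 / (summaries$n - 1))
  num <- sum(w * (summaries$mean - mw)^2) / (k - 1)
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f <- num / den
  df2 <- (k^2 - 1) / (3 * lambda)
  .test_result(f, k - 1, df2, stats::pf(f, k - 1, df2, lower.tail = FALSE),
               "Welch one-way ANOVA", groups = summaries$group)
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' For every unordered pair of groups, a Welch-type pairwise statistic
#' t = |m_i - m_j| / se with se^2 = s_i^2/n_i + s_j^2/n_j and
#' Welch-Satterthwaite degrees of freedom, calibrated against the
#' studentized range distribution with k groups: the adjusted p-value is
#' P(Q_{k,df} >= t sqrt(2)). Confidence bounds use the corresponding
#' studentized-range quantile. This studentized-range calibration is the
#' Tukey-method adjustment intrinsic to the test; no further correction is
#' applied.
#'
#' @param summaries Summary data.frame (columns `group`, `n`, `mean`, `sd`)
#'   for one trait.
#' @param conf_level Confidence level for the mean-difference bounds.
#' @return A data.frame with one row per pair: `group1`, `group2`,
#'   `estimate` (m1 - m2), `conf_low`, `conf_high`, `statistic`, `df`,
#'   `p_adj`, and significance code (`*` < 0.05, `**` < 0.01, `***` < 0.001).
#' @export
games_howell <- function(summaries, conf_level = 0.95) {
  k <- nrow(summaries)
  if (k < 2L) stop("need >= 2 groups")
  if (any(summaries$n < 2L) ||
      any(!is.finite(summaries$sd) | summaries$sd <= 0)) {
    stop("each group needs n >= 2 and sd > 0")
  }
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    a <- summaries[i, ]; b <- summaries[j, ]
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    tstat <- abs(a$mean - b$mean) / se
    p <- stats::ptukey(tstat * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    q <- stats::qtukey(conf_level, nmeans = k, df = df)
    est <- a$mean - b$mean
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = a$group, group2 = b$group, estimate = est,
      conf_low = est - q / sqrt(2) * se, conf_high = est + q / sqrt(2) * se,
      statistic = tstat, df = df, p_adj = p,
      signif = significance_code(p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Significance star codes
#'
#' @param p Numeric vector of p-values.
#' @return `"***"` for p < 0.001, `"**"` < 0.01, `"*"` < 0.05, else `""`.
#' @export
significance_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' One-sample t-test from a group summary
#'
#' t = (mean - mu0) sqrt(n) / sd on n - 1 degrees of freedom, two-sided.
#' Used to contrast a hybrid group's trait mean against its mid-parent
#' value.
#'
#' @param summary A list or one-row data.frame with `n`, `mean`, `sd`.
#' @param mu0 The null value.
#' @return A test result.
#' @export
one_sample_t <- function(summary, mu0) {
  s <- as.list(summary)
  .check_summaries(s)
  t <- (s$mean - mu0) * sqrt(s$n) / s$sd
  df <- s$n - 1
  .test_result(t, df, NA_real_, 2 * stats::pt(abs(t), df, lower.tail = FALSE),
               "one-sample t")
}

#' Welch two-sample t-test from group summaries
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided; accounts for unbalanced sizes and heterogeneous
#' variances.
#'
#' @param a,b Lists or one-row data.frames with `n`, `mean`, `sd`.
#' @return A test result.
#' @export
welch_t <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  .check_summaries(a, b)
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  .test_result(t, df, NA_real_, 2 * stats::pt(abs(t), df, lower.tail = FALSE),
               "Welch two-sample t")
}

#' Pillai-trace MANOVA screen
#'
#' One-way MANOVA on listwise-complete rows. Pillai's trace is
#' V = trace(H (H + E)^{-1}) with H and E the between- and within-group
#' SSCP matrices. The approximate F uses the standard transformation: with
#' p responses, k groups, N rows, s = min(p, k - 1),
#' m = (|p - k + 1| - 1)/2, n' = (N - k - p - 1)/2,
#' F = \[(2n' + s + 1) / (2m + s + 1)\] V / (s - V) on
#' df1 = s(2m + s + 1) and df2 = s(2n' + s + 1).
#'
#' @param matrix Numeric matrix or data.frame of responses (rows with any
#'   missing value are dropped).
#' @param groups Group labels, one per row.
#' @return A test result carrying the approximate F (`statistic`), df pair,
#'   p-value, and the trace itself in `$pillai`.
#' @export
manova_pillai <- function(matrix, groups) {
  X <- as.matrix(matrix)
  groups <- as.character(groups)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  groups <- groups[keep]
  p <- ncol(X)
  N <- nrow(X)
  levels <- unique(groups)
  k <- length(levels)
  if (k < 2L) stop("need >= 2 groups with complete rows")
  if (N <= p + k) stop("need more complete rows than traits plus groups")
  grand <- colMeans(X)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (g in levels) {
    Xg <- X[groups == g, , drop = FALSE]
    mg <- colMeans(Xg)
    H <- H + nrow(Xg) * tcrossprod(mg - grand)
    Xc <- sweep(Xg, 2, mg)
    E <- E + crossprod(Xc)
  }
  T <- H + E
  if (rcond(T) < .Machine$double.eps * 1e3) {
    stop("singular SSCP matrix; remove collinear traits or tiny groups")
  }
  V <- sum(diag(H %*% solve(T)))
  s <- min(p, k - 1)
  m <- (abs(p - k + 1) - 1) / 2
  nprime <- (N - k - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nprime + s + 1)
  f <- (2 * nprime + s + 1) / (2 * m + s + 1) * V / (s - V)
  res <- .test_result(f, df1, df2,
                      stats::pf(f, df1, df2, lower.tail = FALSE),
                      "MANOVA (Pillai)", groups = levels)
  res$pillai <- V
  res$n_used <- N
  res
}

#' Univariate screening across all traits
#'
#' Runs, per trait, the Levene homogeneity check, Welch's one-way ANOVA,
#' and Games-Howell post-hoc comparisons over all taxa — the standard
#' heterogeneous-variance screen for per-taxon trait differences.
#'
#' @param flat Flat trait data.frame.
#' @param by Grouping column (default `"Taxon"`).
#' @param traits Traits to screen.
#' @return A list with `anova` (one row per trait: Welch F, df1, df2, p)
#'   and `posthoc` (one row per trait and pair, Games-Howell).
#' @export
screen_traits <- function(flat, by = "Taxon", traits = trait_names()) {
  summ <- summarize_traits(flat, by = by, traits = traits)
  anova_rows <- list(); posthoc_rows <- list()
  for (tr in traits) {
    s <- summ[summ$trait == tr & summ$n >= 2 & is.finite(summ$sd) &
                summ$sd > 0, , drop = FALSE]
    if (nrow(s) < 2L) next
    vals <- lapply(s$group, function(g) {
      v <- flat[flat[[by]] == g, tr]; v[!is.na(v)]
    })
    lev <- levene_test(vals)
    wa <- welch_anova(s)
    anova_rows[[tr]] <- data.frame(
      trait = tr, levene_W = lev$statistic, levene_p = lev$p_value,
      welch_F = wa$statistic, df1 = wa$df1, df2 = wa$df2, p = wa$p_value,
      signif = significance_code(wa$p_value), stringsAsFactors = FALSE)
    gh <- games_howell(s)
    gh <- cbind(trait = tr, gh, stringsAsFactors = FALSE)
    posthoc_rows[[tr]] <- gh
  }
  list(anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
       posthoc = do.call(rbind, c(posthoc_rows, list(make.row.names = FALSE))),
       summaries = summ)
}
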