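test_that("summarize_traits: n over non-missing values, sample SD, degenerate cells", {
  flat <- data.frame(Taxon = c("a", "a", "b", "b", "b"),
                     X = c(2, 4, 5, NA, NA), Y = c(1, 2, 3, 4, 5))
  s <- summarize_traits(flat, traits = c("X", "Y"))
  a_x <- s[s$group == "a" & s$trait == "X", ]
  expect_equal(a_x$n, 2L)
  expect_equal(a_x$mean, 3)
  expect_equal(a_x$sd, sqrt(2))
  b_x <- s[s$group == "b" & s$trait == "X", ]
  expect_equal(b_x$n, 1L)           # single value: sd undefined, flagged NA
  expect_true(is.na(b_x$sd))
  flat$Z <- c(NA, NA, 1, 2, 3)      # empty cell -> omitted with warning
  expect_warning(s2 <- summarize_traits(flat, traits = "Z"), "no values")
  expect_equal(nrow(s2), 1L)
})

test_that("generator recovers stated group parameters within sampling error", {
  # C. jacchus BODY is generated at mean 19.9, sd 1.6 (published magnitudes)
  sc <- synthetic_scenario(group_sizes = c(J = 29L, P = 52L), seed = 99)
  s <- summarize_traits(flatten_traits(generate_traits(sc)))
  j <- s[s$group == "J" & s$trait == "BODY", ]
  expect_lt(abs(j$mean - 19.9), 3 * 1.6 / sqrt(29))
})

test_that("Levene/Brown-Forsythe equals a brute-force ANOVA on deviations", {
  # center = mean: deviations computable by hand
  lv <- levene_test(list(c(1, 2, 3), c(10, 20, 30)), center = "mean")
  z <- c(abs(c(1, 2, 3) - 2), abs(c(10, 20, 30) - 20))
  oracle <- stats::anova(stats::lm(z ~ factor(rep(1:2, each = 3))))
  expect_equal(lv$statistic, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(lv$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(lv$df1, 1); expect_equal(lv$df2, 4)
  # identical multisets across groups -> zero statistic
  same <- levene_test(list(c(1, 5, 9), c(9, 1, 5)))
  expect_equal(same$statistic, 0)
  # scale invariance of F
  set.seed(1)
  g <- list(rnorm(8), rnorm(11, sd = 2), rnorm(9))
  f1 <- levene_test(g)$statistic
  f2 <- levene_test(lapply(g, function(v) 7.3 * v))$statistic
  expect_equal(f1, f2, tolerance = 1e-12)
  # all-constant group with median centering is undefined
  expect_error(levene_test(list(c(2, 2, 2), c(3, 3, 3))), "undefined")
})

test_that("Welch ANOVA matches its written formula and the k=2 identity", {
  s3 <- data.frame(group = c("a", "b", "c"), n = c(10, 10, 10),
                   mean = c(0, 0.5, 1), sd = c(1, 1, 2))
  wa <- welch_anova(s3)
  # brute-force, term by term
  w <- s3$n / s3$sd^2
  mw <- sum(w * s3$mean) / sum(w)
  lam <- sum((1 - w / sum(w))^2 / (s3$n - 1))
  f <- (sum(w * (s3$mean - mw)^2) / 2) / (1 + 2 * (3 - 2) / (9 - 1) * lam)
  expect_equal(wa$statistic, f, tolerance = 1e-12)
  expect_equal(wa$df2, 8 / (3 * lam), tolerance = 1e-12)
  expect_equal(wa$p_value, pf(f, 2, 8 / (3 * lam), lower.tail = FALSE))
  # against the ecosystem oracle on raw data
  set.seed(2)
  y <- c(rnorm(12), rnorm(9, 1, 2), rnorm(15, 0.3, 0.5))
  g <- rep(c("a", "b", "c"), c(12, 9, 15))
  su <- summarize_traits(data.frame(Taxon = g, Y = y), traits = "Y")
  wa2 <- welch_anova(su)
  or <- stats::oneway.test(y ~ factor(g), var.equal = FALSE)
  expect_equal(wa2$statistic, unname(or$statistic), tolerance = 1e-10)
  expect_equal(wa2$p_value, or$p.value, tolerance = 1e-10)
  # k = 2: F* is the squared Welch t and df2 the Welch-Satterthwaite df
  s2 <- su[1:2, ]
  wt <- welch_t(s2[1, ], s2[2, ])
  wa3 <- welch_anova(s2)
  expect_equal(wa3$statistic, wt$statistic^2, tolerance = 1e-10)
  expect_equal(wa3$df2, wt$df1, tolerance = 1e-10)
  # equal means -> F = 0, p = 1
  eq <- welch_anova(data.frame(group = c("a", "b"), n = 5, mean = 2, sd = 1:2))
  expect_equal(eq$statistic, 0); expect_equal(eq$p_value, 1)
  # sd = 0 is an error
  expect_error(welch_anova(data.frame(group = c("a", "b"), n = 5,
                                      mean = 1:2, sd = c(0, 1))), "sd > 0")
})

test_that("Games-Howell: studentized-range calibration, bounds, monotonicity", {
  s <- data.frame(group = c("a", "b", "c"), n = c(8, 14, 10),
                  mean = c(1, 1, 3), sd = c(1, 2, 1.5))
  gh <- games_howell(s)
  expect_equal(nrow(gh), 3L)
  expect_true(all(gh$p_adj >= 0 & gh$p_adj <= 1))
  # equal means -> t = 0, adjusted p = 1
  ab <- gh[gh$group1 == "a" & gh$group2 == "b", ]
  expect_equal(ab$statistic, 0); expect_equal(ab$p_adj, 1)
  # CI bounds bracket the estimate symmetrically
  expect_equal(gh$estimate - gh$conf_low, gh$conf_high - gh$estimate,
               tolerance = 1e-12)
  # p decreases strictly as |mean difference| grows, everything else fixed
  deltas <- c(0.5, 1, 1.5, 2.5)
  ps <- vapply(deltas, function(d) {
    si <- data.frame(group = c("a", "b", "c"), n = 10,
                     mean = c(0, d, 5), sd = 1)
    games_howell(si)$p_adj[1]
  }, 1)
  expect_true(all(diff(ps) < 0))
  # k = 2: significance decision agrees with the Welch two-sample test
  for (d in c(0.2, 1.2, 3)) {
    s2 <- data.frame(group = c("a", "b"), n = c(9, 17),
                     mean = c(0, d), sd = c(1, 2))
    p_gh <- games_howell(s2)$p_adj
    p_w <- welch_t(s2[1, ], s2[2, ])$p_value
    expect_equal(p_gh < 0.05, p_w < 0.05)
  }
})

test_that("one-sample t from summaries: closed form, scaling, boundary", {
  expect_equal(one_sample_t(list(n = 10, mean = 4, sd = 2), 4)$p_value, 1)
  # the hybrid-vs-MPV worked example: n=54, mean=21.3, sd=2.7 vs 20.4
  r <- one_sample_t(list(n = 54, mean = 21.3, sd = 2.7), 20.4)
  expect_equal(r$statistic, 0.9 * sqrt(54) / 2.7, tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), 2.449)
  expect_equal(round(r$p_value, 3), 0.018)
  expect_lt(r$p_value, 0.05)
  # doubling n multiplies t by sqrt(2)
  r2 <- one_sample_t(list(n = 108, mean = 21.3, sd = 2.7), 20.4)
  expect_equal(r2$statistic, r$statistic * sqrt(2), tolerance = 1e-12)
  # matches the ecosystem oracle on raw data
  set.seed(3); y <- rnorm(20, 1)
  mine <- one_sample_t(list(n = 20, mean = mean(y), sd = sd(y)), 0.5)
  or <- stats::t.test(y, mu = 0.5)
  expect_equal(mine$p_value, or$p.value, tolerance = 1e-12)
  expect_error(one_sample_t(list(n = 5, mean = 1, sd = 0), 0), "sd > 0")
})

test_that("Welch two-sample t from summaries: identities and oracle", {
  a <- list(n = 12, mean = 3, sd = 1.5)
  expect_equal(welch_t(a, a)$statistic, 0)
  expect_equal(welch_t(a, a)$p_value, 1)
  # equal variances and n: df reduces to 2n - 2 exactly
  b <- list(n = 12, mean = 5, sd = 1.5)
  expect_equal(welch_t(a, b)$df1, 22, tolerance = 1e-12)
  # the aurita-hybrid HAND contrast is significant at 0.05
  r <- welch_t(list(n = 9, mean = 39.0, sd = 3.7),
               list(n = 21, mean = 30.5, sd = 15.1))
  expect_lt(r$p_value, 0.05)
  # oracle
  set.seed(4); x <- rnorm(14, 1, 2); y <- rnorm(23, 0, 1)
  mine <- welch_t(list(n = 14, mean = mean(x), sd = sd(x)),
                  list(n = 23, mean = mean(y), sd = sd(y)))
  or <- stats::t.test(x, y)
  expect_equal(mine$statistic, unname(or$statistic), tolerance = 1e-12)
  expect_equal(mine$df1, unname(or$parameter), tolerance = 1e-12)
  expect_equal(mine$p_value, or$p.value, tolerance = 1e-12)
})

test_that("Pillai MANOVA: oracle equality, reductions, df structure", {
  set.seed(5)
  X <- cbind(rnorm(60, rep(c(0, 1, 0.5), each = 20)), rnorm(60), rnorm(60))
  g <- rep(c("a", "b", "c"), each = 20)
  mine <- manova_pillai(X, g)
  or <- summary(stats::manova(X ~ factor(g)), test = "Pillai")$stats
  expect_equal(mine$pillai, unname(or[1, "Pillai"]), tolerance = 1e-10)
  expect_equal(mine$statistic, unname(or[1, "approx F"]), tolerance = 1e-10)
  expect_equal(mine$df1, unname(or[1, "num Df"]))
  expect_equal(mine$df2, unname(or[1, "den Df"]))
  expect_equal(mine$p_value, unname(or[1, "Pr(>F)"]), tolerance = 1e-10)
  # brute-force eigen identity: V = sum of eigenvalues of H (H+E)^-1
  # (recompute H, E independently per group)
  Xs <- scale(X, scale = FALSE)
  H <- Reduce(`+`, lapply(unique(g), function(l) {
    nrow(X[g == l, ]) * tcrossprod(colMeans(X[g == l, ]) - colMeans(X))
  }))
  E <- Reduce(`+`, lapply(unique(g), function(l) {
    crossprod(scale(X[g == l, ], scale = FALSE))
  }))
  expect_equal(mine$pillai, sum(eigen(H %*% solve(H + E))$values),
               tolerance = 1e-10)
  # duplicated data across two labels: V ~ 0, p ~ 1
  dup <- manova_pillai(rbind(X[1:20, ], X[1:20, ]),
                       rep(c("u", "v"), each = 20))
  expect_lt(dup$pillai, 1e-20)
  expect_gt(dup$p_value, 0.999)
  # one response: approximate F equals the classic one-way ANOVA F
  uni <- manova_pillai(X[, 1, drop = FALSE], g)
  or1 <- stats::anova(stats::lm(X[, 1] ~ factor(g)))
  expect_equal(uni$statistic, or1$`F value`[1], tolerance = 1e-10)
  # 13 traits x 8 groups reproduces the published df1 = 91 structure
  sc <- synthetic_scenario(seed = 6)
  flat <- flatten_traits(generate_traits(sc))
  man <- manova_pillai(flat[, trait_names()], flat$Taxon)
  expect_equal(man$df1, 91)
})

test_that("tests are invariant to group order and p-values stay in [0,1]", {
  set.seed(6)
  s <- data.frame(group = c("a", "b", "c"), n = c(7, 12, 20),
                  mean = c(0.3, -1, 2), sd = c(1, 3, 0.4))
  perm <- s[c(3, 1, 2), ]
  expect_equal(welch_anova(s)$statistic, welch_anova(perm)$statistic,
               tolerance = 1e-12)
  gh1 <- games_howell(s); gh2 <- games_howell(perm)
  key <- function(d) {
    k <- apply(cbind(d$group1, d$group2), 1, function(r) paste(sort(r),
                                                               collapse = "_"))
    d$p_adj[order(k)]
  }
  expect_equal(key(gh1), key(gh2), tolerance = 1e-12)
  for (p in c(welch_anova(s)$p_value, gh1$p_adj)) {
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("screen_traits emits one ANOVA row per trait and all pairwise rows", {
  sc <- synthetic_scenario(group_sizes = c(A = 20L, J = 20L, P = 20L),
                           seed = 10)
  flat <- flatten_traits(generate_traits(sc))
  sc_res <- screen_traits(flat)
  expect_equal(nrow(sc_res$anova), 13L)
  expect_equal(nrow(sc_res$posthoc), 13L * 3L)
  expect_true(all(sc_res$posthoc$p_adj >= 0 & sc_res$posthoc$p_adj <= 1))
})
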