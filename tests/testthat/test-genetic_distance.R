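test_that("grouped FASTA reading: grouping, validation, round trip", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGTACGT", ">s2", "ACGTACGA"), fa)
  aln <- read_grouped_fasta(fa, c(s1 = "g1", s2 = "g2"))
  expect_s3_class(aln, "grouped_alignment")
  expect_equal(unname(aln$groups), c("g1", "g2"))
  expect_equal(aln$sequences$s1, strsplit("ACGTACGT", "")[[1]])
  # unmapped id errors by name
  expect_error(read_grouped_fasta(fa, c(s1 = "g1")), "s2")
  # unequal lengths refuse (no aligning here)
  writeLines(c(">s1", "ACGTACGT", ">s2", "ACGT"), fa)
  expect_error(read_grouped_fasta(fa, c(s1 = "g1", s2 = "g2")), "unequal")
  # simulator fixture round-trips residues exactly through FASTA
  aln2 <- generate_sequences(c(a = 0.02, b = 0.05, c = 0.01, d = 0.03),
                             tn93_test_params(), length = 300,
                             n_per_group = 2, seed = 31)
  fa2 <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_grouped_fasta(aln2, fa2, tsv)
  back <- read_grouped_fasta(fa2, tsv)
  expect_equal(back$sequences, aln2$sequences)
  expect_equal(back$groups, aln2$groups)
})

test_that("site-pattern counts under pairwise deletion", {
  a <- strsplit("ACGTT", "")[[1]]
  b <- strsplit("ACGAN", "")[[1]]
  pc <- pairwise_site_pattern_counts(a, b)
  expect_equal(pc$retained, 4L)            # the N site is deleted
  expect_equal(sum(diag(pc$counts)), 3L)
  expect_equal(pc$counts["T", "A"], 1L)    # the single mismatch
  # identical ungapped sequences: diagonal sums to L
  s <- strsplit("ACGTACGTAC", "")[[1]]
  pc2 <- pairwise_site_pattern_counts(s, s)
  expect_equal(sum(diag(pc2$counts)), 10L)
  expect_equal(sum(pc2$counts) - sum(diag(pc2$counts)), 0L)
  # random pair equals a brute-force per-site loop
  set.seed(32)
  alph <- c("A", "C", "G", "T", "-", "N")
  x <- sample(alph, 500, replace = TRUE, prob = c(rep(0.23, 4), 0.04, 0.04))
  y <- sample(alph, 500, replace = TRUE, prob = c(rep(0.23, 4), 0.04, 0.04))
  pc3 <- pairwise_site_pattern_counts(x, y)
  brute <- matrix(0L, 4, 4, dimnames = dimnames(pc3$counts))
  kept <- 0L
  for (i in seq_along(x)) {
    if (x[i] %in% c("A", "C", "G", "T") && y[i] %in% c("A", "C", "G", "T")) {
      kept <- kept + 1L
      brute[x[i], y[i]] <- brute[x[i], y[i]] + 1L
    }
  }
  expect_equal(pc3$counts, brute)
  expect_equal(pc3$retained, kept)
  # all-missing overlap errors
  expect_error(pairwise_site_pattern_counts(c("A", "N"), c("-", "C")),
               "zero retained")
})

test_that("TN93 distance: zero, Jukes-Cantor limit, saturation flag", {
  params_jc <- list(base_freqs = c(A = .25, C = .25, G = .25, T = .25),
                    kappa1 = 1, kappa2 = 1)
  s <- strsplit("ACGTACGTACGTACGT", "")[[1]]
  pc <- pairwise_site_pattern_counts(s, s)
  expect_equal(pairwise_distance(pc, params_jc), 0)
  # equal frequencies + equal pattern-class proportions: JC closed form
  for (p in c(0.03, 0.12, 0.4)) {
    L <- 1.2e6
    cm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
    cm["A", "G"] <- cm["C", "T"] <- L * p / 6
    cm["A", "C"] <- cm["A", "T"] <- cm["G", "C"] <- cm["G", "T"] <- L * p / 6
    diag(cm) <- c(L * (1 - p), 0, 0, 0)
    d <- pairwise_distance(list(counts = cm, retained = L), params_jc)
    expect_equal(d, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-9)
  }
  # saturated pair flagged as NA
  cm <- matrix(1e4, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  d <- pairwise_distance(list(counts = cm, retained = sum(cm)), params_jc)
  expect_true(is.na(d))
  expect_true(attr(d, "saturated"))
})

test_that("simulated pair at distance 0.06 is recovered within 3 bootstrap SE", {
  params <- tn93_test_params()
  aln <- generate_sequences(c(x = 0.03, y = 0.03), params, length = 20000,
                            n_per_group = 1, seed = 33)
  est_params <- estimate_mcl_params(aln)
  pc <- pairwise_site_pattern_counts(aln$sequences[[1]], aln$sequences[[2]])
  d <- pairwise_distance(pc, est_params)
  # site-resampling bootstrap SE from the multinomial pattern counts
  set.seed(34)
  probs <- as.vector(pc$counts) / pc$retained
  boot <- replicate(200, {
    cm <- matrix(stats::rmultinom(1, pc$retained, probs), 4, 4,
                 dimnames = dimnames(pc$counts))
    pairwise_distance(list(counts = cm, retained = pc$retained), est_params)
  })
  se <- stats::sd(boot, na.rm = TRUE)
  expect_lt(abs(d - 0.06), 3 * se)
})

test_that("composite-likelihood estimation recovers the rate ratios", {
  params <- tn93_test_params()   # kappa1 = 4, kappa2 = 8
  aln <- generate_sequences(c(g1 = .01, g2 = .02, g3 = .03, g4 = .04),
                            params, length = 20000, n_per_group = 4,
                            tip_length = 0.002, seed = 35)
  est <- estimate_mcl_params(aln)   # 16 sequences x 20 kb
  expect_true(est$converged)
  expect_lt(abs(est$kappa1 - 4) / 4, 0.15)
  expect_lt(abs(est$kappa2 - 8) / 8, 0.15)
  expect_equal(sum(est$base_freqs), 1, tolerance = 1e-12)
})

test_that("identical sequences make the rate ratios unidentifiable", {
  s <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  aln <- grouped_alignment(list(a = s, b = s), c(a = "g1", b = "g2"))
  expect_warning(est <- estimate_mcl_params(aln), "unidentifiable")
  expect_equal(est$kappa1, 1)
  expect_equal(est$kappa2, 1)
  expect_false(est$identifiable)
})

test_that("unit-kappa equal-frequency simulation is consistent with JC", {
  params <- list(base_freqs = c(A = .25, C = .25, G = .25, T = .25),
                 kappa1 = 1, kappa2 = 1)
  aln <- generate_sequences(c(x = 0.05, y = 0.05), params, length = 20000,
                            n_per_group = 2, tip_length = 0.01, seed = 36)
  est <- estimate_mcl_params(aln)
  expect_lt(abs(log(est$kappa1)), log(1.6))
  expect_lt(abs(log(est$kappa2)), log(1.6))
})

test_that("between-group means: singletons, duplicated labels, invariances", {
  params <- tn93_test_params()
  aln <- generate_sequences(c(u = 0.02, v = 0.04), params, length = 8000,
                            n_per_group = 1, seed = 37)
  bg <- between_group_means(aln, params)
  d <- pairwise_distance(
    pairwise_site_pattern_counts(aln$sequences[[1]], aln$sequences[[2]]),
    params)
  # two singleton groups: the entry is that single pairwise distance
  expect_equal(bg$values["u", "v"], d)
  expect_equal(bg$values, t(bg$values))
  expect_equal(unname(diag(bg$values)), c(0, 0))
  # a set duplicated under two labels: between-label mean equals the
  # brute-force mean over all cross pairs
  aln2 <- generate_sequences(c(g = 0.02), params, length = 4000,
                             n_per_group = 3, tip_length = 0.01, seed = 38)
  seqs <- aln2$sequences
  both <- grouped_alignment(
    stats::setNames(c(seqs, seqs), c("a1", "a2", "a3", "b1", "b2", "b3")),
    c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B"))
  bg2 <- between_group_means(both, params)
  brute <- mean(vapply(1:3, function(i) vapply(1:3, function(j) {
    pairwise_distance(pairwise_site_pattern_counts(seqs[[i]], seqs[[j]]),
                      params)
  }, 1), rep(1, 3)))
  expect_equal(bg2$values["A", "B"], brute, tolerance = 1e-12)
  expect_equal(bg2$n_pairs["A", "B"], 9L)
  # pairwise deletion: adding an all-N sequence changes no other entry
  with_n <- grouped_alignment(
    c(aln$sequences, list(nn = rep("N", 8000))),
    c(u_01 = "u", v_01 = "v", nn = "u"))
  expect_warning(bg3 <- between_group_means(with_n, params), "saturated|zero")
  expect_equal(bg3$values["u", "v"], bg$values["u", "v"])
})

test_that("star-tree simulation recovers the configured group distances", {
  params <- tn93_test_params()
  bl <- c(A = 0.030, B = 0.030, C = 0.009, D = 0.005)
  aln <- generate_sequences(bl, params, length = 20000, n_per_group = 2,
                            seed = 39)
  bg <- between_group_means(aln)
  truth <- attr(aln, "truth")$distances
  expect_equal(truth["C", "D"], 0.014)  # the smallest published magnitude
  for (i in rownames(truth)) for (j in colnames(truth)) {
    if (i < j) expect_lt(abs(bg$values[i, j] - truth[i, j]),
                         0.15 * truth[i, j] + 0.002)
  }
})
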