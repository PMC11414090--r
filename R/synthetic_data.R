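#' Define a synthetic morphometrics scenario
#'
#' A scenario states the generative world for the trait simulator: per-taxon
#' per-trait means and SDs for the parental species, a regime for each
#' hybrid group, group sizes, an exchangeable between-trait correlation, a
#' missing-cell rate, and a seed. The defaults mirror the reference study's
#' scale: the four species parameterized by the published summary table,
#' the three analysed hybrid classes (plus the two-animal CC class)
#' generated additively, and the published per-taxon sample sizes (209
#' individuals over 8 taxa).
#'
#' @param parental_specs Data.frame with columns `group`, `trait`, `mean`,
#'   `sd` for every parental taxon (default: the published species
#'   summaries).
#' @param hybrid_specs Named list: hybrid code -> list with `parents`
#'   (two parental codes), `regime` (one of `"additive"`, `"heterotic"`,
#'   `"dysgenetic"`, `"transgressive"`, `"parent1_like"`,
#'   `"parent2_like"`), and `effect_size` (in pooled-SD units; pooled SD =
#'   mean of the two parental SDs for that trait).
#' @param group_sizes Named integer vector of per-taxon sample sizes.
#' @param missing_rate Probability that any one measured cell is masked as
#'   missing (default 0).
#' @param trait_correlation Exchangeable between-trait correlation rho in
#'   \[0, 1) (default 0.5).
#' @param adult_fraction Fraction of generated animals flagged adult
#'   (default 1; the remainder are juveniles, for exercising the adult
#'   filter).
#' @param bilateral_jitter SD of the symmetric left/right measurement
#'   jitter, as a fraction of the trait SD (default 0.02). Left and right
#'   are emitted as value +/- jitter so their average is exact.
#' @param traits Traits to generate (default all 13).
#' @param seed Integer seed; the generator is bit-reproducible from it.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(parental_specs = NULL, hybrid_specs = NULL,
                               group_sizes = NULL, missing_rate = 0,
                               trait_correlation = 0.5, adult_fraction = 1,
                               bilateral_jitter = 0.02,
                               traits = trait_names(), seed = 1L) {
  if (is.null(parental_specs)) {
    ref <- reference_species_summaries()
    parental_specs <- ref[, c("group", "trait", "mean", "sd")]
  }
  if (is.null(hybrid_specs)) {
    hybrid_specs <- list(
      PJ = list(parents = c("J", "P"), regime = "additive", effect_size = 0),
      PG = list(parents = c("G", "P"), regime = "additive", effect_size = 0),
      AH = list(parents = c("A", "J"), regime = "additive", effect_size = 0),
      CC = list(parents = c("G", "J"), regime = "additive", effect_size = 0))
  }
  if (is.null(group_sizes)) group_sizes <- reference_group_sizes()
  group_sizes <- unlist(group_sizes)   # JSON configs deliver named lists
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be named by taxon code")
  }
  stopifnot(missing_rate >= 0, missing_rate < 1,
            adult_fraction > 0, adult_fraction <= 1)
  p <- length(traits)
  if (trait_correlation < 0 || trait_correlation >= 1 ||
      (p > 1 && trait_correlation <= -1 / (p - 1))) {
    stop("trait_correlation does not define a valid correlation structure")
  }
  for (h in names(hybrid_specs)) {
    hs <- hybrid_specs[[h]]
    stopifnot(length(hs$parents) == 2L,
              hs$regime %in% c("additive", "heterotic", "dysgenetic",
                               "transgressive", "parent1_like",
                               "parent2_like"),
              hs$effect_size >= 0)
    if (!all(hs$parents %in% parental_specs$group)) {
      stop("hybrid ", h, " names unknown parent(s)")
    }
  }
  if (any(group_sizes < 2L)) stop("group sizes must be >= 2")
  structure(list(parental_specs = parental_specs,
                 hybrid_specs = hybrid_specs, group_sizes = group_sizes,
                 missing_rate = missing_rate,
                 trait_correlation = trait_correlation,
                 adult_fraction = adult_fraction,
                 bilateral_jitter = bilateral_jitter,
                 traits = traits, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# true (mean, sd) per group x trait implied by a scenario
.scenario_truth <- function(scenario) {
  specs <- scenario$parental_specs
  truth <- specs
  for (h in names(scenario$hybrid_specs)) {
    hs <- scenario$hybrid_specs[[h]]
    p1 <- specs[specs$group == hs$parents[1], ]
    p2 <- specs[specs$group == hs$parents[2], ]
    p2 <- p2[match(p1$trait, p2$trait), ]
    pooled_sd <- (p1$sd + p2$sd) / 2
    mpv <- 0.5 * (p1$mean + p2$mean)
    mu <- switch(hs$regime,
      additive = mpv,
      heterotic = mpv + hs$effect_size * pooled_sd,
      dysgenetic = mpv - hs$effect_size * pooled_sd,
      transgressive = pmax(p1$mean, p2$mean) + hs$effect_size * pooled_sd,
      parent1_like = p1$mean,
      parent2_like = p2$mean)
    truth <- rbind(truth, data.frame(group = h, trait = p1$trait,
                                     mean = mu, sd = pooled_sd,
                                     stringsAsFactors = FALSE))
  }
  truth
}

#' Generate a synthetic trait table with known ground truth
#'
#' Draws each animal's 13-trait vector from a multivariate normal with the
#' scenario's per-taxon means and SDs and an exchangeable between-trait
#' correlation. Hybrid group means follow the declared regime relative to
#' the mid-parent value (see [synthetic_scenario()]); hybrid SDs are the
#' pooled (mean) parental SDs. Bilateral traits are emitted as left/right
#' pairs with symmetric jitter, missing cells are masked at the scenario
#' rate, and a fraction of animals can be flagged juvenile. The output is
#' a `trait_table` in the exact raw CSV layout of [read_trait_table()], so
#' generated data flow through the real pipeline unchanged; the generative
#' truth (true means/SDs, regimes, adult count) is attached as attribute
#' `"truth"` for use as a test oracle.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A `trait_table` with attribute `truth`.
#' @export
generate_traits <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  traits <- scenario$traits
  p <- length(traits)
  rho <- scenario$trait_correlation
  truth <- .scenario_truth(scenario)
  groups <- names(scenario$group_sizes)
  unknown <- setdiff(groups, unique(truth$group))
  if (length(unknown) > 0L) {
    stop("group size given for taxon without a spec: ",
         paste(unknown, collapse = ", "))
  }
  rows <- list()
  idn <- 0L
  for (g in groups) {
    n <- scenario$group_sizes[[g]]
    tg <- truth[truth$group == g, ]
    tg <- tg[match(traits, tg$trait), ]
    # exchangeable correlation: shared factor + independent residual
    z_shared <- stats::rnorm(n)
    Z <- sqrt(rho) * matrix(z_shared, n, p) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
    X <- sweep(sweep(Z, 2, tg$sd, "*"), 2, tg$mean, "+")
    colnames(X) <- traits
    n_adult <- round(scenario$adult_fraction * n)
    df <- data.frame(Individual = sprintf("SIM%04d", idn + seq_len(n)),
                     Taxon = g,
                     Sex = sample(c("M", "F"), n, replace = TRUE),
                     Age = c(rep("adult", n_adult),
                             rep("juvenile", n - n_adult)),
                     Site = "synthetic", stringsAsFactors = FALSE)
    idn <- idn + n
    for (tr in traits) {
      if (tr %in% bilateral_traits()) {
        e <- stats::rnorm(n, 0, scenario$bilateral_jitter *
                            tg$sd[tg$trait == tr])
        df[[paste0(tr, "_L")]] <- X[, tr] + e
        df[[paste0(tr, "_R")]] <- X[, tr] - e
      } else {
        df[[tr]] <- X[, tr]
      }
    }
    rows[[g]] <- df
  }
  common <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) {
    for (col in setdiff(common, names(d))) d[[col]] <- NA_real_
    d[, common]
  })
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  # ensure full raw layout even when generating a trait subset
  for (col in c(.meta_columns(), .raw_trait_columns())) {
    if (!col %in% names(rec)) rec[[col]] <- NA_real_
  }
  rec <- rec[, c(.meta_columns(), .raw_trait_columns())]
  meas_cols <- intersect(names(rec), .raw_trait_columns())
  if (scenario$missing_rate > 0) {
    for (col in meas_cols) {
      mask <- stats::runif(nrow(rec)) < scenario$missing_rate
      rec[[col]][mask] <- NA_real_
    }
  }
  tab <- structure(list(
    records = rec, trait_names = trait_names(),
    provenance = list(source = "synthetic", n_rows = nrow(rec),
                      missing_cells = vapply(rec[meas_cols],
                                             function(v) sum(is.na(v)), 0L),
                      warnings = character(0))
  ), class = "trait_table")
  attr(tab, "truth") <- list(
    scenario = scenario, true_summaries = truth,
    regimes = vapply(scenario$hybrid_specs, function(h) h$regime, ""),
    n_adult = sum(rec$Age == "adult"))
  tab
}

#' Simulate grouped sequences under the TN93 substitution model
#'
#' Evolves nucleotide sequences site-independently on a star tree: a root
#' sequence is drawn from the stationary base frequencies, each group's
#' ancestor evolves along its branch, and each of the group's sequences
#' evolves a further (default zero) tip branch. Branch lengths are in
#' expected substitutions/site, so the expected pairwise distance between
#' two groups equals the sum of their branch lengths (plus tip lengths).
#'
#' @param branch_lengths Named numeric vector: group label -> branch length
#'   from the star center (>= 0).
#' @param params Model parameters: list with `base_freqs` (named A/C/G/T,
#'   sums to 1), `kappa1`, `kappa2`.
#' @param length Number of sites (>= 1).
#' @param n_per_group Sequences per group.
#' @param tip_length Extra per-sequence branch length (default 0:
#'   sequences within a group are identical).
#' @param seed Integer seed.
#' @return A `grouped_alignment`; the true between-group distances are
#'   attached as attribute `"truth"`.
#' @export
generate_sequences <- function(branch_lengths, params, length = 20000L,
                               n_per_group = 2L, tip_length = 0,
                               seed = 1L) {
  stopifnot(all(branch_lengths >= 0), length >= 1L, n_per_group >= 1L,
            tip_length >= 0)
  f <- params$base_freqs[c("A", "C", "G", "T")]
  stopifnot(abs(sum(f) - 1) < 1e-8, all(f > 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rate <- .tn93_rate(params$kappa1, params$kappa2, f)
  evolve <- function(seq_codes, d) {
    if (d == 0) return(seq_codes)
    P <- .tn93_pmatrix(d / rate, params$kappa1, params$kappa2, f)
    out <- integer(length(seq_codes))
    for (b in 1:4) {
      idx <- which(seq_codes == b)
      if (length(idx) > 0L) {
        out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = P[b, ])
      }
    }
    out
  }
  root <- sample.int(4L, length, replace = TRUE, prob = f)
  seqs <- list()
  groups <- character(0)
  for (g in names(branch_lengths)) {
    anc <- evolve(root, branch_lengths[[g]])
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      seqs[[id]] <- bases[evolve(anc, tip_length)]
      groups[id] <- g
    }
  }
  aln <- grouped_alignment(seqs, groups)
  gl <- names(branch_lengths)
  truth <- outer(branch_lengths[gl], branch_lengths[gl], "+") +
    2 * tip_length
  diag(truth) <- 0
  dimnames(truth) <- list(gl, gl)
  attr(aln, "truth") <- list(distances = truth, params = params,
                             tip_length = tip_length)
  aln
}
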