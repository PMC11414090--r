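# shared fixture builders; everything is generated in code at test time

# write a tiny raw-layout CSV and return its path
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# a minimal well-formed raw table with `n` rows
tiny_raw_table <- function(n = 3) {
  df <- data.frame(Individual = sprintf("ID%02d", seq_len(n)),
                   Taxon = rep(c("J", "P"), length.out = n),
                   Sex = "F", Age = "adult", Site = "here",
                   stringsAsFactors = FALSE)
  for (tr in unilateral_traits()) df[[tr]] <- seq_len(n) + 10
  for (tr in bilateral_traits()) {
    df[[paste0(tr, "_L")]] <- seq_len(n) + 5
    df[[paste0(tr, "_R")]] <- seq_len(n) + 5.2
  }
  df
}

# combined published species + hybrid summaries (summary-mode input)
reference_all_summaries <- function() {
  rbind(reference_species_summaries(), reference_hybrid_summaries())
}

# two-parent single-trait scenario for regime-recovery simulations;
# parents 4 pooled SD apart (see methods vignette for the rationale)
recovery_scenario <- function(regime, effect_size = 1, n = 50, seed = 1) {
  synthetic_scenario(
    parental_specs = data.frame(group = c("P1", "P2"), trait = "BODY",
                                mean = c(18, 26), sd = 2,
                                stringsAsFactors = FALSE),
    hybrid_specs = list(H = list(parents = c("P1", "P2"), regime = regime,
                                 effect_size = effect_size)),
    group_sizes = c(P1 = n, P2 = n, H = n),
    traits = "BODY", seed = seed)
}

classify_one_rep <- function(regime, seed, effect_size = 1, n = 50) {
  sc <- recovery_scenario(regime, effect_size = effect_size, n = n,
                          seed = seed)
  flat <- flatten_traits(generate_traits(sc))
  su <- summarize_traits(flat, traits = "BODY")
  classify_trait(su[su$group == "H", ], su[su$group == "P1", ],
                 su[su$group == "P2", ])$label
}

# small TN93 parameter set used across sequence tests
tn93_test_params <- function() {
  list(base_freqs = c(A = 0.3, C = 0.2, G = 0.25, T = 0.25),
       kappa1 = 4, kappa2 = 8)
}
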