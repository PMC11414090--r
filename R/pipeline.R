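#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: ingest (from a CSV or the synthetic
#' generator) -> adult filter -> bilateral averaging -> per-taxon summaries
#' -> univariate heterogeneous-variance screen (Levene, Welch ANOVA,
#' Games-Howell) -> Pillai MANOVA screen -> mid-parent-value hybrid
#' classification -> morphospace PCAs -> optional between-group mitogenomic
#' distances. Every stage writes a CSV into the output directory and a JSON
#' run manifest records versions, seed, config, and aggregated warnings.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param config A named list, or path to a JSON file, with elements:
#'   `traits` (input CSV path) or `scenario` (arguments for
#'   [synthetic_scenario()]; used when `traits` is absent), `plan` (hybrid
#'   -> list of 2-vectors of parents; default [reference_plan()]), `alpha`
#'   (default 0.05), `pca_subsets` (list of taxon-code vectors; default the
#'   three morphospace views), `pca_scaling`, `fasta` + `groups` (optional
#'   alignment inputs; the distance stage is skipped and noted when
#'   absent), `out_dir` (required), `seed` (default 1).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  stopifnot(alpha > 0, alpha < 1)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "callimorph",
                   version = as.character(utils::packageVersion("callimorph")),
                   seed = seed, alpha = alpha, warnings = list(),
                   skipped = character(0))
  note <- function(stage, w) {
    manifest$warnings[[stage]] <<- c(manifest$warnings[[stage]], w)
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note(name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  # ingest
  tab <- stage("ingest", {
    if (!is.null(config$traits)) {
      read_trait_table(config$traits)
    } else {
      sc_args <- if (is.null(config$scenario)) list() else config$scenario
      sc_args$seed <- seed
      generate_traits(do.call(synthetic_scenario, sc_args))
    }
  })
  tab <- stage("filter_adults", filter_adults(tab))
  flat <- stage("flatten", flatten_traits(tab))
  utils::write.csv(flat, file.path(out_dir, "traits_clean.csv"),
                   row.names = FALSE, na = "")

  summaries <- stage("summaries", summarize_traits(flat))
  utils::write.csv(summaries, file.path(out_dir, "group_summaries.csv"),
                   row.names = FALSE)

  screen <- stage("screen", screen_traits(flat))
  utils::write.csv(screen$anova, file.path(out_dir, "welch_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$posthoc, file.path(out_dir, "games_howell.csv"),
                   row.names = FALSE)

  man <- stage("manova", {
    X <- flat[, trait_names()]
    manova_pillai(X, flat$Taxon)
  })
  utils::write.csv(
    data.frame(pillai = man$pillai, F = man$statistic, df1 = man$df1,
               df2 = man$df2, p = man$p_value, n_used = man$n_used),
    file.path(out_dir, "manova.csv"), row.names = FALSE)

  plan <- if (is.null(config$plan)) {
    pl <- reference_plan()
    pl[intersect(names(pl), unique(flat$Taxon))]
  } else {
    lapply(config$plan, function(pairs) {
      if (is.matrix(pairs)) {
        matrix(as.character(pairs), ncol = 2)
      } else {
        do.call(rbind, lapply(pairs,
                              function(p) matrix(as.character(p), ncol = 2)))
      }
    })
  }
  classification <- stage("classify",
                          classify_all(flat, plan, alpha = alpha))
  utils::write.csv(classification,
                   file.path(out_dir, "classification_long.csv"),
                   row.names = FALSE)
  utils::write.csv(render_classification(classification),
                   file.path(out_dir, "classification_rendered.csv"),
                   row.names = FALSE)

  pca_subsets <- config$pca_subsets
  if (is.null(pca_subsets)) {
    pca_subsets <- list(c("J", "P", "PJ"), c("G", "P", "PG"),
                        c("A", "G", "J", "P", "AH"))
    pca_subsets <- Filter(function(s) all(s %in% unique(flat$Taxon)),
                          pca_subsets)
  }
  scaling <- if (is.null(config$pca_scaling)) "correlation"
             else config$pca_scaling
  pcas <- list()
  for (s in pca_subsets) {
    key <- paste(s, collapse = "")
    pcas[[key]] <- stage(paste0("pca_", key),
                         run_pca(flat, subset = s, scaling = scaling))
    rep <- pca_report(pcas[[key]])
    utils::write.csv(rep$eigen,
                     file.path(out_dir, sprintf("pca_%s_eigen.csv", key)),
                     row.names = FALSE)
    utils::write.csv(rep$loadings,
                     file.path(out_dir, sprintf("pca_%s_loadings.csv", key)),
                     row.names = FALSE)
    utils::write.csv(rep$scores,
                     file.path(out_dir, sprintf("pca_%s_scores.csv", key)),
                     row.names = FALSE)
  }

  distances <- NULL
  if (!is.null(config$fasta)) {
    distances <- stage("gdist", {
      aln <- read_grouped_fasta(config$fasta, config$groups)
      between_group_means(aln)
    })
    utils::write.csv(as.data.frame(distances$values),
                     file.path(out_dir, "between_group_distances.csv"))
  } else {
    manifest$skipped <- c(manifest$skipped,
                          "gdist (no fasta input configured)")
  }

  manifest$config <- config
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table = tab, flat = flat, summaries = summaries,
                 screen = screen, manova = man,
                 classification = classification, pcas = pcas,
                 distances = distances, manifest = manifest))
}
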