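#' Mid-parent value
#'
#' The additive expectation for a hybrid trait: half the sum of the two
#' parental species' trait means. Symmetric in its arguments.
#'
#' @param mean1,mean2 Parental trait means (same units).
#' @return `0.5 * (mean1 + mean2)`.
#' @export
mid_parent_value <- function(mean1, mean2) {
  stopifnot(is.finite(mean1), is.finite(mean2))
  0.5 * (mean1 + mean2)
}

# canonical alphabetical pair label, e.g. "A_J"
pair_label <- function(parent1, parent2) {
  paste(sort(c(parent1, parent2)), collapse = "_")
}

#' Classify one hybrid trait against a parental pair
#'
#' Implements the mid-parent-value decision procedure for a single
#' (hybrid group, parental pair, trait) cell, from summary statistics
#' alone:
#'
#' 1. Compute the MPV from the parental means; run a one-sample t-test of
#'    the hybrid mean against the MPV and Welch two-sample t-tests of the
#'    hybrid against each parent.
#' 2. **transgressive** if the hybrid mean exceeds both parental means and
#'    both hybrid-parent contrasts are significant (transgression is tested
#'    before heterosis: a transgressive trait usually also has a
#'    significant MPV contrast).
#' 3. Otherwise **heterotic** (**dysgenetic**) if the MPV contrast is
#'    significant and the hybrid mean is above (below) the MPV.
#' 4. Otherwise (MPV contrast nonsignificant): **intermediate** if the
#'    hybrid mean lies strictly between the parental means;
#'    **parent1_like**/**parent2_like** if it equals a parental mean or
#'    lies outside the range with at least one significant parental
#'    contrast, attributed to the nearer parent (exact tie:
#'    intermediate); **above_both_ns**/**below_both_ns** if it lies outside
#'    the range with both parental contrasts nonsignificant ("larger/
#'    smaller than both parents", resemblance to neither established).
#'
#' @param hybrid,parent1,parent2 Lists or one-row data.frames with `n`,
#'   `mean`, `sd` (all n >= 2, sd > 0), same trait and units.
#' @param alpha Two-sided significance level for every branch (default
#'   0.05).
#' @param low_transgression If `TRUE`, also label as transgressive a hybrid
#'   mean below both parental means with both contrasts significant
#'   (default off: only upward transgression is defined in the field's
#'   usual sense).
#' @return A one-row data.frame: `label`, `mpv`, `hybrid_mean`,
#'   `parent1_mean`, `parent2_mean`, `t_mpv`, `p_mpv`, `p_vs_parent1`,
#'   `p_vs_parent2`, `direction` (sign of hybrid mean - MPV).
#' @export
classify_trait <- function(hybrid, parent1, parent2, alpha = 0.05,
                           low_transgression = FALSE) {
  hybrid <- as.list(hybrid); parent1 <- as.list(parent1)
  parent2 <- as.list(parent2)
  .check_summaries(hybrid, parent1, parent2)
  mpv <- mid_parent_value(parent1$mean, parent2$mean)
  t_mpv <- one_sample_t(hybrid, mpv)
  w1 <- welch_t(hybrid, parent1)
  w2 <- welch_t(hybrid, parent2)
  hm <- hybrid$mean; m1 <- parent1$mean; m2 <- parent2$mean
  both_sig <- w1$p_value < alpha && w2$p_value < alpha
  lo <- min(m1, m2); hi <- max(m1, m2)
  if (hm > hi && both_sig) {
    label <- "transgressive"
  } else if (low_transgression && hm < lo && both_sig) {
    label <- "transgressive"
  } else if (t_mpv$p_value < alpha) {
    label <- if (hm > mpv) "heterotic" else "dysgenetic"
  } else if (hm > lo && hm < hi) {
    label <- "intermediate"
  } else {
    d1 <- abs(hm - m1); d2 <- abs(hm - m2)
    any_sig <- w1$p_value < alpha || w2$p_value < alpha
    if (d1 == d2) {
      label <- "intermediate"
    } else if (hm == m1 || hm == m2 || any_sig) {
      label <- if (d1 < d2) "parent1_like" else "parent2_like"
    } else {
      label <- if (hm > hi) "above_both_ns" else "below_both_ns"
    }
  }
  data.frame(label = label, mpv = mpv, hybrid_mean = hm,
             parent1_mean = m1, parent2_mean = m2,
             t_mpv = t_mpv$statistic, p_mpv = t_mpv$p_value,
             p_vs_parent1 = w1$p_value, p_vs_parent2 = w2$p_value,
             direction = sign(hm - mpv), stringsAsFactors = FALSE)
}

#' Classify every hybrid trait in a dataset
#'
#' For each hybrid group in `plan`, each configured putative parental pair,
#' and each trait, computes group summaries from the flat trait matrix and
#' applies [classify_trait()]. A hybrid whose exact parental species are
#' unknown (the aurita-hybrid case) is simply given several pairs in the
#' plan and yields one row per pair.
#'
#' @param flat Flat trait data.frame with a `Taxon` column.
#' @param plan Named list: hybrid taxon code -> two-column character matrix
#'   of parental pairs, e.g. `list(PJ = rbind(c("J","P")))`. See
#'   [reference_plan()].
#' @param alpha Significance level.
#' @param traits Traits to classify.
#' @return A long-format data.frame, one row per (hybrid, pair, trait):
#'   the paper-style classification table. Cells whose hybrid or parental
#'   summary has n < 2 are skipped with a warning.
#' @export
classify_all <- function(flat, plan, alpha = 0.05, traits = trait_names()) {
  if (length(plan) == 0L) return(.empty_classification())
  summaries <- summarize_traits(flat, by = "Taxon", traits = traits)
  present <- unique(flat$Taxon)
  for (h in names(plan)) {
    if (!(h %in% present)) stop("hybrid group absent from data: ", h)
  }
  summary_mode_classify(summaries, plan, alpha = alpha, traits = traits,
                        provenance = "raw-data")
}

#' Classify hybrid traits from externally supplied summaries
#'
#' Identical decision logic to [classify_all()], but fed directly from a
#' (group, trait) summary table — e.g. summaries typed in from a published
#' table of n/mean/SD — so the classification can be reproduced without raw
#' data. Results computed this way inherit the rounding of the printed
#' summaries: p-values near the significance boundary can drift relative to
#' a raw-data run.
#'
#' @param summaries Data.frame with columns `group`, `trait`, `n`, `mean`,
#'   `sd` covering every (group, trait) the plan needs.
#' @param plan,alpha,traits As in [classify_all()].
#' @param provenance Provenance string stored on the result
#'   (default `"summary-mode"`).
#' @return Long-format classification data.frame with columns
#'   `hybrid_group`, `pair`, `parent1`, `parent2`, `trait`, `n`, `mean`,
#'   `sd`, plus the [classify_trait()] fields.
#' @export
summary_mode_classify <- function(summaries, plan, alpha = 0.05,
                                  traits = trait_names(),
                                  provenance = "summary-mode") {
  rows <- list()
  for (h in names(plan)) {
    pairs <- plan[[h]]
    for (r in seq_len(nrow(pairs))) {
      p1 <- pairs[r, 1]; p2 <- pairs[r, 2]
      if (p1 == p2) stop("parental pair must name two distinct taxa")
      for (tr in traits) {
        hs <- tryCatch(.get_summary(summaries, h, tr), error = function(e) e)
        s1 <- tryCatch(.get_summary(summaries, p1, tr), error = function(e) e)
        s2 <- tryCatch(.get_summary(summaries, p2, tr), error = function(e) e)
        bad <- vapply(list(hs, s1, s2), function(x) {
          inherits(x, "error") || x$n < 2L || !is.finite(x$sd) || x$sd <= 0
        }, TRUE)
        if (any(bad)) {
          if (identical(provenance, "summary-mode") &&
              any(vapply(list(hs, s1, s2), inherits, TRUE, "error"))) {
            stop("missing summary for (", h, "/", p1, "/", p2, ", ", tr, ")")
          }
          warning(sprintf("skipping %s %s_%s %s: degenerate summary",
                          h, p1, p2, tr))
          next
        }
        cls <- classify_trait(hs, s1, s2, alpha = alpha)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(hybrid_group = h, pair = pair_label(p1, p2),
                     parent1 = p1, parent2 = p2, trait = tr,
                     n = hs$n, mean = hs$mean, sd = hs$sd,
                     stringsAsFactors = FALSE),
          cls)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_classification())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "provenance") <- provenance
  attr(out, "multiple_testing") <-
    "no correction across traits within a hybrid group"
  out
}

.empty_classification <- function() {
  out <- data.frame(hybrid_group = character(), pair = character(),
                    parent1 = character(), parent2 = character(),
                    trait = character(), n = integer(), mean = numeric(),
                    sd = numeric(), label = character(), mpv = numeric(),
                    hybrid_mean = numeric(), parent1_mean = numeric(),
                    parent2_mean = numeric(), t_mpv = numeric(),
                    p_mpv = numeric(), p_vs_parent1 = numeric(),
                    p_vs_parent2 = numeric(), direction = numeric(),
                    stringsAsFactors = FALSE)
  out
}

#' Render a classification table in the published wide style
#'
#' Rounds means/SDs/MPVs to one decimal place and p-values to three
#' decimals with star codes, one row per trait — the layout of the
#' paper-style hybrid tables.
#'
#' @param classification Result of [classify_all()] or
#'   [summary_mode_classify()].
#' @return A data.frame, one row per (hybrid, pair, trait), with rendered
#'   columns.
#' @export
render_classification <- function(classification) {
  x <- classification
  fmt_p <- function(p) paste0(formatC(p, digits = 3, format = "f"),
                              significance_code(p))
  data.frame(
    hybrid_group = x$hybrid_group, pair = x$pair, trait = x$trait,
    n = x$n, mean = round(x$mean, 1), sd = round(x$sd, 1),
    mpv = round(x$mpv, 1), p_mpv = fmt_p(x$p_mpv),
    p_vs_parent1 = fmt_p(x$p_vs_parent1),
    p_vs_parent2 = fmt_p(x$p_vs_parent2),
    label = x$label, stringsAsFactors = FALSE)
}

#' Count classification labels per hybrid group and pair
#'
#' @param classification Long-format classification table.
#' @return A data.frame of label counts by (hybrid_group, pair).
#' @export
count_labels <- function(classification) {
  if (nrow(classification) == 0L) {
    return(data.frame(hybrid_group = character(), pair = character(),
                      label = character(), count = integer()))
  }
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(classification))),
    by = list(hybrid_group = classification$hybrid_group,
              pair = classification$pair, label = classification$label),
    FUN = sum)
  agg[order(agg$hybrid_group, agg$pair, agg$label), , drop = FALSE]
}
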