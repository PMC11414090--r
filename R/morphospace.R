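#' Morphospace principal components analysis
#'
#' PCA of the flat trait matrix for a configured taxon subset. Rows with
#' any missing trait are dropped (listwise deletion; the count is
#' recorded), columns are centered, and — by default — scaled to unit
#' variance (correlation PCA), since the traits mix grams, centimeters,
#' and millimeters. The decomposition is an eigen-decomposition of the
#' correlation (or covariance) matrix with a deterministic sign
#' convention: the largest-magnitude loading of each component is made
#' positive, so results are reproducible across runs and platforms.
#'
#' @param flat Flat trait data.frame with a `Taxon` column.
#' @param subset Taxon codes to include (default: all rows).
#' @param scaling `"correlation"` (default) or `"covariance"`.
#' @param traits Trait columns to use.
#' @return A `pca_result` list: `subset`, `n_used`, `n_dropped`,
#'   `eigenvalues` (nonincreasing), `pct_variance` (sums to 100),
#'   `loadings` (trait x component), `scores` (row x component, rows
#'   labelled by taxon in `taxon`), `scaling`, `center`, `scale`.
#' @export
run_pca <- function(flat, subset = NULL, scaling = c("correlation",
                                                     "covariance"),
                    traits = trait_names()) {
  scaling <- match.arg(scaling)
  if (!is.null(subset)) flat <- flat[flat$Taxon %in% subset, , drop = FALSE]
  X <- as.matrix(flat[, traits, drop = FALSE])
  keep <- stats::complete.cases(X)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  taxon <- flat$Taxon[keep]
  p <- ncol(X)
  if (nrow(X) <= p) {
    stop("need more complete-case rows (", nrow(X), ") than traits (", p, ")")
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (scaling == "correlation") {
    scl <- apply(X, 2, stats::sd)
    if (any(scl == 0)) {
      stop("constant trait under correlation scaling: ",
           paste(traits[scl == 0], collapse = ", "))
    }
    Xc <- sweep(Xc, 2, scl, "/")
  } else {
    scl <- rep(1, p)
  }
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  vec <- eig$vectors
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(p)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(traits, paste0("PC", seq_len(p)))
  scores <- Xc %*% vec
  structure(list(
    subset = if (is.null(subset)) sort(unique(taxon)) else subset,
    n_used = nrow(X), n_dropped = n_dropped,
    eigenvalues = ev, pct_variance = 100 * ev / sum(ev),
    loadings = vec, scores = scores, taxon = taxon,
    scaling = scaling, center = ctr, scale = scl
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA (%s scaling) on taxa %s: %d complete rows (%d dropped)\n",
              x$scaling, paste(x$subset, collapse = ","),
              x$n_used, x$n_dropped))
  k <- min(4L, length(x$eigenvalues))
  cat("  PC variance %:",
      paste(sprintf("PC%d=%.2f", seq_len(k), x$pct_variance[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tabular report of a PCA
#'
#' @param result A `pca_result`.
#' @param k Number of components for the loading and score tables
#'   (default 2, the usual morphospace view).
#' @return A list of data.frames: `eigen` (component, eigenvalue, percent
#'   and cumulative percent of variance), `loadings` (trait x k), and
#'   `scores` (first k score columns labelled by taxon — the coordinates
#'   of the morphospace scatter).
#' @export
pca_report <- function(result, k = 2L) {
  stopifnot(inherits(result, "pca_result"))
  p <- length(result$eigenvalues)
  k <- min(k, p)
  eigen_tab <- data.frame(
    component = paste0("PC", seq_len(p)),
    eigenvalue = result$eigenvalues,
    pct_variance = result$pct_variance,
    cum_pct = cumsum(result$pct_variance))
  loadings <- as.data.frame(result$loadings[, seq_len(k), drop = FALSE])
  loadings <- cbind(trait = rownames(result$loadings), loadings)
  rownames(loadings) <- NULL
  scores <- as.data.frame(result$scores[, seq_len(k), drop = FALSE])
  scores <- cbind(taxon = result$taxon, scores)
  rownames(scores) <- NULL
  list(eigen = eigen_tab, loadings = loadings, scores = scores)
}
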