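#' Read a grouped, pre-aligned multi-FASTA
#'
#' Reads an aligned nucleotide FASTA (no alignment is performed here) and
#' attaches a species/group label to every sequence. Sequences are
#' uppercased; anything other than A/C/G/T (gaps, N, IUPAC ambiguity
#' codes) is treated as missing downstream, under pairwise deletion.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param group_map Either a named character vector (names = sequence ids,
#'   values = group labels) or a data.frame/two-column table with columns
#'   `id` and `group` (a TSV path is also accepted).
#' @return A `grouped_alignment`: list with `sequences` (named list of
#'   uppercase character vectors) and `groups` (named character vector).
#' @export
read_grouped_fasta <- function(path, group_map) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("input error: no sequences in ", path)
  seqs <- lapply(as.character(dna), function(s) toupper(s))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("unequal sequence lengths (inputs must be pre-aligned): ",
         paste(range(lens), collapse = "-"))
  }
  if (is.character(group_map) && length(group_map) == 1L &&
      file.exists(group_map)) {
    group_map <- utils::read.table(group_map, sep = "\t", header = FALSE,
                                   col.names = c("id", "group"),
                                   colClasses = "character")
  }
  if (is.data.frame(group_map)) {
    gm <- stats::setNames(as.character(group_map$group),
                          as.character(group_map$id))
  } else {
    gm <- group_map
  }
  unmapped <- setdiff(names(seqs), names(gm))
  if (length(unmapped) > 0L) {
    stop("sequence id(s) missing from group map: ",
         paste(unmapped, collapse = ", "))
  }
  grouped_alignment(seqs, gm[names(seqs)])
}

#' Construct a grouped alignment
#'
#' @param sequences Named list of equal-length uppercase character vectors
#'   over the nucleotide alphabet.
#' @param groups Named character vector mapping each sequence id to a group.
#' @return A `grouped_alignment` object.
#' @export
grouped_alignment <- function(sequences, groups) {
  stopifnot(length(unique(lengths(sequences))) == 1L,
            all(names(sequences) %in% names(groups)))
  structure(list(sequences = sequences,
                 groups = groups[names(sequences)]),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat(sprintf("grouped_alignment: %d sequences x %d sites, %d group(s)\n",
              length(x$sequences), length(x$sequences[[1]]),
              length(unique(x$groups))))
  invisible(x)
}

# integer-code a sequence: A=1, C=2, G=3, T=4, anything else 0 (missing)
.code_seq <- function(s) {
  code <- match(s, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  code
}

#' Pairwise site-pattern counts under pairwise deletion
#'
#' Counts, over the sites where *both* residues are unambiguous A/C/G/T,
#' the 4x4 table of observed residue pairs. Gapped, ambiguous, or missing
#' sites are excluded for this pair only (pairwise deletion).
#'
#' @param a,b Equal-length character vectors (or integer-coded sequences).
#' @return A list: `counts` (4x4 integer matrix, rows = residue in `a`,
#'   columns = residue in `b`), `retained` (number of compared sites).
#'   Errors if no site survives deletion.
#' @export
pairwise_site_pattern_counts <- function(a, b) {
  if (is.character(a)) a <- .code_seq(a)
  if (is.character(b)) b <- .code_seq(b)
  stopifnot(length(a) == length(b))
  keep <- a > 0L & b > 0L
  L <- sum(keep)
  if (L == 0L) stop("zero retained sites for this pair")
  idx <- (a[keep] - 1L) * 4L + b[keep]
  counts <- matrix(tabulate(idx, nbins = 16L), 4, 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"),
                                   c("A", "C", "G", "T")))
  list(counts = counts, retained = L)
}

# collapse a 4x4 pattern-count matrix to (purine transitions, pyrimidine
# transitions, transversions, identical) counts
.pattern_classes <- function(counts) {
  s1 <- counts["A", "G"] + counts["G", "A"]
  s2 <- counts["C", "T"] + counts["T", "C"]
  same <- sum(diag(counts))
  tv <- sum(counts) - s1 - s2 - same
  c(P1 = s1, P2 = s2, Q = tv, same = same)
}

# TN93 expected pattern-class proportions at transversion exposure u
# (u = beta * t, with beta the transversion rate set to 1)
.tn93_props <- function(u, kappa1, kappa2, freqs) {
  pa <- freqs["A"]; pc <- freqs["C"]; pg <- freqs["G"]; pt <- freqs["T"]
  pr <- pa + pg; py <- pc + pt
  e3 <- exp(-u)
  e1 <- exp(-(pr * kappa1 + py) * u)
  e2 <- exp(-(py * kappa2 + pr) * u)
  c(P1 = unname(2 * pa * pg * (1 + (py / pr) * e3 - e1 / pr)),
    P2 = unname(2 * pt * pc * (1 + (pr / py) * e3 - e2 / py)),
    Q = unname(2 * pr * py * (1 - e3)))
}

# TN93 transition-probability matrix (A,C,G,T order) at exposure u
.tn93_pmatrix <- function(u, kappa1, kappa2, freqs) {
  pa <- freqs["A"]; pc <- freqs["C"]; pg <- freqs["G"]; pt <- freqs["T"]
  pr <- pa + pg; py <- pc + pt
  e3 <- exp(-u)
  e1 <- exp(-(pr * kappa1 + py) * u)
  e2 <- exp(-(py * kappa2 + pr) * u)
  P <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  P["A", "A"] <- pa + pa * py / pr * e3 + pg / pr * e1
  P["A", "G"] <- pg + pg * py / pr * e3 - pg / pr * e1
  P["G", "A"] <- pa + pa * py / pr * e3 - pa / pr * e1
  P["G", "G"] <- pg + pg * py / pr * e3 + pa / pr * e1
  P["C", "C"] <- pc + pc * pr / py * e3 + pt / py * e2
  P["C", "T"] <- pt + pt * pr / py * e3 - pt / py * e2
  P["T", "C"] <- pc + pc * pr / py * e3 - pc / py * e2
  P["T", "T"] <- pt + pt * pr / py * e3 + pc / py * e2
  P["A", "C"] <- P["G", "C"] <- pc * (1 - e3)
  P["A", "T"] <- P["G", "T"] <- pt * (1 - e3)
  P["C", "A"] <- P["T", "A"] <- pa * (1 - e3)
  P["C", "G"] <- P["T", "G"] <- pg * (1 - e3)
  P
}

# expected substitutions/site per unit of transversion exposure u
.tn93_rate <- function(kappa1, kappa2, freqs) {
  pa <- freqs["A"]; pc <- freqs["C"]; pg <- freqs["G"]; pt <- freqs["T"]
  unname(2 * (pa * pg * kappa1 + pt * pc * kappa2 + (pa + pg) * (pc + pt)))
}

# multinomial log-likelihood of one pair's class counts at exposure u
.tn93_pair_loglik <- function(u, cls, kappa1, kappa2, freqs) {
  pr <- .tn93_props(u, kappa1, kappa2, freqs)
  ps <- 1 - sum(pr)
  probs <- c(pr, same = ps)
  probs <- pmax(probs, 1e-300)
  sum(cls * log(probs))
}

#' Estimate shared substitution-model parameters by composite likelihood
#'
#' Base frequencies are taken from the pooled unambiguous residues of all
#' sequences. The two transition/transversion rate ratios of the
#' Tamura-Nei (1993) model — kappa1 for purine (A/G) and kappa2 for
#' pyrimidine (C/T) transitions — are estimated by maximizing the sum over
#' all sequence pairs of the multinomial log-likelihood of that pair's
#' site-pattern class counts, with a free per-pair divergence profiled out
#' (profile composite likelihood). The optimizer is deterministic:
#' Nelder-Mead on log-kappas from the fixed start (1, 1), relative
#' tolerance 1e-8, at most 500 iterations.
#'
#' @param alignment A `grouped_alignment`.
#' @return A list: `base_freqs` (A/C/G/T, sums to 1), `kappa1`, `kappa2`,
#'   `loglik`, `converged`, `identifiable`. If the alignment carries no
#'   substitutions at all, flagged defaults kappa1 = kappa2 = 1 are
#'   returned with a warning.
#' @export
estimate_mcl_params <- function(alignment) {
  stopifnot(inherits(alignment, "grouped_alignment"))
  coded <- lapply(alignment$sequences, .code_seq)
  if (length(coded) < 2L) stop("need >= 2 sequences")
  pooled <- tabulate(unlist(coded)[unlist(coded) > 0L], nbins = 4L)
  freqs <- stats::setNames(pooled / sum(pooled), c("A", "C", "G", "T"))
  n <- length(coded)
  cls <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pc <- pairwise_site_pattern_counts(coded[[i]], coded[[j]])
    cls[[length(cls) + 1L]] <- .pattern_classes(pc$counts)
  }
  ndiff <- sum(vapply(cls, function(x) sum(x[c("P1", "P2", "Q")]), 1))
  if (ndiff == 0) {
    warning("all sequences identical: rate ratios unidentifiable; ",
            "returning kappa1 = kappa2 = 1")
    return(list(base_freqs = freqs, kappa1 = 1, kappa2 = 1,
                loglik = NA_real_, converged = TRUE, identifiable = FALSE))
  }
  profile <- function(logk) {
    k1 <- exp(logk[1]); k2 <- exp(logk[2])
    tot <- 0
    for (c in cls) {
      if (sum(c[c("P1", "P2", "Q")]) == 0) next
      opt <- stats::optimize(.tn93_pair_loglik, interval = c(1e-9, 30),
                             cls = c, kappa1 = k1, kappa2 = k2,
                             freqs = freqs, maximum = TRUE, tol = 1e-9)
      tot <- tot + opt$objective
    }
    -tot
  }
  fit <- stats::optim(c(0, 0), profile, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 500))
  if (fit$convergence != 0) {
    stop("composite-likelihood optimization did not converge (code ",
         fit$convergence, ")")
  }
  list(base_freqs = freqs, kappa1 = exp(fit$par[1]),
       kappa2 = exp(fit$par[2]), loglik = -fit$value,
       converged = TRUE, identifiable = TRUE)
}

#' Tamura-Nei (1993) pairwise distance
#'
#' Evaluates the TN93 distance from one pair's site-pattern counts using
#' shared base frequencies (from the composite-likelihood fit):
#' with purine-transition, pyrimidine-transition, and transversion
#' proportions p1, p2, q over the retained sites,
#' `d = -(2 pA pG / pR) log(w1) - (2 pT pC / pY) log(w2)
#'  - 2 (pR pY - pA pG pY / pR - pT pC pR / pY) log(w3)`
#' where `w1 = 1 - pR p1 / (2 pA pG) - q / (2 pR)`,
#' `w2 = 1 - pY p2 / (2 pT pC) - q / (2 pY)`,
#' `w3 = 1 - q / (2 pR pY)`. Negative estimates are clamped at 0.
#'
#' @param counts Result of [pairwise_site_pattern_counts()].
#' @param params Model parameters (needs `base_freqs`), e.g. from
#'   [estimate_mcl_params()].
#' @return The distance in substitutions/site, or `NA` with attribute
#'   `saturated = TRUE` when a logarithm argument is nonpositive.
#' @export
pairwise_distance <- function(counts, params) {
  cl <- .pattern_classes(counts$counts)
  L <- counts$retained
  p1 <- cl[["P1"]] / L; p2 <- cl[["P2"]] / L; q <- cl[["Q"]] / L
  f <- params$base_freqs
  pa <- f[["A"]]; pc <- f[["C"]]; pg <- f[["G"]]; pt <- f[["T"]]
  pr <- pa + pg; py <- pc + pt
  w1 <- 1 - pr * p1 / (2 * pa * pg) - q / (2 * pr)
  w2 <- 1 - py * p2 / (2 * pt * pc) - q / (2 * py)
  w3 <- 1 - q / (2 * pr * py)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    return(structure(NA_real_, saturated = TRUE))
  }
  d <- -(2 * pa * pg / pr) * log(w1) - (2 * pt * pc / py) * log(w2) -
    2 * (pr * py - pa * pg * py / pr - pt * pc * pr / py) * log(w3)
  max(d, 0)
}

#' Between-group mean genetic distances
#'
#' The grouped analogue of a distance matrix: entry (g, h) is the
#' arithmetic mean of the pairwise TN93 distances over all cross pairs
#' (one sequence from g, one from h). Saturated pairs are excluded from
#' the mean with a warning; a group pair with every pair saturated gets a
#' missing entry. The diagonal is zero by convention (within-group
#' diversity is not computed).
#'
#' @param alignment A `grouped_alignment`.
#' @param params Optional model parameters; estimated with
#'   [estimate_mcl_params()] when omitted.
#' @return A list: `labels`, `values` (symmetric matrix,
#'   substitutions/site), `n_pairs` (cross-pair counts used per entry),
#'   `params`.
#' @export
between_group_means <- function(alignment, params = NULL) {
  stopifnot(inherits(alignment, "grouped_alignment"))
  if (is.null(params)) params <- estimate_mcl_params(alignment)
  groups <- sort(unique(alignment$groups))
  if (length(groups) < 2L) stop("need >= 2 groups")
  coded <- lapply(alignment$sequences, .code_seq)
  k <- length(groups)
  values <- matrix(0, k, k, dimnames = list(groups, groups))
  n_pairs <- matrix(0L, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    ids_i <- names(alignment$groups)[alignment$groups == groups[i]]
    ids_j <- names(alignment$groups)[alignment$groups == groups[j]]
    ds <- c()
    for (a in ids_i) for (b in ids_j) {
      d <- tryCatch(
        pairwise_distance(pairwise_site_pattern_counts(coded[[a]],
                                                       coded[[b]]),
                          params),
        error = function(e) structure(NA_real_, saturated = TRUE))
      if (is.na(d)) {
        warning(sprintf("saturated or empty pair %s-%s excluded", a, b))
      } else {
        ds <- c(ds, d)
      }
    }
    if (length(ds) == 0L) {
      warning(sprintf("all pairs saturated for groups %s-%s; entry missing",
                      groups[i], groups[j]))
      values[i, j] <- values[j, i] <- NA_real_
    } else {
      values[i, j] <- values[j, i] <- mean(ds)
    }
    n_pairs[i, j] <- n_pairs[j, i] <- length(ds)
  }
  list(labels = groups, values = values, n_pairs = n_pairs, params = params)
}

#' Write a grouped alignment to FASTA (+ id-to-group TSV)
#'
#' @param alignment A `grouped_alignment`.
#' @param fasta Output FASTA path.
#' @param groups_tsv Optional output path for the two-column id/group TSV.
#' @return `fasta`, invisibly.
#' @export
write_grouped_fasta <- function(alignment, fasta, groups_tsv = NULL) {
  stopifnot(inherits(alignment, "grouped_alignment"))
  dna <- ape::as.DNAbin(lapply(alignment$sequences, tolower))
  ape::write.FASTA(dna, fasta)
  if (!is.null(groups_tsv)) {
    utils::write.table(
      data.frame(id = names(alignment$groups),
                 group = unname(alignment$groups)),
      groups_tsv, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta)
}
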