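#' Published reference summaries for the four marmoset species
#'
#' Per-taxon sample size, mean, and sample standard deviation for the 13
#' morphometric traits of the four parental species (A = C. aurita,
#' G = C. geoffroyi, J = C. jacchus, P = C. penicillata), as printed in the
#' source study's species summary table. Units are grams for WEIGHT,
#' centimeters for BODY/TAIL/HUMERUS/FOREARM/FEMUR/TIBIA, millimeters for
#' the rest. These summaries are the package's built-in input for
#' summary-mode classification and the calibration defaults for the
#' synthetic-data generator.
#'
#' @return A data.frame with columns `group`, `trait`, `n`, `mean`, `sd`.
#' @export
reference_species_summaries <- function() {
  tab <- c(
    # trait      A: n mean  sd     G: n mean  sd     J: n mean  sd     P: n mean  sd
    "BODY",      27, 21.9,  1.4,   14, 22.2,  1.9,   29, 19.9,  1.6,   52, 20.9,  2.7,
    "FEMUR",     27,  6.5,  0.6,   14,  6.3,  0.5,   29,  5.5,  0.7,   54,  5.8,  0.6,
    "FO",        27, 42.6,  2.9,   14, 40.2,  2.6,   24, 39.7,  2.2,   50, 39.8,  2.1,
    "FOOT",      24, 61.1,  5.6,   14, 55.4,  3.2,   27, 54.7,  4.6,   54, 54.2,  3.7,
    "FOREARM",   27,  5.2,  0.4,   14,  4.8,  0.3,   29,  4.5,  0.4,   54,  4.6,  0.5,
    "HAND",      21, 30.5, 15.1,   13, 36.3,  2.7,   28, 35.4,  3.3,   48, 35.2,  4.0,
    "HUMERUS",   26,  5.4,  0.8,   14,  5.3,  0.3,   29,  4.7,  0.5,   54,  4.6,  0.7,
    "IC",        27, 33.1,  1.3,   14, 30.2,  1.9,   29, 27.4,  2.2,   54, 28.4,  1.6,
    "JAW",       23, 23.7,  3.9,   14, 25.7,  3.1,   29, 22.2,  2.9,   52, 22.9,  2.3,
    "TAIL",      26, 32.3,  1.7,   13, 30.7,  3.2,   24, 27.4,  2.9,   51, 27.7,  3.2,
    "TIBIA",     27,  7.2,  0.5,   14,  7.1,  0.3,   29,  6.6,  0.6,   54,  6.5,  0.6,
    "WEIGHT",    25, 440.6, 66.8,  14, 386.2, 63.0,  30, 322.6, 65.2,  54, 308.4, 68.1,
    "ZYG",       23, 31.4,  2.6,   14, 30.1,  3.3,   29, 28.7,  1.5,   51, 28.6,  2.1
  )
  m <- matrix(tab, ncol = 13, byrow = TRUE)
  traits <- as.character(m[, 1])
  species <- c("A", "G", "J", "P")
  out <- do.call(rbind, lapply(seq_along(species), function(i) {
    cols <- 1 + (i - 1) * 3 + 1:3
    data.frame(group = species[i], trait = traits,
               n = as.integer(m[, cols[1]]),
               mean = as.numeric(m[, cols[2]]),
               sd = as.numeric(m[, cols[3]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Published reference summaries for the three analysed hybrid classes
#'
#' Sample size, mean, and SD for the hybrid groups AH (C. aurita x
#' Callithrix sp.), PJ (C. penicillata x C. jacchus), and PG
#' (C. penicillata x C. geoffroyi), as printed in the source study's
#' hybrid summary tables. Same units as [reference_species_summaries()].
#'
#' @return A data.frame with columns `group`, `trait`, `n`, `mean`, `sd`.
#' @export
reference_hybrid_summaries <- function() {
  mk <- function(group, n, mean, sd) {
    data.frame(group = group, trait = trait_names(), n = as.integer(n),
               mean = mean, sd = sd, stringsAsFactors = FALSE)
  }
  rbind(
    mk("AH",
       n    = c(9, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9),
       mean = c(21.4, 6.4, 38.8, 57.9, 5.2, 39.0, 5.2, 32.6, 26.3, 29.7,
                7.2, 408.1, 30.3),
       sd   = c(1.9, 0.6, 3.6, 4.5, 0.5, 3.7, 0.8, 4.8, 12.4, 3.6, 0.7,
                39.6, 3.0)),
    mk("PJ",
       n    = c(54, 54, 49, 54, 54, 50, 54, 54, 53, 52, 54, 53, 53),
       mean = c(21.3, 5.8, 39.2, 54.4, 4.6, 34.4, 4.7, 28.9, 23.7, 28.7,
                6.7, 317.9, 29.1),
       sd   = c(2.7, 0.6, 3.1, 5.1, 0.5, 3.6, 0.7, 2.2, 4.2, 2.4, 0.6,
                73.2, 2.4)),
    mk("PG",
       n    = c(18, 18, 18, 16, 18, 9, 18, 18, 18, 18, 18, 18, 18),
       mean = c(21.4, 6.6, 37.7, 53.3, 4.8, 36.8, 5.1, 29.8, 22.7, 30.7,
                7.1, 355.8, 30.3),
       sd   = c(0.9, 0.6, 3.7, 3.2, 0.4, 3.2, 0.4, 2.2, 2.9, 1.6, 0.4,
                27.8, 1.2))
  )
}

#' Reference study design: group sizes and hybrid plan
#'
#' `reference_group_sizes()` gives the number of sampled adults per taxon in
#' the reference study (209 individuals over 8 taxa). `reference_plan()`
#' gives the hybrid-to-putative-parental-pair mapping used throughout: PJ is
#' evaluated against (J, P), PG against (G, P), and AH — whose exact
#' parental species cannot be determined — against all pairings of A with a
#' jacchus-group species present in the sample: (A, J), (A, P), (A, G).
#'
#' @return `reference_group_sizes()`: named integer vector.
#'   `reference_plan()`: named list of two-column character matrices.
#' @export
reference_group_sizes <- function() {
  c(A = 27L, AH = 9L, CC = 2L, G = 14L, J = 30L, P = 55L, PG = 18L, PJ = 54L)
}

#' @rdname reference_group_sizes
#' @export
reference_plan <- function() {
  list(
    PJ = matrix(c("J", "P"), ncol = 2, byrow = TRUE),
    PG = matrix(c("G", "P"), ncol = 2, byrow = TRUE),
    AH = matrix(c("A", "J", "A", "P", "A", "G"), ncol = 2, byrow = TRUE)
  )
}

#' Published between-species mitogenomic distances
#'
#' The reference study's between-group mean mitogenomic distances
#' (substitutions/site) for the four species, used as generative inputs for
#' the sequence simulator's default scenarios.
#'
#' @return A symmetric 4x4 matrix with zero diagonal.
#' @export
reference_distances <- function() {
  sp <- c("A", "G", "J", "P")
  d <- matrix(0, 4, 4, dimnames = list(sp, sp))
  d["A", "G"] <- d["G", "A"] <- 0.059
  d["A", "J"] <- d["J", "A"] <- 0.060
  d["A", "P"] <- d["P", "A"] <- 0.059
  d["G", "J"] <- d["J", "G"] <- 0.018
  d["G", "P"] <- d["P", "G"] <- 0.018
  d["J", "P"] <- d["P", "J"] <- 0.014
  d
}
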