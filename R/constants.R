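#' Canonical trait and taxon vocabulary
#'
#' The pipeline works on 13 morphometric traits: body weight plus 12 linear
#' distances. Six limb measurements are taken on both sides and averaged per
#' individual before analysis; the remaining traits are single measurements.
#' Taxon codes follow the field's convention for these marmosets: four
#' species (A, G, J, P) and four hybrid classes (AH, PJ, PG, CC).
#'
#' @format `trait_names()` returns the 13 canonical trait keys in table
#'   order; `bilateral_traits()` the six left/right traits;
#'   `unilateral_traits()` the rest (including weight); `trait_units()` a
#'   named character vector of units (g, cm, mm); `taxon_codes()` the eight
#'   recognized taxon codes.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
trait_names <- function() {
  c("BODY", "FEMUR", "FO", "FOOT", "FOREARM", "HAND", "HUMERUS",
    "IC", "JAW", "TAIL", "TIBIA", "WEIGHT", "ZYG")
}

#' @rdname vocabulary
#' @export
bilateral_traits <- function() {
  c("HUMERUS", "FOREARM", "FEMUR", "TIBIA", "HAND", "FOOT")
}

#' @rdname vocabulary
#' @export
unilateral_traits <- function() {
  setdiff(trait_names(), bilateral_traits())
}

#' @rdname vocabulary
#' @export
trait_units <- function() {
  c(BODY = "cm", FEMUR = "cm", FO = "mm", FOOT = "mm", FOREARM = "cm",
    HAND = "mm", HUMERUS = "cm", IC = "mm", JAW = "mm", TAIL = "cm",
    TIBIA = "cm", WEIGHT = "g", ZYG = "mm")
}

#' @rdname vocabulary
#' @export
taxon_codes <- function() {
  c("A", "G", "J", "P", "AH", "PJ", "PG", "CC")
}

# metadata columns expected in the raw trait table
.meta_columns <- function() {
  c("Individual", "Taxon", "Sex", "Age", "Site")
}

# raw-file columns: unilateral traits as-is, bilateral as _L/_R pairs
.raw_trait_columns <- function() {
  bl <- bilateral_traits()
  c(unilateral_traits(), paste0(rep(bl, each = 2), c("_L", "_R")))
}
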