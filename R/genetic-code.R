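# Standard genetic code tables and the GeneticCode container.
#
# Codons are indexed in fixed lexicographic order (AAA..TTT) everywhere in
# the package so that count vectors, RSCU vectors and file outputs are
# reproducible and comparable across runs.

BASES <- c("A", "C", "G", "T")

#' The 64 codons in lexicographic order
#'
#' Fixed codon ordering (AAA, AAC, ..., TTT) used for every count vector and
#' matrix column in the package.
#' @return Character vector of length 64.
#' @export
#' @examples
#' head(codonOrder())
codonOrder <- function() CODONS

CODONS <- {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> one-letter amino acid, "*" for stop (standard code, table 1)
AA_OF <- {
  aa <- as.character(Biostrings::GENETIC_CODE[CODONS])
  names(aa) <- CODONS
  aa
}

SENSE_CODONS <- CODONS[AA_OF != "*"]

# The 59 "informative" codons: sense codons excluding the two
# single-codon families (Met/ATG, Trp/TGG). These carry all synonymous
# usage information and are the coordinates of RSCU vectors.
INFORMATIVE_CODONS <- setdiff(SENSE_CODONS, c("ATG", "TGG"))

# amino acid -> member codons (synonymous family)
FAMILIES <- split(SENSE_CODONS, AA_OF[SENSE_CODONS])

FAMILY_SIZE_BY_AA <- vapply(FAMILIES, length, integer(1))

# per-codon family size (degeneracy of its amino acid)
FAMILY_SIZE <- FAMILY_SIZE_BY_AA[AA_OF[SENSE_CODONS]]
names(FAMILY_SIZE) <- SENSE_CODONS

#' Genetic code container
#'
#' Holds the codon-to-amino-acid map, the partition of sense codons into
#' synonymous families, and the degeneracy class of each family. Only the
#' standard code (NCBI table 1) is shipped; the class exists so the mapping
#' travels with results and can be validated.
#'
#' @slot codonToAA Named character vector over all 64 codons; \code{"*"}
#'   marks stop codons.
#' @slot families Named list, amino acid -> character vector of codons.
#' @slot degeneracy Named integer vector, amino acid -> family size.
#' @export
setClass("GeneticCode",
  representation(codonToAA = "character",
                 families  = "list",
                 degeneracy = "integer"))

setValidity("GeneticCode", function(object) {
  msg <- character(0)
  if (length(object@codonToAA) != 64L)
    msg <- c(msg, "codonToAA must cover all 64 codons")
  stops <- sort(names(object@codonToAA)[object@codonToAA == "*"])
  if (!identical(stops, STOP_CODONS))
    msg <- c(msg, "stop codons must be TAA, TAG, TGA")
  if (sum(object@codonToAA != "*") != 61L)
    msg <- c(msg, "there must be exactly 61 sense codons")
  census <- table(factor(object@degeneracy, levels = c(1, 2, 3, 4, 6)))
  if (!identical(as.integer(census), c(2L, 9L, 1L, 5L, 3L)))
    msg <- c(msg, "degeneracy census must be {1:2, 2:9, 3:1, 4:5, 6:3}")
  memb <- unlist(object@families, use.names = FALSE)
  if (anyDuplicated(memb) || length(memb) != 61L)
    msg <- c(msg, "every sense codon must belong to exactly one family")
  if (length(msg)) msg else TRUE
})

#' Standard genetic code
#'
#' @return A validated \linkS4class{GeneticCode} for the standard nuclear
#'   code.
#' @export
#' @examples
#' gc <- standardGeneticCode()
#' degeneracy(gc)[["L"]]  # Leu is six-fold degenerate
standardGeneticCode <- function() {
  new("GeneticCode",
      codonToAA = AA_OF,
      families = FAMILIES,
      degeneracy = FAMILY_SIZE_BY_AA)
}

#' @describeIn GeneticCode-class Amino-acid degeneracy (family sizes).
#' @param object A \code{GeneticCode}.
#' @export
setGeneric("degeneracy", function(object) standardGeneric("degeneracy"))

#' @export
setMethod("degeneracy", "GeneticCode", function(object) object@degeneracy)

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode (standard): 61 sense codons, 3 stops,",
      length(object@families), "families\n")
})

# --- internal codon feature tables (position bases, GC flags) -------------

codonBase <- function(pos) substr(CODONS, pos, pos)

.POS_BASE <- cbind(p1 = codonBase(1), p2 = codonBase(2), p3 = codonBase(3))
rownames(.POS_BASE) <- CODONS

.IS_GC <- matrix(.POS_BASE %in% c("G", "C"), ncol = 3,
                 dimnames = list(CODONS, c("p1", "p2", "p3")))

# third-position bases silently available to each family: the set of bases
# occupied by the family's codons at position 3
.FAMILY_P3_BASES <- lapply(FAMILIES, function(cs) unique(substr(cs, 3, 3)))
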