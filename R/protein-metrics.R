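# Protein-level metrics: GRAVY, aromaticity, isoelectric point, molecular
# weight. Constant tables are bundled here so results are bit-exact and
# versioned with the package.

# Kyte-Doolittle hydropathy
.KD <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# average residue masses (Da); water added once per chain
.RESIDUE_MASS <- c(A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                   C = 103.1388, E = 129.1155, Q = 128.1307, G =  57.0519,
                   H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                   M = 131.1926, F = 147.1766, P =  97.1167, S =  87.0782,
                   T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
.WATER_MASS <- 18.0153

# Lehninger-style pKa set used for the charge model
.PKA <- list(nterm = 9.69, cterm = 2.34,
             D = 3.65, E = 4.25, C = 8.33, Y = 10.07,
             H = 6.00, K = 10.53, R = 12.48)

.residueCounts <- function(protein) {
  if (nchar(protein) == 0L) stop("empty protein")
  res <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(res), names(.KD))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  table(factor(res, levels = names(.KD)))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Negative values
#' indicate hydrophilic proteins.
#'
#' @param protein Character vector of amino-acid strings.
#' @return Numeric vector of GRAVY scores.
#' @export
#' @examples
#' gravy("III")  # 4.5
gravy <- function(protein) {
  vapply(protein, function(p) {
    cnt <- .residueCounts(p)
    sum(cnt * .KD) / sum(cnt)
  }, numeric(1), USE.NAMES = !is.null(names(protein)))
}

#' Aromaticity (AROMO)
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp).
#'
#' @inheritParams gravy
#' @return Numeric vector in \code{[0, 1]}.
#' @export
aromo <- function(protein) {
  vapply(protein, function(p) {
    cnt <- .residueCounts(p)
    sum(cnt[c("F", "Y", "W")]) / sum(cnt)
  }, numeric(1), USE.NAMES = !is.null(names(protein)))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch charge over the termini and the ionizable side
#' chains (D, E, C, Y, K, R, H) using the bundled pKa table.
#'
#' @param protein Amino-acid string.
#' @param pH pH value(s).
#' @return Net charge (elementary charges), vectorized over \code{pH}.
#' @export
netCharge <- function(protein, pH) {
  cnt <- .residueCounts(protein)
  pos <- c(nterm = 1, K = unname(cnt["K"]), R = unname(cnt["R"]),
           H = unname(cnt["H"]))
  neg <- c(cterm = 1, D = unname(cnt["D"]), E = unname(cnt["E"]),
           C = unname(cnt["C"]), Y = unname(cnt["Y"]))
  vapply(pH, function(x) {
    p <- sum(vapply(names(pos), function(r)
      pos[[r]] / (1 + 10^(x - .PKA[[r]])), numeric(1)))
    n <- sum(vapply(names(neg), function(r)
      neg[[r]] / (1 + 10^(.PKA[[r]] - x)), numeric(1)))
    p - n
  }, numeric(1))
}

#' Isoelectric point
#'
#' The pH at which \code{\link{netCharge}} crosses zero, found by bisection
#' on \code{[0, 14]} to a tolerance of 1e-4 pH units. The net charge is
#' strictly decreasing in pH, so the root is unique.
#'
#' @inheritParams gravy
#' @return Numeric vector of pI values (pH units).
#' @export
#' @examples
#' isoelectricPoint("KKKK") > isoelectricPoint("DDDD")
isoelectricPoint <- function(protein) {
  vapply(protein, function(p) {
    lo <- 0; hi <- 14
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (netCharge(p, mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = !is.null(names(protein)))
}

#' Molecular weight
#'
#' Sum of average residue masses plus one water, in kilodaltons.
#'
#' @inheritParams gravy
#' @return Numeric vector of masses (kDa).
#' @export
#' @examples
#' molecularWeight("G")  # 0.0750672 kDa
molecularWeight <- function(protein) {
  vapply(protein, function(p) {
    cnt <- .residueCounts(p)
    (sum(cnt * .RESIDUE_MASS) + .WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = !is.null(names(protein)))
}
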