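# Nucleotide composition metrics by codon position.

# indicator matrices over the 59 synonymous (informative) codons
.X3S_TABLES <- local({
  inf <- INFORMATIVE_CODONS
  p3 <- substr(inf, 3, 3)
  fam <- AA_OF[inf]
  num <- sapply(BASES, function(b) as.numeric(p3 == b))
  # denominator indicator: codon's family offers base b at position 3
  den <- sapply(BASES, function(b)
    as.numeric(vapply(fam, function(a) b %in% .FAMILY_P3_BASES[[a]],
                      logical(1))))
  rownames(num) <- rownames(den) <- inf
  list(num = num, den = den)
})

#' Per-gene nucleotide composition
#'
#' Computes overall and positional GC content plus silent-site statistics
#' from a codon count table (terminal stop codons are assumed excluded, as
#' \code{\link{codonCounts}} does by default):
#' \itemize{
#'   \item \code{gc1}, \code{gc2}, \code{gc3}: GC fraction at each codon
#'     position over \emph{all} sense codons, so that
#'     \code{gc = (gc1 + gc2 + gc3)/3} holds exactly, and
#'     \code{gc12 = (gc1 + gc2)/2}.
#'   \item \code{gc3s}: GC fraction at third positions of synonymous codons
#'     only (Met and Trp excluded).
#'   \item \code{a3s}, \code{t3s}, \code{g3s}, \code{c3s}: silent
#'     third-position base frequencies in the CodonW sense — the number of
#'     synonymous codons ending in base x divided by the number of
#'     synonymous codons whose family offers at least one x-ending codon.
#'     With \code{x3sSimple = TRUE} the simpler variant (fraction of all
#'     synonymous third positions) is returned instead.
#' }
#'
#' @param object A \linkS4class{CodonCounts}.
#' @param x3sSimple Use all synonymous codons as the x3s denominator.
#' @return Data frame with one row per gene: \code{gene_id}, \code{n_codons},
#'   \code{gc}, \code{gc1}, \code{gc2}, \code{gc3}, \code{gc12},
#'   \code{gc3s}, \code{a3s}, \code{t3s}, \code{g3s}, \code{c3s}, and
#'   overall base fractions \code{a}, \code{c}, \code{g}, \code{t}.
#' @export
#' @examples
#' cc <- codonCounts(c(g = "ATGGGGCCCTGA"))
#' composition(cc)[, c("gc1", "gc2", "gc3", "gc")]
composition <- function(object, x3sSimple = FALSE) {
  stopifnot(is(object, "CodonCounts"))
  m <- counts(object)[, SENSE_CODONS, drop = FALSE]
  n <- rowSums(m)
  if (any(n < 1L)) stop("composition undefined for genes with zero codons")

  gcPos <- .IS_GC[SENSE_CODONS, , drop = FALSE]
  gc1 <- as.vector(m %*% gcPos[, "p1"]) / n
  gc2 <- as.vector(m %*% gcPos[, "p2"]) / n
  gc3 <- as.vector(m %*% gcPos[, "p3"]) / n

  inf <- counts(object)[, INFORMATIVE_CODONS, drop = FALSE]
  nSyn <- rowSums(inf)
  gc3s <- ifelse(nSyn > 0,
                 as.vector(inf %*% .IS_GC[INFORMATIVE_CODONS, "p3"]) / nSyn,
                 NA_real_)

  x3sNum <- inf %*% .X3S_TABLES$num
  x3sDen <- if (x3sSimple) matrix(nSyn, nrow(inf), 4L)
            else inf %*% .X3S_TABLES$den
  x3s <- ifelse(x3sDen > 0, x3sNum / x3sDen, NA_real_)
  colnames(x3s) <- tolower(paste0(BASES, "3s"))

  baseCount <- sapply(BASES, function(b)
    as.vector(m %*% rowSums(.POS_BASE[SENSE_CODONS, , drop = FALSE] == b)))
  baseCount <- matrix(baseCount, nrow = nrow(m), ncol = 4L,
                      dimnames = list(NULL, tolower(BASES)))
  baseFrac <- baseCount / (3 * n)

  data.frame(gene_id = rownames(m), n_codons = n,
             gc = (gc1 + gc2 + gc3) / 3,
             gc1 = gc1, gc2 = gc2, gc3 = gc3,
             gc12 = (gc1 + gc2) / 2, gc3s = gc3s,
             x3s, baseFrac,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' CDS and protein length summary
#'
#' Extremes of CDS length (nt) and encoded protein length (aa, terminal
#' stop excluded) over a set of coding sequences.
#'
#' @param cds \code{DNAStringSet} or character vector of valid CDS.
#' @return List with \code{min_nt}, \code{max_nt}, \code{max_difference_nt},
#'   \code{min_aa}, \code{max_aa}.
#' @export
#' @examples
#' lengthSummary(c(a = "ATGAAATGA", b = "ATGAAAAAATGA"))
lengthSummary <- function(cds) {
  seqs <- .asNamedSeqs(cds)
  if (length(seqs) == 0L) stop("empty CDS set")
  nt <- nchar(seqs)
  stopifnot(all(nt %% 3L == 0L))
  last <- substr(seqs, nt - 2L, nt)
  # protein length = codons excluding the terminal stop, Met included
  aa <- nt %/% 3L - as.integer(last %in% STOP_CODONS)
  list(min_nt = min(nt), max_nt = max(nt),
       max_difference_nt = max(nt) - min(nt),
       min_aa = min(aa), max_aa = max(aa))
}
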