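# Codon counting: the CodonCounts matrix container and pooling.

#' Per-gene codon count matrix
#'
#' A genes-by-64 integer matrix of codon occurrences, with columns fixed in
#' lexicographic codon order (\code{\link{codonOrder}}). This is the
#' substrate for every index in the package. Row names are gene
#' identifiers; pooled rows (species super-genes, expression databases)
#' carry the pool label.
#'
#' @slot counts Integer matrix, one row per gene, 64 codon columns.
#' @export
setClass("CodonCounts", representation(counts = "matrix"))

setValidity("CodonCounts", function(object) {
  m <- object@counts
  msg <- character(0)
  if (!identical(colnames(m), CODONS))
    msg <- c(msg, "columns must be the 64 codons in lexicographic order")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "rows must carry unique gene identifiers")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Count codons in coding sequences
#'
#' Tallies consecutive non-overlapping triplets of each CDS. With
#' \code{includeStop = FALSE} (default) a terminal stop codon is excluded
#' from the counts and from the codon total, matching the convention of all
#' downstream composition and index computations.
#'
#' @param cds \code{DNAStringSet} or named character vector of CDS
#'   (length divisible by 3).
#' @param includeStop Keep the terminal stop codon in the counts.
#' @return A \linkS4class{CodonCounts} object.
#' @export
#' @examples
#' cc <- codonCounts(c(g1 = "ATGAAAAAATGA"))
#' counts(cc)[, c("ATG", "AAA")]
#' nCodons(cc)  # 3: the terminal TGA is excluded
codonCounts <- function(cds, includeStop = FALSE) {
  seqs <- .asNamedSeqs(cds)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (any(nchar(seqs) %% 3L != 0L))
    stop("sequence length(s) not divisible by 3")
  m <- matrix(0L, nrow = length(seqs), ncol = 64L,
              dimnames = list(names(seqs), CODONS))
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]]) %/% 3L
    cod <- substring(seqs[[i]], 3L * seq_len(n) - 2L, 3L * seq_len(n))
    if (!includeStop && n > 0L && cod[n] %in% STOP_CODONS)
      cod <- cod[-n]
    m[i, ] <- tabulate(factor(cod, levels = CODONS), nbins = 64L)
  }
  new("CodonCounts", counts = m)
}

#' @describeIn CodonCounts-class The underlying counts matrix.
#' @param object A \code{CodonCounts}.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @export
setMethod("counts", "CodonCounts", function(object) object@counts)

#' @describeIn CodonCounts-class Gene identifiers (row names).
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))

#' @export
setMethod("geneIDs", "CodonCounts", function(object)
  rownames(object@counts))

#' @describeIn CodonCounts-class Total codons per gene.
#' @export
setGeneric("nCodons", function(object) standardGeneric("nCodons"))

#' @export
setMethod("nCodons", "CodonCounts", function(object)
  rowSums(object@counts))

setMethod("show", "CodonCounts", function(object) {
  cat("CodonCounts:", nrow(object@counts), "gene(s),",
      sum(object@counts), "codons total\n")
})

#' @export
setMethod("[", "CodonCounts", function(x, i, j, ..., drop = FALSE) {
  new("CodonCounts", counts = x@counts[i, , drop = FALSE])
})

#' Pool codon count tables
#'
#' Element-wise sum of the selected rows, e.g. to form species super-genes
#' or the high/low-expression databases used for optimal-codon
#' determination. Pooling is associative and commutative.
#'
#' @param object A \linkS4class{CodonCounts}.
#' @param label Row label of the pooled table.
#' @param rows Optional row subset (indices or gene ids); default all rows.
#' @return A single-row \code{CodonCounts}.
#' @export
setGeneric("poolCounts", function(object, label, rows = NULL)
  standardGeneric("poolCounts"))

#' @export
setMethod("poolCounts", "CodonCounts", function(object, label, rows = NULL) {
  m <- object@counts
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (nrow(m) == 0L) stop("cannot pool an empty set of genes")
  pooled <- matrix(as.integer(colSums(m)), nrow = 1,
                   dimnames = list(label, CODONS))
  new("CodonCounts", counts = pooled)
})
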