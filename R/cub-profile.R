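# The per-gene CUB profile table: one row per gene, every index the
# downstream analyses consume.

#' Per-gene CUB profile
#'
#' Computes the full per-gene index table: composition metrics
#' (\code{\link{composition}}), Wright's ENc, CAI, CBI and Fop against a
#' reference weight set, and protein metrics (GRAVY, AROMO, pI, MW,
#' length). When \code{ref} is omitted, weights are derived from the
#' data themselves: the pooled bottom-\code{k} genes by ENc (the putative
#' high-expression pool) define the reference — the only reproducible
#' default when no external reference organism is given.
#'
#' @param cds \code{DNAStringSet} or named character vector of valid CDS.
#' @param ref Optional \linkS4class{ReferenceWeights}.
#' @param k Pool size for the self-derived reference (default 5).
#' @return Data frame, one row per gene, with columns \code{gene_id},
#'   \code{length_nt}, \code{length_aa}, composition columns, \code{enc},
#'   \code{cai}, \code{cbi}, \code{fop}, \code{gravy}, \code{aromo},
#'   \code{pi}, \code{mw_kda}. The reference used is attached as
#'   \code{attr(x, "reference")}.
#' @export
#' @examples
#' set.seed(1)
#' d <- generateCDSSet(generatorConfig(nGenes = 12, seed = 7))
#' prof <- cubProfile(d$cds)
#' head(prof[, c("gene_id", "enc", "gc3s", "cai")])
cubProfile <- function(cds, ref = NULL, k = 5) {
  cc <- codonCounts(cds)
  comp <- composition(cc)
  encv <- enc(cc)

  if (is.null(ref)) {
    defined <- names(encv)[!is.na(encv)]
    kUse <- min(k, length(defined))
    if (kUse < 1L)
      stop("cannot derive reference weights: no gene has a defined ENc")
    ord <- defined[order(encv[defined], defined)]
    ref <- referenceWeights(
      poolCounts(cc, "self_high_expression", rows = ord[seq_len(kUse)]),
      label = "self_high_expression")
  }

  prot <- translateCDS(cds, strict = FALSE)
  out <- data.frame(
    gene_id = geneIDs(cc),
    length_nt = nchar(as.character(cds)),
    length_aa = nchar(prot),
    comp[, setdiff(names(comp), "gene_id")],
    enc = unname(encv),
    cai = unname(cai(cc, ref)),
    cbi = unname(cbi(cc, ref)),
    fop = unname(fop(cc, ref)),
    gravy = unname(gravy(prot)),
    aromo = unname(aromo(prot)),
    pi = unname(isoelectricPoint(prot)),
    mw_kda = unname(molecularWeight(prot)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "reference") <- ref
  out
}

#' Write a CUB profile table as TSV
#'
#' @param profile Data frame from \code{\link{cubProfile}}.
#' @param path Output path.
#' @param comments Optional '#'-prefixed header lines.
#' @export
writeProfileTSV <- function(profile, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  write.table(profile, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
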