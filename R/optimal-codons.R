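# Optimal codon determination from ENc-extreme gene pools.

#' ENc-extreme expression databases
#'
#' Pools of the k most and least biased genes by ENc, standing in for
#' high- and low-expression gene sets: genes with the lowest ENc (strongest
#' bias) form the putative high-expression database, genes with the
#' highest ENc the low-expression database.
#'
#' @slot highPool Single-row \linkS4class{CodonCounts}: pooled bottom-k
#'   ENc genes.
#' @slot lowPool Single-row \code{CodonCounts}: pooled top-k ENc genes.
#' @slot k Pool size.
#' @slot highMembers,lowMembers Gene ids in each pool.
#' @export
setClass("ExpressionDatabases",
  representation(highPool = "CodonCounts", lowPool = "CodonCounts",
                 k = "integer", highMembers = "character",
                 lowMembers = "character"))

setValidity("ExpressionDatabases", function(object) {
  msg <- character(0)
  if (length(intersect(object@highMembers, object@lowMembers)))
    msg <- c(msg, "high and low pools must be disjoint")
  if (length(object@highMembers) != object@k ||
      length(object@lowMembers) != object@k)
    msg <- c(msg, "each pool must have exactly k members")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExpressionDatabases", function(object) {
  cat("ExpressionDatabases: k =", object@k, "\n  high (low ENc):",
      paste(object@highMembers, collapse = ", "), "\n  low (high ENc): ",
      paste(object@lowMembers, collapse = ", "), "\n")
})

#' Build ENc-extreme expression databases
#'
#' Sorts genes by ENc (ascending, ties broken lexicographically by gene
#' id), pools the bottom \code{k} as the high-expression database and the
#' top \code{k} as the low-expression database.
#'
#' @param profiles Data frame with \code{gene_id} and \code{enc}.
#' @param object \linkS4class{CodonCounts} for the same genes.
#' @param k Genes per pool (default 5).
#' @return An \linkS4class{ExpressionDatabases}.
#' @export
buildExpressionDatabases <- function(profiles, object, k = 5) {
  stopifnot(is(object, "CodonCounts"),
            all(c("gene_id", "enc") %in% names(profiles)))
  ok <- profiles[!is.na(profiles$enc), ]
  if (nrow(ok) < 2 * k)
    stop("need at least 2k = ", 2 * k, " genes with defined ENc")
  ord <- ok$gene_id[order(ok$enc, ok$gene_id)]
  high <- ord[seq_len(k)]
  low <- rev(ord)[seq_len(k)]
  new("ExpressionDatabases",
      highPool = poolCounts(object, "high_expression", rows = high),
      lowPool = poolCounts(object, "low_expression", rows = low),
      k = as.integer(k), highMembers = high, lowMembers = low)
}

#' Optimal codon scan
#'
#' Applies the two-criterion definition over the 59 informative codons: a
#' codon is optimal when its RSCU exceeds 1 in \emph{both} the high- and
#' low-expression databases and the difference
#' \code{delta = RSCU_high - RSCU_low} reaches the threshold (default
#' 0.08, inclusive; set \code{inclusive = FALSE} for a strict
#' inequality). Codons whose family is absent from either pool are marked
#' non-evaluable (\code{NA}).
#'
#' @param db An \linkS4class{ExpressionDatabases}.
#' @param deltaThreshold Minimum RSCU difference (default 0.08).
#' @param inclusive Treat the threshold as \code{>=} (default) or \code{>}.
#' @return Data frame with one row per informative codon: \code{codon},
#'   \code{aa}, \code{rscu_high}, \code{rscu_low}, \code{delta},
#'   \code{high_frequency} (RSCU_high > 1), \code{optimal}. The optimal
#'   set is also attached as \code{attr(x, "optimal")}.
#' @export
optimalCodonScan <- function(db, deltaThreshold = 0.08, inclusive = TRUE) {
  stopifnot(is(db, "ExpressionDatabases"))
  rh <- rscu(db@highPool)[1, ]
  rl <- rscu(db@lowPool)[1, ]
  delta <- rh - rl
  meets <- if (inclusive) delta >= deltaThreshold else delta > deltaThreshold
  optimal <- !is.na(rh) & !is.na(rl) & rh > 1 & rl > 1 & meets
  out <- data.frame(
    codon = INFORMATIVE_CODONS,
    aa = unname(AA_OF[INFORMATIVE_CODONS]),
    rscu_high = unname(rh), rscu_low = unname(rl),
    delta = unname(delta),
    high_frequency = unname(!is.na(rh) & rh > 1),
    optimal = unname(optimal),
    stringsAsFactors = FALSE)
  attr(out, "optimal") <- out$codon[out$optimal]
  out
}

.toDNA <- function(codons) toupper(chartr("Uu", "Tt", codons))

#' Cross-species optimal codon summary
#'
#' Union of per-species optimal codon sets, per-codon species membership,
#' and a tally of third-position bases across the union. Codon names may
#' be given in RNA style (U for T).
#'
#' @param results Named list: species -> optimal codon scan result (from
#'   \code{\link{optimalCodonScan}}) or plain character vector of codons.
#' @return List with \code{union} (sorted codons, DNA alphabet),
#'   \code{membership} (logical matrix codon x species),
#'   \code{ending_base} (named integer tally over A/T/G/C), and
#'   \code{n_union}.
#' @export
crossSpeciesSummary <- function(results) {
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  sets <- lapply(results, function(r) {
    if (is.data.frame(r)) r <- attr(r, "optimal")
    .toDNA(as.character(r))
  })
  u <- sort(unique(unlist(sets)))
  membership <- sapply(sets, function(s) u %in% s)
  membership <- matrix(membership, nrow = length(u),
                       dimnames = list(u, names(results)))
  ends <- substr(u, 3, 3)
  tally <- vapply(c("A", "T", "G", "C"), function(b) sum(ends == b),
                  integer(1))
  list(union = u, membership = membership, ending_base = tally,
       n_union = length(u))
}
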