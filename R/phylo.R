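# Distance-based phylogenetics: p-distances on aligned CDS,
# neighbor-joining, bootstrap support, Newick output. Tree algebra is
# delegated to 'ape'; this module fixes the conventions (gap handling,
# branch-length clamping, seeding) used throughout the package.

.alignmentMatrix <- function(aln) {
  seqs <- toupper(.asNamedSeqs(aln))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("aligned sequences must have equal length")
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

#' Pairwise p-distances on an alignment
#'
#' Proportion of differing sites between aligned nucleotide sequences.
#' With \code{"complete_deletion"} (default) every column containing a gap
#' or ambiguous base in \emph{any} sequence is removed before comparison;
#' with \code{"pairwise_deletion"} only the columns unusable for a given
#' pair are skipped.
#'
#' @param aln Aligned sequences: \code{DNAStringSet}, named character
#'   vector, or character matrix (rows = sequences).
#' @param gapMode \code{"complete_deletion"} or \code{"pairwise_deletion"}.
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
#' @examples
#' pDistance(c(a = "ACGT", b = "ACGA"))["a", "b"]  # 0.25
pDistance <- function(aln,
                      gapMode = c("complete_deletion",
                                  "pairwise_deletion")) {
  gapMode <- match.arg(gapMode)
  m <- if (is.matrix(aln)) aln else .alignmentMatrix(aln)
  usable <- matrix(m %in% BASES, nrow(m), ncol(m))
  if (gapMode == "complete_deletion") {
    keep <- colSums(usable) == nrow(m)
    if (!any(keep)) stop("no usable columns after complete deletion")
    m <- m[, keep, drop = FALSE]
    usable <- usable[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- usable[i, ] & usable[j, ]
    if (!any(ok)) stop("no usable columns for pair ", i, ",", j)
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via \code{\link[ape]{nj}}) on a symmetric
#' distance matrix. Negative branch lengths, which NJ can produce on
#' non-additive matrices, are clamped to zero; the total clamped length is
#' recorded in \code{attr(tree, "clamped")}.
#'
#' @param dm Symmetric numeric matrix with zero diagonal (n >= 3).
#' @return An unrooted \code{phylo} tree.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tree <- ape::nj(as.dist(dm))
  neg <- tree$edge.length < 0
  clamped <- -sum(tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Neighbor-joining with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement \code{replicates} times, rebuilding the tree each time.
#' The support of each internal edge is the percentage of replicate trees
#' containing the same bipartition, attached as node labels. Replicates
#' with no usable columns are redrawn (and counted in
#' \code{attr(tree, "resampled")}).
#'
#' @param aln Aligned sequences (>= 4), as in \code{\link{pDistance}}.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed; required, so runs are reproducible.
#' @param gapMode Passed to \code{\link{pDistance}}.
#' @return The full-data \code{phylo} tree with \code{node.label} holding
#'   support percentages (root label empty).
#' @export
bootstrapSupport <- function(aln, replicates = 1000, seed,
                             gapMode = c("complete_deletion",
                                         "pairwise_deletion")) {
  gapMode <- match.arg(gapMode)
  if (missing(seed)) stop("a seed is required for bootstrapping")
  m <- if (is.matrix(aln)) aln else .alignmentMatrix(aln)
  if (nrow(m) < 4L) stop("need at least 4 sequences")
  # taxon-order-invariant contract: work in sorted taxon order
  m <- m[order(rownames(m)), , drop = FALSE]
  full <- njTree(pDistance(m, gapMode))
  set.seed(seed)
  resampled <- 0L
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    repeat {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      t <- tryCatch(njTree(pDistance(m[, cols, drop = FALSE], gapMode)),
                    error = function(e) NULL)
      if (!is.null(t)) break
      resampled <- resampled + 1L
    }
    reps[[b]] <- t
  }
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(full, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- round(100 * cnt / replicates, 1)
  support[1] <- NA  # root pseudo-node of an unrooted tree
  full$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(full, "resampled") <- resampled
  full
}

#' Write a tree as Newick
#'
#' Standard single-line Newick with bootstrap supports as internal node
#' labels and branch lengths rounded to 6 significant digits; safe for
#' parse round-trips with \code{\link[ape]{read.tree}}.
#'
#' @param tree A \code{phylo} object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  tree$edge.length <- signif(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
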