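# RSCU-matrix construction, PCA, and hierarchical clustering of genes and
# species super-genes.

#' Build an RSCU matrix
#'
#' Aligns per-gene RSCU vectors into a rows-by-59-codons matrix and
#' resolves missing families (amino acids unobserved in a gene) per
#' policy: \code{"family_mean"} imputes the column mean over observed
#' rows, \code{"zero"} imputes 0, \code{"drop_rows"} removes incomplete
#' rows. Columns missing in every row are dropped with a warning.
#'
#' @param rscuValues Matrix from \code{\link{rscu}} (genes x 59, NA marks
#'   missing families).
#' @param impute One of \code{"family_mean"}, \code{"drop_rows"},
#'   \code{"zero"}.
#' @param metadata Optional data frame keyed by \code{gene_id} (carried
#'   through as \code{attr(x, "metadata")}).
#' @return Numeric matrix without NAs; the policy used is recorded in
#'   \code{attr(x, "impute")}.
#' @export
buildRSCUMatrix <- function(rscuValues,
                            impute = c("family_mean", "drop_rows", "zero"),
                            metadata = NULL) {
  impute <- match.arg(impute)
  m <- as.matrix(rscuValues)
  stopifnot(nrow(m) >= 2L)
  allMissing <- colSums(!is.na(m)) == 0L
  if (any(allMissing)) {
    warning("dropping all-missing codon column(s): ",
            paste(colnames(m)[allMissing], collapse = ", "))
    m <- m[, !allMissing, drop = FALSE]
  }
  if (anyNA(m)) {
    if (impute == "drop_rows") {
      m <- m[complete.cases(m), , drop = FALSE]
    } else if (impute == "zero") {
      m[is.na(m)] <- 0
    } else {
      for (j in which(colSums(is.na(m)) > 0)) {
        mu <- mean(m[, j], na.rm = TRUE)
        m[is.na(m[, j]), j] <- mu
      }
    }
  }
  attr(m, "impute") <- impute
  if (!is.null(metadata)) attr(m, "metadata") <- metadata
  m
}

#' PCA of RSCU vectors
#'
#' Principal component analysis of the centered (by default unscaled) RSCU
#' matrix — RSCU is already normalized within families, so variance
#' scaling would mostly inflate rare-family noise. Loading signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param m Matrix from \code{\link{buildRSCUMatrix}} (rows >= 3).
#' @param nComponents Components to report (default 2).
#' @param scale. Also scale columns to unit variance.
#' @return List of class \code{"cubPCA"}: \code{scores},
#'   \code{loadings}, \code{explained} (variance fractions, all
#'   components).
#' @export
rscuPCA <- function(m, nComponents = 2, scale. = FALSE) {
  stopifnot(nrow(m) >= 3L)
  keep <- apply(m, 2, stats::var) > 0 | !scale.
  fit <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  nComponents <- min(nComponents, ncol(fit$rotation))
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- fit$x[, seq_len(nComponents), drop = FALSE]
  loadings <- fit$rotation[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(nComponents)) {  # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained = explained), class = "cubPCA")
}

#' @export
print.cubPCA <- function(x, ...) {
  cat("PCA of RSCU:", nrow(x$scores), "rows;",
      "PC1", sprintf("%.1f%%", 100 * x$explained[1]),
      "PC2", sprintf("%.1f%%", 100 * x$explained[2]), "\n")
  invisible(x)
}

#' Hierarchical clustering of RSCU vectors
#'
#' Agglomerative clustering with squared Euclidean dissimilarity and
#' between-groups (average) linkage — the "intergroup linkage" of common
#' statistics packages. Returns the standard \code{hclust} object.
#'
#' @param m Matrix from \code{\link{buildRSCUMatrix}} (rows >= 2).
#' @return An \code{hclust} object.
#' @export
rscuCluster <- function(m) {
  stopifnot(nrow(m) >= 2L)
  d <- dist(m)^2
  hclust(d, method = "average")
}

#' Serialize a cluster tree as Newick
#'
#' @param hc An \code{hclust} object.
#' @return Single-line Newick string with branch lengths.
#' @export
clusterNewick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Species super-gene clustering
#'
#' Pools the codon counts of all genes of each species into one composite
#' ("super-gene") count table, computes RSCU per species, and clusters the
#' species. Species with zero genes are excluded with a message.
#'
#' @param object \linkS4class{CodonCounts} over all genes.
#' @param species Character vector (or factor) of species labels, one per
#'   gene.
#' @return An \code{hclust} over species.
#' @export
speciesSupergeneCluster <- function(object, species) {
  stopifnot(is(object, "CodonCounts"),
            length(species) == nrow(counts(object)))
  species <- as.character(species)
  sp <- unique(species)
  sp <- sp[vapply(sp, function(s) sum(species == s) > 0, logical(1))]
  if (length(sp) < 2L) stop("need at least 2 species with genes")
  pooled <- do.call(rbind, lapply(sp, function(s)
    counts(poolCounts(object, s, rows = which(species == s)))))
  cc <- new("CodonCounts", counts = pooled)
  m <- buildRSCUMatrix(rscu(cc), impute = "family_mean")
  rscuCluster(m)
}
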