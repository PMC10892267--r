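# Synthetic CDS generator with planted codon preferences.
#
# The generator emulates the statistical structure the analyses assume:
# CDS lengths within a realistic small heat-shock-protein range, AT-rich
# composition, per-gene codon bias of varying strength towards subfamily
# specific preferred codons, optional GC drift (at silent third positions
# only, or across all positions), and expression levels that increase with
# bias strength so that FPKM correlates negatively with ENc.

# default amino-acid frequencies: typical globular plant protein
.DEFAULT_AA_FREQ <- local({
  f <- c(A = 7.9, R = 5.0, N = 4.4, D = 5.4, C = 1.6, Q = 3.5, E = 6.5,
         G = 7.0, H = 2.3, I = 5.4, L = 9.4, K = 6.4, M = 2.3, F = 4.5,
         P = 4.9, S = 7.9, T = 5.3, W = 1.1, Y = 3.1, V = 6.9)
  f / sum(f)
})

#' Configuration for the synthetic CDS generator
#'
#' Defaults describe the study conditions the package is tested under:
#' 140 genes, CDS lengths 393-1116 nt, four species, twelve subfamilies,
#' per-gene selection strength s ~ Uniform(0, S) with S = 3, no GC drift,
#' and log-linear expression in s.
#'
#' @param nGenes Number of genes.
#' @param lengthRange CDS length range in nt (multiples of 3, including
#'   start and stop codons).
#' @param biasStrength S: per-gene preference strength s is drawn from
#'   Uniform(0, S). s is the log-odds boost of the subfamily's preferred
#'   codon within its family.
#' @param baselinePreference Background log-odds boost of the preferred
#'   codon shared by \emph{every} gene, on top of the per-gene s. Real
#'   genomes keep a mild genome-wide preference for their optimal codons
#'   even in weakly expressed genes; without it the classic
#'   "RSCU > 1 in both expression databases" criterion sits exactly on
#'   its RSCU = 1 boundary in the unbiased pool. Default 0.5 (mild).
#' @param gc3Drift Log-weight gamma on G/C bases; a scalar (same for all
#'   genes) or a length-2 range for per-gene Uniform draws.
#' @param driftScope \code{"third_position_only"} applies gamma to G/C at
#'   silent third positions inside families (amino-acid usage untouched);
#'   \code{"all_positions"} weights whole codons by their G+C count and
#'   lets amino-acid usage drift with it, emulating genome-wide mutation
#'   pressure.
#' @param aaFreq Named amino-acid frequency vector (20 residues).
#' @param nSpecies,nSubfamilies Number of species / subfamily labels.
#' @param expression List \code{a}, \code{b}, \code{sigma}:
#'   \code{log(FPKM) = a + b*s + Normal(0, sigma)} per condition.
#' @param conditions Condition names for the expression table.
#' @param seed Integer seed (mandatory; the generator is fully
#'   deterministic given the config).
#' @return List of class \code{"cubGeneratorConfig"}.
#' @export
generatorConfig <- function(nGenes = 140,
                            lengthRange = c(393, 1116),
                            biasStrength = 3,
                            baselinePreference = 0.5,
                            gc3Drift = 0,
                            driftScope = c("third_position_only",
                                           "all_positions"),
                            aaFreq = .DEFAULT_AA_FREQ,
                            nSpecies = 4,
                            nSubfamilies = 12,
                            expression = list(a = 3, b = 0.8, sigma = 0.5),
                            conditions = c("normal", "salinity", "drought"),
                            seed) {
  if (missing(seed)) stop("a seed is mandatory")
  driftScope <- match.arg(driftScope)
  stopifnot(length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2],
            all(lengthRange %% 3 == 0), nGenes >= 1,
            length(gc3Drift) %in% c(1L, 2L),
            setequal(names(aaFreq), names(.DEFAULT_AA_FREQ)),
            all(aaFreq >= 0), sum(aaFreq) > 0)
  structure(list(nGenes = nGenes, lengthRange = lengthRange,
                 biasStrength = biasStrength,
                 baselinePreference = baselinePreference,
                 gc3Drift = gc3Drift,
                 driftScope = driftScope,
                 aaFreq = aaFreq / sum(aaFreq),
                 nSpecies = nSpecies, nSubfamilies = nSubfamilies,
                 expression = expression, conditions = conditions,
                 seed = as.integer(seed)),
            class = "cubGeneratorConfig")
}

# one preferred codon per degenerate family per subfamily
.drawPreferredMap <- function(nSubfamilies) {
  degAA <- names(FAMILY_SIZE_BY_AA)[FAMILY_SIZE_BY_AA >= 2L]
  lapply(seq_len(nSubfamilies), function(s) {
    vapply(degAA, function(a) {
      fam <- FAMILIES[[a]]
      fam[sample.int(length(fam), 1L)]
    }, character(1))
  })
}

.geneCodonProbs <- function(cfg, sg, gammaG, preferred) {
  aa <- AA_OF[SENSE_CODONS]
  prefBoost <- as.numeric(SENSE_CODONS %in% preferred)
  s <- cfg$baselinePreference + sg
  if (cfg$driftScope == "third_position_only") {
    gcBoost <- as.numeric(.IS_GC[SENSE_CODONS, "p3"])
    w <- exp(s * prefBoost + gammaG * gcBoost)
    # normalize within families so amino-acid usage stays at aaFreq
    famTot <- tapply(w, aa, sum)[aa]
    p <- cfg$aaFreq[aa] * w / famTot
  } else {
    gcCount <- rowSums(.IS_GC[SENSE_CODONS, , drop = FALSE])
    w <- exp(s * prefBoost + gammaG * gcCount)
    k <- FAMILY_SIZE[SENSE_CODONS]
    p <- cfg$aaFreq[aa] / k * w
  }
  p / sum(p)
}

#' Generate a synthetic CDS dataset
#'
#' Draws, per gene: a CDS length, species and subfamily labels, a
#' selection strength s, and (if configured) a GC-drift weight; then
#' samples interior codons, prepends ATG and appends a stop codon, and
#' simulates per-condition FPKM from the expression model. Every emitted
#' CDS passes strict validation. The full generating truth (per-gene s and
#' gamma, the preferred codon map, the config) is returned so parameter
#' recovery can be tested.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @return List with \code{cds} (\code{DNAStringSet}), \code{expression}
#'   (long data frame \code{gene_id}, \code{condition}, \code{fpkm}),
#'   \code{metadata} (\code{gene_id}, \code{species}, \code{subfamily}),
#'   and \code{truth} (list).
#' @export
#' @examples
#' d <- generateCDSSet(generatorConfig(nGenes = 5, seed = 42))
#' nchar(as.character(d$cds))
generateCDSSet <- function(cfg) {
  stopifnot(inherits(cfg, "cubGeneratorConfig"))
  set.seed(cfg$seed)
  n <- cfg$nGenes
  ids <- sprintf("gene%03d", seq_len(n))
  lengths <- sample(seq(cfg$lengthRange[1], cfg$lengthRange[2], by = 3),
                    n, replace = TRUE)
  species <- sprintf("sp%02d", sample.int(cfg$nSpecies, n, replace = TRUE))
  subfam <- sample.int(cfg$nSubfamilies, n, replace = TRUE)
  sg <- runif(n, 0, cfg$biasStrength)
  gammaG <- if (length(cfg$gc3Drift) == 2L)
    runif(n, cfg$gc3Drift[1], cfg$gc3Drift[2])
  else rep(cfg$gc3Drift, n)
  prefMap <- .drawPreferredMap(cfg$nSubfamilies)

  seqs <- character(n)
  for (i in seq_len(n)) {
    nInterior <- lengths[i] %/% 3L - 2L
    p <- .geneCodonProbs(cfg, sg[i], gammaG[i], prefMap[[subfam[i]]])
    cod <- sample(SENSE_CODONS, nInterior, replace = TRUE, prob = p)
    seqs[i] <- paste0("ATG", paste(cod, collapse = ""),
                      sample(STOP_CODONS, 1L))
  }
  cds <- Biostrings::DNAStringSet(setNames(seqs, ids))

  expr <- do.call(rbind, lapply(cfg$conditions, function(cond) {
    data.frame(gene_id = ids, condition = cond,
               fpkm = exp(cfg$expression$a + cfg$expression$b * sg +
                            rnorm(n, 0, cfg$expression$sigma)),
               stringsAsFactors = FALSE)
  }))

  list(cds = cds,
       expression = expr,
       metadata = data.frame(gene_id = ids, species = species,
                             subfamily = sprintf("SF%02d", subfam),
                             stringsAsFactors = FALSE),
       truth = list(s = setNames(sg, ids), gamma = setNames(gammaG, ids),
                    preferred = prefMap, config = cfg))
}

#' Generate a mutation- or selection-regime dataset
#'
#' Two canonical regimes for the neutrality diagnostic:
#' \describe{
#'   \item{mutation}{GC drift across all codon positions and no planted
#'     selection — GC12 and GC3 co-vary, so the neutrality slope is high.}
#'   \item{selection}{per-gene codon preference plus GC drift confined to
#'     silent third positions — GC3 varies while GC12 stays put, so the
#'     slope is near zero and most genes fall below the expected ENc
#'     curve.}
#' }
#'
#' @param cfg A \code{\link{generatorConfig}}; its drift settings are
#'   overridden per regime.
#' @param regime \code{"mutation"} or \code{"selection"}.
#' @return As \code{\link{generateCDSSet}}; \code{truth$regime} records
#'   the regime.
#' @export
generateRegime <- function(cfg, regime = c("mutation", "selection")) {
  regime <- match.arg(regime)
  stopifnot(inherits(cfg, "cubGeneratorConfig"))
  if (regime == "mutation") {
    cfg$biasStrength <- 0
    cfg$baselinePreference <- 0
    cfg$gc3Drift <- c(-1.5, 1.5)
    cfg$driftScope <- "all_positions"
  } else {
    cfg$gc3Drift <- c(-1, 1)
    cfg$driftScope <- "third_position_only"
  }
  out <- generateCDSSet(cfg)
  out$truth$regime <- regime
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits FASTA (CDS), two TSVs (expression, metadata) and a JSON truth
#' file from which the dataset can be regenerated exactly.
#'
#' @param dataset Result of \code{\link{generateCDSSet}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
writeSyntheticData <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "cds.fa"),
             expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(dataset$cds, paths["fasta"])
  write.table(dataset$expression, paths["expression"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$metadata, paths["metadata"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Deterministic worked fixtures
#'
#' Small deterministic inputs used in worked examples and validation
#' tests, mirroring summary characteristics reported for small
#' heat-shock-protein (HSP20) gene families in crucifers:
#' \itemize{
#'   \item \code{cds}: two strictly valid CDS of 393 nt (130 aa) and
#'     1116 nt (371 aa), the extremes of the family's length range.
#'   \item \code{encTable}: a 140-gene ENc/GC3s table in which exactly 94
#'     genes fall in the weak-bias band (50-61] and none at or below 35.
#'   \item \code{speciesOptimal}: per-species optimal codon sets (RNA
#'     alphabet, as printed in the CUB literature) whose union has 12
#'     codons, with known sharing structure. These sets are a synthetic
#'     stand-in assembled from published per-species counts and shared
#'     codons; the assignment of the non-shared codons to species is
#'     arbitrary (the union and ending-base tally are not affected).
#' }
#'
#' @return List with \code{cds}, \code{encTable}, \code{speciesOptimal}.
#' @export
workedFixtures <- function() {
  interior <- c("GCT", "GAA", "AAG", "CTT", "GAT", "TCT")
  mkCDS <- function(nt) {
    nInt <- nt %/% 3L - 2L
    body <- rep_len(interior, nInt)
    paste0("ATG", paste(body, collapse = ""), "TGA")
  }
  cds <- Biostrings::DNAStringSet(c(cds393 = mkCDS(393L),
                                    cds1116 = mkCDS(1116L)))

  encTable <- data.frame(
    gene_id = sprintf("g%03d", 1:140),
    enc = c(seq(50.2, 60.8, length.out = 94),
            seq(35.5, 49.5, length.out = 46)),
    gc3s = seq(0.25, 0.65, length.out = 140),
    stringsAsFactors = FALSE)

  speciesOptimal <- list(
    A_thaliana = c("AAC", "GGU", "AGG", "CCA", "GAA", "GAG"),
    B_napus    = c("UAC"),
    B_rapa     = c("UAC", "AGA", "UGA"),
    C_sativa   = c("AAC", "GGU", "AGA", "GCU", "GUG", "UCU"))

  list(cds = cds, encTable = encTable, speciesOptimal = speciesOptimal)
}
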