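# RSCU matrix, PCA, hierarchical clustering.

rscuMatrixFor <- function(nGenes, cfgSeed = 67, ...) {
  d <- generateCDSSet(generatorConfig(nGenes = nGenes, seed = cfgSeed, ...))
  list(m = buildRSCUMatrix(rscu(codonCounts(d$cds))), data = d)
}

test_that("buildRSCUMatrix aligns rows and applies the impute policy", {
  cc <- codonCounts(c(a = "ATGAAAAAGTGA", b = "ATGAAAGGGTGA",
                      c = "ATGGGGGGCTGA"))
  r <- rscu(cc)
  # tiny genes leave many families unobserved in every row: those codon
  # columns are dropped with a warning
  expect_warning(m <- buildRSCUMatrix(r, impute = "family_mean"),
                 "all-missing")
  expect_equal(nrow(m), 3)
  # observed entries survive the round trip
  expect_equal(m["a", "AAA"], r["a", "AAA"])
  # gene 'a' lacks Gly: imputed with the column mean of observed rows
  expect_equal(m["a", "GGG"], mean(r[c("b", "c"), "GGG"]))
  z <- suppressWarnings(buildRSCUMatrix(r, impute = "zero"))
  expect_equal(z["a", "GGG"], 0)
  dr <- suppressWarnings(buildRSCUMatrix(r, impute = "drop_rows"))
  expect_lt(nrow(dr), 3)
  expect_warning(buildRSCUMatrix(r[, c("AAA", "AAG", "TTT")]),
                 "all-missing")
})

test_that("PCA explains a 1-D embedding with the leading component", {
  set.seed(71)
  direction <- rnorm(59)
  base <- rnorm(59)
  m <- t(vapply(seq(-2, 2, length.out = 10), function(t)
    base + t * direction, numeric(59)))
  colnames(m) <- paste0("c", 1:59); rownames(m) <- paste0("r", 1:10)
  p <- rscuPCA(m)
  expect_gt(p$explained[1], 0.999)
  expect_true(all(diff(p$explained) <= 1e-12))
})

test_that("PCA scores reproduce centered-data inner products", {
  mm <- rscuMatrixFor(20)
  m <- mm$m
  p <- rscuPCA(m, nComponents = min(dim(m)))
  xc <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(p$scores %*% t(p$scores)), unname(xc %*% t(xc)),
               tolerance = 1e-8)
  # row permutation leaves explained variance untouched
  p2 <- rscuPCA(m[sample(nrow(m)), ], nComponents = 2)
  expect_equal(p2$explained, p$explained, tolerance = 1e-9)
})

test_that("planted clusters separate along PC1", {
  cfgA <- generatorConfig(nGenes = 15, biasStrength = 6, nSubfamilies = 1,
                          seed = 73)
  cfgB <- generatorConfig(nGenes = 15, biasStrength = 6, nSubfamilies = 1,
                          seed = 74)  # different preferred codons
  dA <- generateCDSSet(cfgA); dB <- generateCDSSet(cfgB)
  cds <- c(setNames(as.character(dA$cds), paste0("A", 1:15)),
           setNames(as.character(dB$cds), paste0("B", 1:15)))
  m <- buildRSCUMatrix(rscu(codonCounts(cds)))
  p <- rscuPCA(m)
  a <- p$scores[1:15, 1]; b <- p$scores[16:30, 1]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("average-linkage clustering matches a brute-force oracle", {
  # nearest pair merges first
  m3 <- rbind(A = c(0, 0), B = c(1, 0), C = c(100, 0))
  hc3 <- rscuCluster(m3)
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))
  # identical rows merge at height zero
  m0 <- rbind(A = 1:5, B = 1:5, C = 6:10)
  expect_equal(rscuCluster(m0)$height[1], 0)

  set.seed(79)
  for (i in 1:5) {
    m <- matrix(rnorm(20 * 6), 20, dimnames = list(paste0("r", 1:20), NULL))
    hc <- rscuCluster(m)
    expect_true(all(diff(hc$height) >= -1e-9))
    coph <- as.matrix(stats::cophenetic(hc))
    oracle <- oracleAvgLinkCophenetic(m)
    expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-9)
  }
})

test_that("species super-genes cluster by shared codon preference", {
  # two identical species pools merge at height zero
  set.seed(83)
  seqs <- setNames(vapply(1:6, function(i) randomCDS(120), character(1)),
                   paste0("g", 1:6))
  cc2 <- codonCounts(c(seqs[1:3],
                       setNames(seqs[1:3], paste0("dup", 1:3))))
  hcDup <- speciesSupergeneCluster(cc2, rep(c("s1", "s2"), each = 3))
  expect_equal(hcDup$height[1], 0)

  # species sharing planted preferences pair before the divergent one:
  # split one preference regime across two species, add a third regime
  mk <- function(seed) generateCDSSet(
    generatorConfig(nGenes = 20, biasStrength = 6, nSubfamilies = 1,
                    seed = seed))
  shared <- mk(11); divergent <- mk(99)  # different preferred-codon maps
  csA <- as.character(shared$cds)
  cds <- c(setNames(csA[1:10], paste0("x", 1:10)),
           setNames(csA[11:20], paste0("y", 1:10)),
           setNames(as.character(divergent$cds), paste0("z", 1:20)))
  species <- rep(c("spX", "spY", "spZ"), c(10, 10, 20))
  hc <- speciesSupergeneCluster(codonCounts(cds), species)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # spX+spY merge first
})

test_that("genes cluster by subfamily rather than species", {
  d <- generateCDSSet(generatorConfig(nGenes = 60, biasStrength = 5,
                                      nSubfamilies = 3, nSpecies = 4,
                                      seed = 89))
  m <- buildRSCUMatrix(rscu(codonCounts(d$cds)))
  hc <- rscuCluster(m)
  groups <- stats::cutree(hc, k = 3)
  md <- d$metadata
  ariSub <- mclust::adjustedRandIndex(groups, md$subfamily)
  ariSpec <- mclust::adjustedRandIndex(groups, md$species)
  expect_gt(ariSub, ariSpec)
})
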