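# Selection-versus-mutation diagnostics.

test_that("the expected ENc curve evaluates exactly and is symmetric", {
  expect_equal(expectedENc(0.5), 60.5)
  expect_equal(expectedENc(0), 31)
  expect_equal(expectedENc(1), 32)
  expect_error(expectedENc(1.2), "\\[0, 1\\]")
  s <- seq(0, 1, by = 0.01)
  expect_equal(expectedENc(s) - s, expectedENc(1 - s) - (1 - s),
               tolerance = 1e-12)
})

test_that("ENc-GC3s classification partitions genes and flags the curve", {
  fx <- workedFixtures()
  res <- encGc3sAnalysis(fx$encTable)
  s <- res$summary
  expect_equal(s$n_strong, 0)
  expect_equal(s$n_weak, 94)
  expect_equal(s$n_strong + s$n_intermediate + s$n_weak, s$n_defined)
  expect_equal(s$pct_weak, 100 * 94 / 140, tolerance = 1e-9)

  onCurve <- data.frame(gene_id = "g", gc3s = 0.4,
                        enc = expectedENc(0.4))
  expect_equal(encGc3sAnalysis(onCurve)$points$position, "on")
})

test_that("selection-regime genes fall mostly below the expected curve", {
  d <- generateRegime(generatorConfig(nGenes = 150, seed = 17),
                      "selection")
  cc <- codonCounts(d$cds)
  prof <- data.frame(gene_id = geneIDs(cc), enc = unname(enc(cc)),
                     gc3s = composition(cc)$gc3s)
  res <- encGc3sAnalysis(prof)
  expect_gt(res$summary$n_below_curve, res$summary$n_defined / 2)
})

test_that("PR2 coordinates match third-position tallies", {
  # equal A3/T3 and G3/C3 -> center
  center <- codonCounts(c(g = paste0("ATG",
    "GGTGGAGGGGGC", "CCTCCACCGCCC", "TGA")))  # Gly+Pro, one each ending
  p <- pr2(center)
  expect_equal(p$x, 0.5)
  expect_equal(p$y, 0.5)

  # only T- and G-ending codons -> y = 0, x = 1
  tg <- codonCounts(c(g = paste0("ATG", "GGTGGG", "CCTCCG", "TGA")))
  ptg <- pr2(tg)
  expect_equal(ptg$x, 1)
  expect_equal(ptg$y, 0)

  set.seed(23)
  for (i in 1:10) {
    cv <- randomCountVector()
    p <- pr2(countsFromVector(cv))
    inf <- names(oracleRSCU(cv))
    b3 <- vapply(c("A", "T", "G", "C"), function(b)
      sum(cv[inf][substr(inf, 3, 3) == b]), numeric(1))
    expect_equal(p$x, unname(b3["G"] / (b3["G"] + b3["C"])),
                 tolerance = 1e-12)
    expect_equal(p$y, unname(b3["A"] / (b3["A"] + b3["T"])),
                 tolerance = 1e-12)
  }
  # fourfold-only scope stays within [0,1]
  pf <- pr2(countsFromVector(randomCountVector()), "fourfold_only")
  expect_true(pf$x >= 0 && pf$x <= 1 && pf$y >= 0 && pf$y <= 1)
})

test_that("neutrality regression recovers exact lines and reports
           mutation/selection percentages", {
  gc3 <- seq(0.2, 0.8, length.out = 20)
  prof <- data.frame(gc3 = gc3, gc12 = 0.10 * gc3 + 0.30)
  res <- neutralityRegression(prof)
  expect_equal(res$slope, 0.10, tolerance = 1e-9)
  expect_equal(res$pearson_r, 1, tolerance = 1e-9)
  expect_equal(res$mutation_pct + res$selection_pct, 100)

  prof2 <- data.frame(gc3 = gc3, gc12 = 0.1034 * gc3 + 0.2)
  res2 <- neutralityRegression(prof2)
  expect_equal(res2$mutation_pct, 10.34, tolerance = 1e-6)
  expect_equal(res2$selection_pct, 89.66, tolerance = 1e-6)

  # gene order does not change the fit
  perm <- prof[sample(nrow(prof)), ]
  expect_equal(neutralityRegression(perm)$slope, res$slope,
               tolerance = 1e-12)
  expect_error(neutralityRegression(data.frame(gc3 = rep(0.5, 5),
                                               gc12 = runif(5))),
               "variance")
})

test_that("correlationMatrix is symmetric with tiered stars", {
  set.seed(29)
  n <- 50
  x <- rnorm(n)
  prof <- data.frame(a = x, b = -x, c = x + rnorm(n, 0, 2),
                     d = rnorm(n), konst = rep(1, n))
  cm <- correlationMatrix(prof, c("a", "b", "c", "d", "konst"))
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1, na.rm = TRUE))
  expect_true(is.na(cm$r["a", "konst"]))
  expect_equal(cm$stars["a", "b"], "***")
  # star tiers follow the p-value
  expect_equal(unname(codonbias:::.starsFor(c(0.04, 0.009, 5e-4, 0.2))),
               c("*", "**", "***", ""))
})

test_that("GC and GC3 correlate under a planted third-position gradient", {
  d <- generateCDSSet(generatorConfig(nGenes = 120, gc3Drift = c(-1, 1),
                                      seed = 37))
  co <- composition(codonCounts(d$cds))
  cm <- correlationMatrix(co, c("gc", "gc3"))
  expect_gt(cm$r["gc", "gc3"], 0.5)
  expect_lt(cm$p["gc", "gc3"], 0.001)
})

test_that("expression correlation recovers exact and planted effects", {
  encv <- seq(40, 60, length.out = 25)
  prof <- data.frame(gene_id = paste0("g", 1:25), enc = encv)
  expr <- data.frame(gene_id = prof$gene_id, condition = "normal",
                     fpkm = -2 * encv + 150)
  res <- expressionCorrelation(prof, expr)
  normal <- res[res$condition == "normal", ]
  expect_equal(normal$pearson_r, -1, tolerance = 1e-9)
  expect_equal(normal$slope, -2, tolerance = 1e-9)
  # total = sum over conditions: single condition doubles against itself
  expr2 <- rbind(expr, transform(expr, condition = "stress"))
  res2 <- expressionCorrelation(prof, expr2)
  expect_equal(res2$slope[res2$condition == "total"], -4, tolerance = 1e-9)

  # permuted expression shows no correlation
  set.seed(43)
  d <- generateCDSSet(generatorConfig(nGenes = 100, seed = 43))
  e <- enc(codonCounts(d$cds))
  profd <- data.frame(gene_id = names(e), enc = unname(e))
  permuted <- d$expression
  for (cond in unique(permuted$condition)) {
    idx <- permuted$condition == cond
    permuted$fpkm[idx] <- sample(permuted$fpkm[idx])
  }
  rPerm <- expressionCorrelation(profd, permuted)
  expect_lt(max(abs(rPerm$pearson_r[rPerm$condition != "total"])), 0.2)

  # the planted expression model induces a negative correlation
  rTrue <- expressionCorrelation(profd, d$expression)
  expect_true(all(rTrue$pearson_r < 0))
})
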