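# p-distances, neighbor joining, bootstrap, Newick round trips.

test_that("p-distance matches site tallies under both gap modes", {
  expect_equal(pDistance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(pDistance(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)

  aln <- c(a = "AC-GTT", b = "ACTGTA", c = "ACTGTT")
  # complete deletion drops column 3 (gap in a): 5 columns remain
  dc <- pDistance(aln, "complete_deletion")
  expect_equal(dc["a", "b"], 1 / 5)
  expect_equal(dc["a", "c"], 0 / 5)
  # pairwise deletion keeps column 3 for the b-c pair
  dp <- pDistance(aln, "pairwise_deletion")
  expect_equal(dp["b", "c"], 1 / 6)
  expect_equal(dp["a", "b"], 1 / 5)

  set.seed(91)
  for (i in 1:10) {
    s1 <- sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                 prob = c(rep(0.23, 4), 0.08))
    s2 <- sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                 prob = c(rep(0.23, 4), 0.08))
    keep <- s1 != "-" & s2 != "-"
    expected <- sum(s1[keep] != s2[keep]) / sum(keep)
    got <- pDistance(c(x = paste(s1, collapse = ""),
                       y = paste(s2, collapse = "")))["x", "y"]
    expect_equal(got, expected, tolerance = 1e-12)
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("NJ realizes additive matrices exactly", {
  # 4-taxon tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  D <- rbind(A = c(0, 3, 5, 6), B = c(3, 0, 6, 7),
             C = c(5, 6, 0, 7), D = c(6, 7, 7, 0))
  dimnames(D) <- list(LETTERS[1:4], LETTERS[1:4])
  tree <- njTree(D)
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(D),
                                                      colnames(D)],
               D, tolerance = 1e-9)
  expect_setequal(apeSplits(tree), "C|D")  # AB|CD split

  # 3 taxa: closed-form branch lengths
  D3 <- rbind(A = c(0, 2, 3), B = c(2, 0, 4), C = c(3, 4, 0))
  dimnames(D3) <- list(LETTERS[1:3], LETTERS[1:3])
  t3 <- njTree(D3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(el[["A"]], (2 + 3 - 4) / 2)
  expect_equal(el[["B"]], (2 + 4 - 3) / 2)
  expect_equal(el[["C"]], (3 + 4 - 2) / 2)

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- D; bad[1, 2] <- 99
  expect_error(njTree(bad), "symmetric")
})

test_that("NJ recovers random additive trees up to 12 taxa", {
  set.seed(97)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, rooted = FALSE)
    D <- as.matrix(ape::cophenetic.phylo(ref))
    tree <- njTree(D)
    expect_equal(ape::dist.topo(ape::unroot(ref), tree), 0,
                 ignore_attr = TRUE)
    expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(D),
                                                        colnames(D)],
                 D, tolerance = 1e-9)
  }
})

test_that("NJ agrees with a first-principles Saitou-Nei implementation", {
  set.seed(101)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    m <- matrix(runif(n * n, 0.05, 1), n)
    D <- (m + t(m)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    expect_equal(apeSplits(njTree(D)), oracleNJSplits(D))
  }
})

test_that("an ultrametric matrix yields the generating topology", {
  set.seed(103)
  ref <- ape::rcoal(8)
  D <- as.matrix(ape::cophenetic.phylo(ref))
  expect_equal(ape::dist.topo(ape::unroot(ref), njTree(D)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap supports are deterministic and order-invariant", {
  set.seed(107)
  template <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  mut <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    v[at] <- vapply(v[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }
  groupB <- mut(template, 1:40)
  aln <- c(a1 = template, a2 = mut(template, 115:116),
           b1 = groupB, b2 = mut(groupB, 117:118))
  tree <- bootstrapSupport(aln, replicates = 50, seed = 1)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  expect_equal(max(sup, na.rm = TRUE), 100)  # a|b split in every replicate

  tree2 <- bootstrapSupport(aln, replicates = 50, seed = 1)
  expect_identical(ape::write.tree(tree), ape::write.tree(tree2))
  tree3 <- bootstrapSupport(aln[c(3, 1, 4, 2)], replicates = 50, seed = 1)
  expect_identical(ape::write.tree(tree), ape::write.tree(tree3))
  expect_error(bootstrapSupport(aln, replicates = 10), "seed")
})

test_that("Newick output round-trips with supports and lengths", {
  set.seed(109)
  aln <- setNames(vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = ""),
    character(1)), paste0("t", 1:5))
  tree <- bootstrapSupport(aln, replicates = 20, seed = 2)
  path <- tempfile(fileext = ".nwk")
  writeNewick(tree, path)
  txt <- readLines(path)
  expect_length(txt, 1)
  expect_match(txt, ";$")
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, names(aln))
  expect_equal(back$node.label, tree$node.label)
  # idempotent: write -> read -> write
  path2 <- tempfile(fileext = ".nwk")
  writeNewick(back, path2)
  expect_identical(readLines(path2), txt)
})
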