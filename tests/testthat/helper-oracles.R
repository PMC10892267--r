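# Independent brute-force oracles, deliberately written from first
# principles (genetic code taken straight from Biostrings::GENETIC_CODE)
# rather than reusing package internals.

.oracleCode <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))
  sense <- codons[gc[codons] != "*"]
  list(codons = codons, sense = sense, aa = gc,
       fam = split(sense, as.character(gc[sense])))
})

# Wright's ENc straight from the published estimator
oracleENc <- function(cv) {
  fam <- .oracleCode$fam
  Fk <- data.frame(k = integer(0), F = numeric(0))
  for (a in names(fam)) {
    k <- length(fam[[a]])
    if (k < 2) next
    x <- cv[fam[[a]]]
    n <- sum(x)
    if (n < 2) next
    p <- x / n
    Fk <- rbind(Fk, data.frame(k = k, F = (n * sum(p^2) - 1) / (n - 1)))
  }
  Fbar <- sapply(c(2, 3, 4, 6), function(kk) {
    v <- Fk$F[Fk$k == kk]
    if (!length(v)) NA_real_ else mean(v)
  })
  if (is.na(Fbar[2]) && !is.na(Fbar[1]) && !is.na(Fbar[3]))
    Fbar[2] <- (Fbar[1] + Fbar[3]) / 2
  if (anyNA(Fbar) || any(Fbar <= 0)) return(NA_real_)
  min(2 + 9 / Fbar[1] + 1 / Fbar[2] + 5 / Fbar[3] + 3 / Fbar[4], 61)
}

# RSCU by definition
oracleRSCU <- function(cv) {
  fam <- .oracleCode$fam
  out <- c()
  for (a in setdiff(names(fam), c("M", "W"))) {
    cods <- fam[[a]]
    tot <- sum(cv[cods])
    vals <- if (tot == 0) rep(NA_real_, length(cods))
            else cv[cods] * length(cods) / tot
    out <- c(out, setNames(vals, cods))
  }
  out[order(names(out))]
}

# composition directly from the nucleotide string (stop stripped)
oracleComposition <- function(seq) {
  stopifnot(nchar(seq) %% 3 == 0)
  n <- nchar(seq) %/% 3
  cods <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  if (cods[n] %in% c("TAA", "TAG", "TGA")) cods <- cods[-n]
  chars <- strsplit(paste(cods, collapse = ""), "")[[1]]
  pos <- rep(1:3, length(cods))
  gcAt <- function(p) mean(chars[pos == p] %in% c("G", "C"))
  list(gc = mean(chars %in% c("G", "C")),
       gc1 = gcAt(1), gc2 = gcAt(2), gc3 = gcAt(3))
}

# naive average-linkage agglomeration (squared Euclidean), returning the
# cophenetic matrix of merge heights
oracleAvgLinkCophenetic <- function(m) {
  n <- nrow(m)
  D <- as.matrix(dist(m))^2
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(members) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(members) - 1))
      for (j in (i + 1):length(members)) {
        d <- mean(D[members[[i]], members[[j]], drop = FALSE])
        if (d < best[1] - 1e-12) best <- c(d, i, j)
      }
    i <- best[2]; j <- best[3]
    coph[members[[i]], members[[j]]] <- best[1]
    coph[members[[j]], members[[i]]] <- best[1]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
  }
  dimnames(coph) <- list(rownames(m), rownames(m))
  coph
}

# naive Saitou-Nei neighbor joining; returns the tree's non-trivial
# bipartitions in canonical form (the side not containing the first taxon,
# sorted), for topology comparison
oracleNJSplits <- function(D) {
  labs <- rownames(D)
  active <- as.list(setNames(labs, labs))
  names(active) <- labs
  d <- D
  splits <- list()
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ix <- which(Q == min(Q), arr.ind = TRUE)
    ix <- ix[order(pmin(ix[, 1], ix[, 2]), pmax(ix[, 1], ix[, 2])), ,
             drop = FALSE]
    i <- min(ix[1, ]); j <- max(ix[1, ])
    newLeaves <- sort(c(active[[i]], active[[j]]))
    if (length(newLeaves) <= length(labs) - 2)
      splits <- c(splits, list(newLeaves))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    rn <- c(rownames(d)[keep], paste0("n", length(splits)))
    dimnames(d2) <- list(rn, rn)
    active <- c(active[keep], list(newLeaves))
    names(active) <- rn
    d <- d2
  }
  canon <- function(s) {
    if (labs[1] %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }
  sort(unique(vapply(splits, canon, character(1))))
}

# canonical bipartitions of an unrooted ape tree
apeSplits <- function(tree) {
  labs <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  canon <- function(tips) {
    s <- tree$tip.label[tips]
    if (labs[1] %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }
  out <- vapply(pp, canon, character(1))
  out <- out[out != "" & vapply(strsplit(out, "\\|"), function(x)
    length(x) >= 2 && length(x) <= length(labs) - 2, logical(1))]
  sort(unique(out))
}
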