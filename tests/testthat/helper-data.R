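# fixture builders used across test files

CODS <- codonOrder()
STOPS <- c("TAA", "TAG", "TGA")
SENSE <- CODS[!CODS %in% STOPS]

countsFromVector <- function(cv, id = "g") {
  m <- matrix(0L, 1, 64, dimnames = list(id, CODS))
  m[1, names(cv)] <- as.integer(cv)
  new("CodonCounts", counts = m)
}

# every sense codon used the same number of times -> ENc upper extreme
uniformCounts <- function(times = 12L, id = "uniform") {
  countsFromVector(setNames(rep(times, length(SENSE)), SENSE), id)
}

# one codon per family (first lexicographically) -> ENc lower extreme
oneCodonPerFamilyCounts <- function(times = 5L, id = "onecodon") {
  aa <- as.character(Biostrings::GENETIC_CODE[SENSE])
  first <- vapply(split(SENSE, aa), `[`, character(1), 1)
  countsFromVector(setNames(rep(times, length(first)), first), id)
}

# random count vector guaranteed to observe every family
randomCountVector <- function(nCodons = 300L) {
  probs <- runif(length(SENSE), 0.2, 1)
  draw <- table(factor(sample(SENSE, nCodons, TRUE, probs), levels = SENSE))
  cv <- setNames(as.integer(draw), SENSE)
  aa <- as.character(Biostrings::GENETIC_CODE[SENSE])
  for (a in unique(aa)) {          # top families up to >= 2 observations
    cods <- SENSE[aa == a]
    while (sum(cv[cods]) < 2) cv[cods[1]] <- cv[cods[1]] + 1L
  }
  cv
}

# random strictly valid CDS (no internal stops)
randomCDS <- function(nInterior = 100L) {
  paste0("ATG", paste(sample(SENSE, nInterior, TRUE), collapse = ""),
         sample(STOPS, 1))
}

writeFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(rbind(paste0(">", names(seqs)), unname(seqs)), path)
  path
}
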