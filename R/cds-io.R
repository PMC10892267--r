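# CDS ingestion and validation.

#' Read and validate coding sequences from FASTA
#'
#' Reads a (optionally gzipped) multi-FASTA of coding sequences, uppercases
#' them, maps RNA-style U to T, and validates each record as a CDS: length
#' divisible by three, ATG start, and a single terminal stop codon (TAA, TAG
#' or TGA). Records containing non-ACGT characters (including ambiguity
#' codes) or whose length is not a multiple of three are always rejected.
#' Start/stop violations are rejected in \code{"strict"} mode and kept but
#' flagged in \code{"lenient"} mode.
#'
#' @param path Path to a FASTA file.
#' @param validation \code{"strict"} (default) or \code{"lenient"}.
#' @return A \code{\link[Biostrings]{DNAStringSet}} of accepted records.
#'   \code{mcols()} carries logical columns \code{validStart} and
#'   \code{validStop}; rejected records are reported in
#'   \code{attr(x, "rejected")} as a data frame with columns \code{gene_id}
#'   and \code{reason}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ATGAAATGA"), fa)
#' cds <- readCDS(fa)
#' names(cds)
readCDS <- function(path, validation = c("strict", "lenient")) {
  validation <- match.arg(validation)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA input: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  seqs <- toupper(seqs)

  reasons <- character(length(seqs))
  badChar <- grepl("[^ACGT]", seqs)
  reasons[badChar] <- "non-ACGT characters"
  badLen <- !badChar & nchar(seqs) %% 3L != 0L
  reasons[badLen] <- "length not divisible by 3"
  zeroLen <- !badChar & !badLen & nchar(seqs) == 0L
  reasons[zeroLen] <- "empty sequence"

  candidate <- reasons == ""
  validStart <- rep(NA, length(seqs))
  validStop <- rep(NA, length(seqs))
  validStart[candidate] <- substr(seqs[candidate], 1L, 3L) == "ATG"
  lastCodon <- substr(seqs[candidate],
                      nchar(seqs[candidate]) - 2L, nchar(seqs[candidate]))
  validStop[candidate] <- lastCodon %in% STOP_CODONS

  if (validation == "strict") {
    bad <- candidate & !(validStart & validStop)
    reasons[bad & !validStart] <- "no ATG start codon"
    reasons[bad & validStart & !validStop] <- "no terminal stop codon"
  }
  keep <- reasons == ""

  rejected <- data.frame(gene_id = ids[!keep], reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L)
    warning(nrow(rejected), " record(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "))

  out <- Biostrings::DNAStringSet(seqs[keep])
  names(out) <- ids[keep]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    validStart = validStart[keep], validStop = validStop[keep])
  attr(out, "rejected") <- rejected
  out
}

#' Translate coding sequences
#'
#' Standard-code translation excluding the terminal stop codon. An internal
#' stop codon raises an error in strict mode, or truncates the protein at
#' the first stop with a warning in lenient mode.
#'
#' @param cds A \code{DNAStringSet} or character vector of CDS.
#' @param strict Error on internal stops (default) or truncate with warning.
#' @return Named character vector of amino-acid strings.
#' @export
#' @examples
#' translateCDS(c(g1 = "ATGAAATGA"))  # "MK"
translateCDS <- function(cds, strict = TRUE) {
  seqs <- .asNamedSeqs(cds)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  stopifnot(all(nchar(seqs) %% 3L == 0L), all(nchar(seqs) >= 3L))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seqs), no.init.codon = TRUE))
  # drop a single terminal stop, if present
  hasStop <- substr(aa, nchar(aa), nchar(aa)) == "*"
  aa[hasStop] <- substr(aa[hasStop], 1L, nchar(aa[hasStop]) - 1L)
  internal <- grepl("\\*", aa)
  if (any(internal)) {
    if (strict)
      stop("internal stop codon in: ",
           paste(names(seqs)[internal], collapse = ", "))
    warning("internal stop codon; truncating: ",
            paste(names(seqs)[internal], collapse = ", "))
    aa[internal] <- sub("\\*.*$", "", aa[internal])
  }
  names(aa) <- names(seqs)
  aa
}
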