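# internal helpers

# character conversion that keeps names for both DNAStringSet and
# character input (as.character drops names of plain character vectors)
.asNamedSeqs <- function(cds) {
  seqs <- as.character(cds)
  if (is.null(names(seqs)) && !is.null(names(cds)))
    names(seqs) <- names(cds)
  seqs
}
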