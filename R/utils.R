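# Internal helpers shared across modules.

# Reverse-complement a character vector of DNA sequences (IUPAC-aware).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate a vector of codons to single-letter amino acids ("*" for stop).
# Codons containing non-ACGT characters translate to NA.
translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codon])
  out
}

# Serialize a mutation data.frame to the token form "pos:from>to:region:RS"
# joined by ";". Empty input -> "".
serialize_mutations <- function(mut) {
  if (is.null(mut) || nrow(mut) == 0L) return("")
  paste(sprintf("%d:%s>%s:%s:%s", mut$pos, mut$from, mut$to, mut$region, mut$rs),
        collapse = ";")
}

# Inverse of serialize_mutations().
parse_mutations <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(pos = integer(), from = character(), to = character(),
                      region = character(), rs = character(),
                      stringsAsFactors = FALSE))
  }
  tok <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(
    pos = as.integer(vapply(tok, `[`, character(1L), 1L)),
    from = substr(vapply(tok, `[`, character(1L), 2L), 1L, 1L),
    to = substr(vapply(tok, `[`, character(1L), 2L), 3L, 3L),
    region = vapply(tok, `[`, character(1L), 3L),
    rs = vapply(tok, `[`, character(1L), 4L),
    stringsAsFactors = FALSE
  )
}

# Stop codons in the standard genetic code.
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Write a data.frame as TSV without quoting or row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA, comment.char = "")
}
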