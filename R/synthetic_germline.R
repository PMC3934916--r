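#' Build a small synthetic germline repertoire
#'
#' Constructs a self-contained germline reference for simulation and testing:
#' 8 IGHV genes (families IGHV1, IGHV3, IGHV4, IGHV5), 4 IGHD and 4 IGHJ
#' genes. V genes are 294 nt (98 codons) of random sense codons, free of stop
#' codons, ending in the conserved cysteine codon (TGT) that anchors CDR3;
#' region boundaries mimic realistic Kabat and IMGT FR/CDR extents and are
#' jittered by a codon between genes. J genes embed the tryptophan motif
#' (TGGGG) of the J-region FR4 anchor at varying offsets. This stands in for
#' curated germline databases, which cannot be redistributed; it preserves the
#' structural features the pipeline relies on (region maps, CDR3 anchors,
#' family structure), not real allelic sequence.
#'
#' @param seed Integer seed making the construction reproducible.
#' @return A `germline_repertoire`.
#' @export
make_synthetic_repertoire <- function(seed = 42L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  rand_codons <- function(n) paste(sample(sense_codons, n, replace = TRUE), collapse = "")

  v_names <- c("IGHV1-S1*01", "IGHV1-S2*01", "IGHV3-S1*01", "IGHV3-S2*01",
               "IGHV3-S3*01", "IGHV4-S1*01", "IGHV4-S2*01", "IGHV5-S1*01")
  seqs <- character(0)
  region_rows <- list()
  for (g in v_names) {
    len <- 294L
    s <- paste0(rand_codons(len / 3L - 1L), "TGT")  # conserved 2nd-CYS last codon
    seqs[[g]] <- s
    j1 <- 3L * sample(-1:1, 1L)  # codon-level jitter on CDR1 placement
    j2 <- 3L * sample(-1:1, 1L)
    kabat <- c(fr1_start = 0L, cdr1_start = 90L + j1, fr2_start = 105L + j1,
               cdr2_start = 165L + j2, fr3_start = 195L + j2, fr3_end = len)
    imgt <- c(fr1_start = 0L, cdr1_start = 75L + j1, fr2_start = 99L + j1,
              cdr2_start = 150L + j2, fr3_start = 174L + j2, fr3_end = len)
    region_rows[[paste0(g, "_K")]] <- data.frame(gene = g, scheme = "KABAT",
      t(kabat), stringsAsFactors = FALSE)
    region_rows[[paste0(g, "_I")]] <- data.frame(gene = g, scheme = "IMGT",
      t(imgt), stringsAsFactors = FALSE)
  }

  d_names <- c("IGHD1-S1*01", "IGHD2-S1*01", "IGHD3-S1*01", "IGHD4-S1*01")
  d_len <- c(15L, 18L, 21L, 24L)
  for (i in seq_along(d_names)) {
    seqs[[d_names[i]]] <- paste(sample(c("A", "C", "G", "T"), d_len[i],
                                       replace = TRUE), collapse = "")
  }

  j_names <- c("IGHJ1-S1*01", "IGHJ2-S1*01", "IGHJ3-S1*01", "IGHJ4-S1*01")
  j_prefix <- c(9L, 12L, 15L, 18L)  # CDR3-encoding head before the Trp anchor
  for (i in seq_along(j_names)) {
    repeat {
      head <- paste(sample(c("A", "C", "G", "T"), j_prefix[i], replace = TRUE),
                    collapse = "")
      if (!grepl("TGG", head, fixed = TRUE)) break
    }
    tail <- rand_codons(8L)           # FR4 tail, in frame with the Trp codon
    seqs[[j_names[i]]] <- paste0(head, "TGG", "GGC", tail)
  }

  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fa, tsv)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa, width = 70L)
  write_tsv(do.call(rbind, region_rows), tsv)
  load_repertoire(fa, tsv)
}
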