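#' Constant-region primer sites used for isotype assignment
#'
#' The reverse PCR primers anneal in the CH1 exon of the IGHE and IGHG
#' constant-region genes, so every amplicon carries the reverse complement
#' of one of these sites at its 3' end (in forward orientation). Matching a
#' read end against these sites identifies its isotype.
#'
#' @return Named character vector with elements `IGE` and `IGG`.
#' @export
ig_primers <- function() {
  c(IGE = "GAATGTTTTTGCAGCAGCGGGT",   # IgE CH1 reverse primer site
    IGG = "GGAAGTAGTCCTTGACCAGGCAG")  # IgG CH1 reverse primer site
}

# Match one primer site against all reads on both strands, allowing up to
# max_mm mismatches in the terminal window. Returns per read "FORWARD"
# (site rc at the 3' end), "REVERSE" (site itself at the 5' end) or NA.
match_primer_site <- function(sequences, site, max_mm) {
  w <- nchar(site) + 8L
  n <- nchar(sequences)
  site_rc <- revcomp(site)
  tails <- Biostrings::DNAStringSet(substr(sequences, pmax(1L, n - w + 1L), n))
  heads <- Biostrings::DNAStringSet(substr(sequences, 1L, pmin(w, n)))
  hit_f <- Biostrings::vcountPattern(site_rc, tails, max.mismatch = max_mm,
                                     with.indels = FALSE) > 0L
  hit_r <- Biostrings::vcountPattern(site, heads, max.mismatch = max_mm,
                                     with.indels = FALSE) > 0L
  ifelse(hit_f, "FORWARD", ifelse(hit_r, "REVERSE", NA_character_))
}

#' Assign isotypes from constant-region primer sites
#'
#' A read is called IgE or IgG when its 3' end (on either strand) matches
#' the corresponding CH1 primer site with at most `max_mismatch`
#' mismatches. No qualifying match, or a qualifying match to both sites,
#' yields `UNCERTAIN`. The matching strand also reveals the read
#' orientation, reported alongside.
#'
#' @param sequences Character vector of read sequences.
#' @param primers Named primer-site vector, as [ig_primers()].
#' @param max_mismatch Mismatch tolerance (default 2).
#' @return data.frame with columns `isotype` (`IGE`/`IGG`/`UNCERTAIN`) and
#'   `orientation` (`FORWARD`/`REVERSE`/`UNKNOWN`).
#' @export
assign_isotype <- function(sequences, primers = ig_primers(),
                           max_mismatch = 2L) {
  hits <- vapply(names(primers), function(p)
    match_primer_site(sequences, primers[[p]], max_mismatch),
    character(length(sequences)))
  if (length(sequences) == 1L) {
    hits <- matrix(hits, nrow = 1L, dimnames = list(NULL, names(primers)))
  }
  n_hit <- rowSums(!is.na(hits))
  iso <- rep("UNCERTAIN", length(sequences))
  ori <- rep("UNKNOWN", length(sequences))
  one <- n_hit == 1L
  if (any(one)) {
    which_p <- apply(hits[one, , drop = FALSE], 1L,
                     function(r) which(!is.na(r))[1L])
    iso[one] <- names(primers)[which_p]
    ori[one] <- hits[one, , drop = FALSE][cbind(seq_len(sum(one)), which_p)]
  }
  data.frame(isotype = iso, orientation = ori, stringsAsFactors = FALSE)
}

# k-mer orientation vote against the germline V set, for reads whose
# primer match did not settle the strand.
kmer_orientation <- function(sequences, germlines, k = 11L) {
  vseqs <- germlines$seq[germlines$segment == "V"]
  kmers <- unique(unlist(lapply(vseqs, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  }), use.names = FALSE))
  vapply(sequences, function(s) {
    if (nchar(s) < k) return("FORWARD")
    fw <- substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
    rv <- substring(revcomp(s), 1:(nchar(s) - k + 1L), k:nchar(s))
    nf <- sum(fw %in% kmers); nr <- sum(rv %in% kmers)
    if (nr > nf) "REVERSE" else "FORWARD"
  }, character(1L), USE.NAMES = FALSE)
}

#' Orient reads and collapse duplicates
#'
#' Reverse reads are reverse-complemented into forward orientation (using
#' the primer-site strand where available, otherwise a germline k-mer
#' vote). Two oriented reads are duplicates when they are identical or one
#' is a substring extension of the other (100% identity over the shared
#' span, the situation produced by varying 5' primer truncation); the
#' longest member is retained as representative. The replicate count and a
#' bidirectional flag (both original orientations seen among members) are
#' recorded per unique sequence, and the isotype is resolved by majority
#' over members with a determinate call.
#'
#' @param reads data.frame with columns `id`, `sequence` (raw reads).
#' @param germlines A `germline_repertoire` (orientation fallback).
#' @param primers Primer sites for [assign_isotype()].
#' @param max_mismatch Primer mismatch tolerance.
#' @return data.frame of unique sequences: `id` (representative read id),
#'   `sequence` (oriented), `isotype`, `replicate_count`, `bidirectional`,
#'   `member_ids` (semicolon-joined).
#' @export
orient_and_deduplicate <- function(reads, germlines, primers = ig_primers(),
                                   max_mismatch = 2L) {
  empty <- data.frame(id = character(), sequence = character(),
                      isotype = character(), replicate_count = integer(),
                      bidirectional = logical(), member_ids = character(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  iso <- assign_isotype(reads$sequence, primers, max_mismatch)
  unknown <- iso$orientation == "UNKNOWN"
  if (any(unknown)) {
    iso$orientation[unknown] <-
      kmer_orientation(reads$sequence[unknown], germlines)
  }
  oriented <- ifelse(iso$orientation == "REVERSE",
                     revcomp(reads$sequence), reads$sequence)

  ord <- order(-nchar(oriented), oriented, reads$id)
  seqs <- oriented[ord]
  reps <- character(0)       # representative sequences, longest first
  cluster_of <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- if (length(reps)) which(grepl(seqs[i], reps, fixed = TRUE)) else
      integer(0)
    if (length(hit)) {
      cluster_of[i] <- hit[1L]
    } else {
      reps <- c(reps, seqs[i])
      cluster_of[i] <- length(reps)
    }
  }
  out <- vector("list", length(reps))
  for (cid in seq_along(reps)) {
    members <- ord[cluster_of == cid]
    rep_idx <- members[1L]  # longest (sort order)
    iso_members <- iso$isotype[members]
    det <- iso_members[iso_members != "UNCERTAIN"]
    iso_call <- if (length(det)) names(sort(table(det), decreasing = TRUE))[1L]
                else "UNCERTAIN"
    out[[cid]] <- data.frame(
      id = reads$id[rep_idx], sequence = oriented[rep_idx],
      isotype = iso_call, replicate_count = length(members),
      bidirectional = length(unique(iso$orientation[members])) == 2L,
      member_ids = paste(reads$id[members], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
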