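#' V(D)J annotation by best local alignment
#'
#' Annotates each (oriented, deduplicated) sequence against a germline
#' repertoire. The V gene is the highest-scoring Smith-Waterman local
#' alignment (affine gaps) over all V references, ties broken by fewest
#' mismatches then lexicographic name; the alignment is then extended to
#' its diagonal ends so mutated terminal bases are not soft-clipped. The J
#' gene is assigned the same way in the read region 3' of the V match; the
#' D gene is the best ungapped match inside the junction, requiring at
#' least `min_d_run` consecutive identities ("no D" otherwise). Recorded
#' per sequence: gene calls, the number of missing 5' V nucleotides, the
#' mismatch list in V coordinates, V-indel and ambiguity flags, the CDR3
#' (between the conserved V-end cysteine codon and the J tryptophan
#' motif), frame status and stop-codon status. Sequences whose best V
#' score falls below `min_v_score` are marked unalignable and excluded
#' from downstream datasets (but tallied).
#'
#' @param unique_seqs data.frame from [orient_and_deduplicate()] (columns
#'   `id`, `sequence`; extra columns are carried through), or a character
#'   vector of sequences.
#' @param germlines A `germline_repertoire`.
#' @param min_v_score Minimum acceptable V alignment score (match +5,
#'   mismatch -4, gap open 12, gap extend 3).
#' @param min_j_score Minimum acceptable J alignment score.
#' @param min_d_run Minimum consecutive identities for a D call.
#' @return data.frame with one row per input sequence: `id`, `v_gene`,
#'   `d_gene`, `j_gene`, `v_start_offset`, `v_score`, `n_mismatch`,
#'   `mismatches` (serialized `pos:germ>read` tokens, 0-based V
#'   coordinates), `has_indel_in_v`, `has_ambiguity`, `v_aligned_len`,
#'   `cdr3_nt`, `cdr3_aa`, `in_frame`, `has_stop`, `unalignable`, plus any
#'   carried-through input columns.
#' @export
annotate_vdj <- function(unique_seqs, germlines, min_v_score = 100,
                         min_j_score = 60, min_d_run = 5L) {
  if (is.character(unique_seqs)) {
    unique_seqs <- data.frame(
      id = sprintf("S%05d", seq_along(unique_seqs)),
      sequence = unique_seqs, stringsAsFactors = FALSE)
  }
  n <- nrow(unique_seqs)
  na_chr <- rep(NA_character_, n); na_int <- rep(NA_integer_, n)
  ann <- data.frame(
    id = unique_seqs$id, v_gene = na_chr, d_gene = na_chr,
    j_gene = na_chr, v_start_offset = na_int, v_score = rep(NA_real_, n),
    n_mismatch = na_int, mismatches = na_chr,
    has_indel_in_v = rep(NA, n), has_ambiguity = rep(NA, n),
    v_aligned_len = na_int, cdr3_nt = na_chr, cdr3_aa = na_chr,
    in_frame = rep(NA, n), has_stop = rep(NA, n),
    unalignable = rep(TRUE, n), stringsAsFactors = FALSE)
  extra <- setdiff(names(unique_seqs), names(ann))
  if (n == 0L) return(cbind(ann, unique_seqs[, extra, drop = FALSE]))
  seqs <- unique_seqs$sequence
  ann$has_ambiguity <- grepl("[^ACGT]", seqs)

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = FALSE)
  patt <- Biostrings::DNAStringSet(seqs)
  vg <- sort(genes_of(germlines, "V"))
  jg <- sort(genes_of(germlines, "J"))
  dg <- sort(genes_of(germlines, "D"))
  align <- function(p, s) {
    Biostrings::pairwiseAlignment(p, Biostrings::DNAString(s), type = "local",
                                  substitutionMatrix = mat, gapOpening = 25,
                                  gapExtension = 4)
  }
  # batch-extract per-pattern alignment facts (S4 accessors are costly
  # per-element, cheap vectorized)
  unpack <- function(aln, np) {
    nind <- Biostrings::nindel(aln)
    mmt <- Biostrings::mismatchTable(aln)
    list(s0 = Biostrings::start(Biostrings::subject(aln)),
         s1 = Biostrings::end(Biostrings::subject(aln)),
         p0 = Biostrings::start(Biostrings::pattern(aln)),
         p1 = Biostrings::end(Biostrings::pattern(aln)),
         indel = rowSums(Biostrings::insertion(nind)) +
                 rowSums(Biostrings::deletion(nind)) > 0L,
         mm = split(data.frame(pos = as.integer(mmt$SubjectStart) - 1L,
                               germ = as.character(mmt$SubjectSubstring),
                               read = as.character(mmt$PatternSubstring),
                               stringsAsFactors = FALSE),
                    factor(mmt$PatternId, levels = seq_len(np))))
  }

  # phase 1: score every read against every V reference (vectorized)
  v_aln <- lapply(vg, function(g) align(patt, germlines$seq[[g]]))
  names(v_aln) <- vg
  as_mat <- function(x) if (n == 1L)
    matrix(x, nrow = 1L, dimnames = list(NULL, vg)) else x
  v_scores <- as_mat(vapply(v_aln, Biostrings::score, numeric(n)))
  v_mm <- as_mat(vapply(v_aln, Biostrings::nmismatch, numeric(n)))
  v_info <- lapply(v_aln, unpack, np = n)

  p1_end <- rep(NA_integer_, n)  # read coordinate of the V 3' end
  for (i in seq_len(n)) {
    sc <- v_scores[i, ]
    best <- max(sc)
    if (best < min_v_score) next
    cand <- vg[sc == best]
    if (length(cand) > 1L) {
      mm <- v_mm[i, cand]
      cand <- sort(cand[mm == min(mm)])
    }
    v <- cand[1L]
    info <- v_info[[v]]
    s0 <- info$s0[i]; s1 <- info$s1[i]   # 1-based V span
    p0 <- info$p0[i]; p1 <- info$p1[i]   # 1-based read span
    has_indel <- info$indel[i]
    mm_df <- info$mm[[i]]
    # extend the local alignment to its diagonal ends so mutated terminal
    # bases are not soft-clipped: 5' to the read or V start, 3' to the V end
    read <- seqs[i]
    vref <- germlines$seq[[v]]
    d5 <- min(p0 - 1L, s0 - 1L)
    if (d5 > 0L) {
      rseg <- strsplit(substr(read, p0 - d5, p0 - 1L), "")[[1L]]
      vseg <- strsplit(substr(vref, s0 - d5, s0 - 1L), "")[[1L]]
      diffs <- which(rseg != vseg)
      if (length(diffs)) {
        mm_df <- rbind(data.frame(pos = (s0 - d5 - 1L) + diffs - 1L,
                                  germ = vseg[diffs], read = rseg[diffs],
                                  stringsAsFactors = FALSE), mm_df)
      }
      p0 <- p0 - d5; s0 <- s0 - d5
    }
    d3 <- min(nchar(read) - p1, nchar(vref) - s1)
    if (d3 > 0L) {
      rseg <- strsplit(substr(read, p1 + 1L, p1 + d3), "")[[1L]]
      vseg <- strsplit(substr(vref, s1 + 1L, s1 + d3), "")[[1L]]
      diffs <- which(rseg != vseg)
      if (length(diffs)) {
        mm_df <- rbind(mm_df, data.frame(pos = s1 + diffs - 1L,
                                         germ = vseg[diffs],
                                         read = rseg[diffs],
                                         stringsAsFactors = FALSE))
      }
      p1 <- p1 + d3; s1 <- s1 + d3
    }
    mm_df <- mm_df[order(mm_df$pos), , drop = FALSE]
    fr3_end <- germlines$regions[[v]]$UNION[["fr3_end"]]

    ann$v_gene[i] <- v
    ann$v_score[i] <- best
    ann$v_start_offset[i] <- s0 - 1L
    ann$n_mismatch[i] <- nrow(mm_df)
    ann$mismatches[i] <- if (nrow(mm_df))
      paste(sprintf("%d:%s>%s", mm_df$pos, mm_df$germ, mm_df$read),
            collapse = ";") else ""
    ann$has_indel_in_v[i] <- has_indel
    ann$v_aligned_len[i] <- min(s1, fr3_end) - (s0 - 1L)
    ann$unalignable[i] <- FALSE
    p1_end[i] <- p1
  }

  # phase 2: J assignment over all read tails at once, per J reference
  tail_start <- p1_end + 1L
  has_tail <- !is.na(p1_end) & tail_start <= nchar(seqs) - 5L
  j_call <- rep(NA_character_, n)
  jp0 <- rep(NA_integer_, n); js0 <- rep(NA_integer_, n)
  if (any(has_tail)) {
    idx <- which(has_tail)
    tails <- Biostrings::DNAStringSet(substring(seqs[idx], tail_start[idx]))
    j_aln <- lapply(jg, function(g) align(tails, germlines$seq[[g]]))
    names(j_aln) <- jg
    m <- length(idx)
    as_mat_j <- function(x) if (m == 1L)
      matrix(x, nrow = 1L, dimnames = list(NULL, jg)) else x
    j_scores <- as_mat_j(vapply(j_aln, Biostrings::score, numeric(m)))
    j_mm <- as_mat_j(vapply(j_aln, Biostrings::nmismatch, numeric(m)))
    j_p0 <- lapply(j_aln, function(a)
      Biostrings::start(Biostrings::pattern(a)))
    j_s0 <- lapply(j_aln, function(a)
      Biostrings::start(Biostrings::subject(a)))
    for (k in seq_len(m)) {
      sc <- j_scores[k, ]
      best <- max(sc)
      if (best < min_j_score) next
      cand <- jg[sc == best]
      if (length(cand) > 1L) {
        mm <- j_mm[k, cand]
        cand <- sort(cand[mm == min(mm)])
      }
      g <- cand[1L]
      i <- idx[k]
      j_call[i] <- g
      jp0[i] <- j_p0[[g]][k]
      js0[i] <- j_s0[[g]][k]
    }
  }
  ann$j_gene <- j_call
  trp_off <- vapply(jg, function(g) j_trp_offset(germlines$seq[[g]]),
                    integer(1L))

  # phase 3: D call, CDR3 extraction, frame and stop-codon status
  for (i in seq_len(n)) {
    j <- j_call[i]
    if (is.na(j)) next
    read <- seqs[i]
    v <- ann$v_gene[i]
    fr3_end <- germlines$regions[[v]]$UNION[["fr3_end"]]
    junc_start <- p1_end[i] + 1L
    junc_end <- tail_start[i] + jp0[i] - 2L
    if (junc_end >= junc_start) {
      junc <- substr(read, junc_start, junc_end)
      best_run <- 0L; d_call <- NA_character_
      for (g in dg) {
        run <- longest_identity_run(junc, germlines$seq[[g]])
        if (run > best_run) { best_run <- run; d_call <- g }
      }
      ann$d_gene[i] <- if (best_run >= min_d_run) d_call else NA_character_
    }
    cys_v0 <- fr3_end - 3L
    cys_read0 <- cys_v0 - (ann$v_start_offset[i]) # 0-based, indel-free map
    trp_read0 <- (tail_start[i] - 1L) + (jp0[i] - 1L) +
      (trp_off[[j]] - (js0[i] - 1L))
    v_cov_end <- ann$v_start_offset[i] + ann$v_aligned_len[i]
    if (!(ann$has_indel_in_v[i] %in% TRUE) && cys_read0 >= 0L &&
        v_cov_end >= fr3_end && trp_off[[j]] >= (js0[i] - 1L) &&
        trp_read0 >= cys_read0 + 3L) {
      cdr3 <- substr(read, cys_read0 + 4L, trp_read0)
      ann$cdr3_nt[i] <- cdr3
      if (nchar(cdr3) > 0L && nchar(cdr3) %% 3L == 0L &&
          !grepl("[^ACGT]", cdr3)) {
        ann$cdr3_aa[i] <- as.character(Biostrings::translate(
          Biostrings::DNAString(cdr3)))
      }
      ann$in_frame[i] <- (trp_read0 - cys_read0) %% 3L == 0L
      # stop-codon scan in the V reading frame, through the end of J
      frame0 <- cys_read0 %% 3L
      scan_end <- min(nchar(read),
                      trp_read0 + (nchar(germlines$seq[[j]]) - trp_off[[j]]))
      if (scan_end - 2L >= frame0 + 1L) {
        starts <- seq(frame0 + 1L, scan_end - 2L, by = 3L)
        cods <- substring(read, starts, starts + 2L)
        ann$has_stop[i] <- any(cods %in% STOP_CODONS)
      }
    }
  }
  cbind(ann, unique_seqs[, extra, drop = FALSE])
}

# Longest run of consecutive identities between two sequences over all
# ungapped offsets.
longest_identity_run <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  best <- 0L
  for (shift in (-(nb - 1L)):(na - 1L)) {
    ia <- max(0L, shift); ib <- max(0L, -shift)
    len <- min(na - ia, nb - ib)
    if (len <= best) next
    eq <- av[(ia + 1L):(ia + len)] == bv[(ib + 1L):(ib + len)]
    r <- rle(eq)
    m <- suppressWarnings(max(r$lengths[r$values]))
    if (is.finite(m) && m > best) best <- m
  }
  best
}
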