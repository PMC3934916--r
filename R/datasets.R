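#' Quality filter cascade producing Dataset A
#'
#' Applies, in order, the quality rules that define the unfiltered working
#' dataset: sequences that could not be V-aligned are dropped first, then
#' sequences missing more than `max_offset` 5' V nucleotides ("more than
#' 45" read strictly: 46 removed, 45 kept), sequences containing ambiguity
#' characters, sequences with insertions or deletions in the V gene, and
#' sequences with more than `max_mutations` apparent V mutations (likely
#' sequencing artefacts). Each removed sequence is tallied under the first
#' rule it fails; duplicates removed earlier at deduplication can be
#' carried into the tally via `n_duplicates`.
#'
#' @param annotations data.frame from [annotate_vdj()].
#' @param max_offset Maximum tolerated missing 5' V nucleotides.
#' @param max_mutations Maximum tolerated apparent V mutations.
#' @param n_duplicates Count of reads collapsed at deduplication, echoed in
#'   the tally.
#' @return list with `dataset` (retained rows) and `tally` (named integer
#'   vector: unalignable, offset, ambiguity, indel, mutation_count,
#'   duplicate).
#' @export
filter_dataset_a <- function(annotations, max_offset = 45L,
                             max_mutations = 45L, n_duplicates = 0L) {
  keep <- rep(TRUE, nrow(annotations))
  tally <- c(unalignable = 0L, offset = 0L, ambiguity = 0L, indel = 0L,
             mutation_count = 0L, duplicate = as.integer(n_duplicates))
  fail <- function(cond, rule) {
    hit <- keep & cond
    tally[[rule]] <<- sum(hit)
    keep[hit] <<- FALSE
  }
  fail(annotations$unalignable, "unalignable")
  fail(!annotations$unalignable & annotations$v_start_offset > max_offset,
       "offset")
  fail(annotations$has_ambiguity %in% TRUE, "ambiguity")
  fail(annotations$has_indel_in_v %in% TRUE, "indel")
  fail(!is.na(annotations$n_mismatch) & annotations$n_mismatch > max_mutations,
       "mutation_count")
  list(dataset = annotations[keep, , drop = FALSE], tally = tally)
}

#' Bidirectional-read filter producing Dataset B
#'
#' Retains only sequences that were observed as both forward and reverse
#' reads, a stringent guard against sequencing error.
#'
#' @param dataset_a Dataset A rows (must carry a `bidirectional` column).
#' @return The subset with `bidirectional == TRUE`.
#' @export
filter_bidirectional <- function(dataset_a) {
  stopifnot("bidirectional" %in% names(dataset_a))
  dataset_a[dataset_a$bidirectional %in% TRUE, , drop = FALSE]
}

#' Collapse clonally related sequences producing Dataset C
#'
#' Sequences sharing IGHV, IGHD and IGHJ gene calls and the same CDR3 key
#' (amino-acid translation by default, nucleotide behind `key`) are grouped
#' as one clone; only the dominant member — highest replicate count, ties
#' broken by longest sequence then lexicographic id — is retained.
#' Sequences lacking a CDR3 call form singleton groups.
#'
#' @param dataset_b Dataset B rows (annotated, with `replicate_count`).
#' @param key `"aa"` (default) or `"nt"` CDR3 keying.
#' @return list with `dataset` (Dataset C: dominant members, plus a
#'   `clone_id` column) and `clones` (data.frame: clone_id, n_members,
#'   dominant id, member ids).
#' @export
collapse_clones <- function(dataset_b, key = c("aa", "nt")) {
  key <- match.arg(key)
  n <- nrow(dataset_b)
  if (n == 0L) {
    dataset_b$clone_id <- character(0)
    return(list(dataset = dataset_b,
                clones = data.frame(clone_id = character(),
                                    n_members = integer(),
                                    dominant = character(),
                                    members = character(),
                                    stringsAsFactors = FALSE)))
  }
  cdr3_key <- if (key == "aa") {
    ifelse(!is.na(dataset_b$cdr3_aa), paste0("aa:", dataset_b$cdr3_aa),
           ifelse(!is.na(dataset_b$cdr3_nt), paste0("nt:", dataset_b$cdr3_nt),
                  NA_character_))
  } else {
    ifelse(!is.na(dataset_b$cdr3_nt), paste0("nt:", dataset_b$cdr3_nt),
           NA_character_)
  }
  grp <- paste(dataset_b$v_gene, dataset_b$d_gene, dataset_b$j_gene,
               cdr3_key, sep = "|")
  grp[is.na(cdr3_key)] <- paste0("singleton|", dataset_b$id[is.na(cdr3_key)])
  rc <- dataset_b$replicate_count
  if (is.null(rc)) rc <- rep(1L, n)
  seq_len_v <- nchar(dataset_b$sequence)
  groups <- split(seq_len(n), grp)
  clone_rows <- vector("list", length(groups))
  dataset_b$clone_id <- NA_character_
  keep_idx <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    cid <- sprintf("CL%05d", g)
    dataset_b$clone_id[idx] <- cid
    ord <- idx[order(-rc[idx], -seq_len_v[idx], dataset_b$id[idx])]
    keep_idx[g] <- ord[1L]
    clone_rows[[g]] <- data.frame(
      clone_id = cid, n_members = length(idx),
      dominant = dataset_b$id[ord[1L]],
      members = paste(dataset_b$id[idx], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(dataset = dataset_b[sort(keep_idx), , drop = FALSE],
       clones = do.call(rbind, clone_rows))
}

#' Tally stop-codon and out-of-frame sequences
#'
#' Counts sequences containing stop codons and out-of-frame sequences in a
#' dataset, with percentages to one decimal (0.0 for an empty dataset).
#' Such sequences arise naturally at low rates but are inflated by
#' sequencing error, so their prevalence tracks dataset quality.
#'
#' @param dataset Annotated dataset rows (columns `has_stop`, `in_frame`).
#' @return data.frame with columns `metric`, `count`, `pct`.
#' @export
quality_tally <- function(dataset) {
  n <- nrow(dataset)
  stops <- sum(dataset$has_stop %in% TRUE)
  oof <- sum(dataset$in_frame %in% FALSE)
  pct <- function(k) if (n == 0L) 0.0 else round(100 * k / n, 1L)
  data.frame(metric = c("stop_codon", "out_of_frame"),
             count = c(stops, oof),
             pct = c(pct(stops), pct(oof)),
             stringsAsFactors = FALSE)
}
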