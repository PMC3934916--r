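#' Replacement/silent classification of a point mutation
#'
#' A mutation is a replacement (R) when the observed codon encodes a
#' different amino acid than the germline codon under the standard genetic
#' code (a mutation creating a stop codon counts as R); otherwise it is
#' silent (S). Each mutation is judged one-at-a-time: the observed codon is
#' the germline codon with only that mutation applied.
#'
#' @param germline_codon,observed_codon Character vectors of 3-nt codons.
#' @return Character vector of `"R"` / `"S"` (NA where a codon contains a
#'   non-ACGT character).
#' @export
classify_rs <- function(germline_codon, observed_codon) {
  ga <- translate_codon(germline_codon)
  oa <- translate_codon(observed_codon)
  out <- ifelse(ga == oa, "S", "R")
  out[is.na(ga) | is.na(oa)] <- NA_character_
  out
}

#' Build per-sequence mutation profiles
#'
#' Converts annotated mismatch lists into mutation bookkeeping: the total
#' V-gene mutation count Mv, each mutation's replacement/silent status
#' (one-at-a-time against the germline codon, reading frame fixed by the
#' germline V annotation) and its region under the broadened union CDR
#' scheme, and the count of CDR1+CDR2 replacement mutations R_CDR.
#' Mutations in codons truncated by the 5' primer offset cannot be
#' classified reliably and are excluded from Mv (counted in
#' `n_excluded`); mismatches involving an ambiguity character are likewise
#' excluded. Mutations 3' of FR3 never enter the mismatch list, as
#' annotation restricts it to the V gene.
#'
#' @param annotations Dataset rows from the filter cascade (indel-free).
#' @param germlines A `germline_repertoire`.
#' @param scheme Region scheme for attribution (default `"UNION"`).
#' @param group Optional character vector (recycled) assigning each
#'   sequence to a donor/analysis group; defaults to the isotype.
#' @return data.frame with one row per sequence: `id`, `isotype`, `group`,
#'   `mv`, `r_cdr`, per-region R and S counts (`fr1_r` ... `fr3_s`),
#'   `n_excluded`, `pct_mutated` (100 * mv / aligned V length), and
#'   `mutations` (serialized `pos:from>to:region:RS` tokens).
#' @export
build_profiles <- function(annotations, germlines,
                           scheme = c("UNION", "KABAT", "IMGT"),
                           group = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(annotations)
  if (any(annotations$has_indel_in_v %in% TRUE)) {
    stop("annotations with V indels must be filtered before profiling")
  }
  if (is.null(group)) {
    group <- if ("isotype" %in% names(annotations)) annotations$isotype
             else rep(NA_character_, n)
  }
  group <- rep_len(group, n)
  regions <- c("fr1", "cdr1", "fr2", "cdr2", "fr3")
  cols <- as.vector(outer(regions, c("r", "s"), paste, sep = "_"))
  counts <- matrix(0L, nrow = n, ncol = length(cols),
                   dimnames = list(NULL, cols))
  mv <- integer(n); r_cdr <- integer(n); excl <- integer(n)
  mut_str <- character(n)
  for (i in seq_len(n)) {
    v <- annotations$v_gene[i]
    mmstr <- annotations$mismatches[i]
    mut_str[i] <- ""
    if (is.na(v) || is.na(mmstr) || !nzchar(mmstr)) next
    tok <- strsplit(strsplit(mmstr, ";", fixed = TRUE)[[1L]], "[:>]")
    pos <- as.integer(vapply(tok, `[`, character(1L), 1L))
    from <- vapply(tok, `[`, character(1L), 2L)
    to <- vapply(tok, `[`, character(1L), 3L)
    vseq <- germlines$seq[[v]]
    greg <- germlines$regions[[v]]
    fr3_end <- greg$UNION[["fr3_end"]]
    off <- annotations$v_start_offset[i]
    codon_i <- pos %/% 3L
    truncated <- (codon_i * 3L) < off        # codon partially missing 5'
    ambig <- !(to %in% c("A", "C", "G", "T")) | !(from %in% c("A", "C", "G", "T"))
    beyond <- pos >= fr3_end | (codon_i * 3L + 3L) > nchar(vseq)
    drop <- truncated | ambig | beyond
    excl[i] <- sum(drop)
    pos <- pos[!drop]; from <- from[!drop]; to <- to[!drop]
    codon_i <- codon_i[!drop]
    if (!length(pos)) next
    germ_codon <- substring(vseq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    obs_codon <- germ_codon
    o <- pos - codon_i * 3L
    substr(obs_codon, o + 1L, o + 1L) <- to
    rs <- classify_rs(germ_codon, obs_codon)
    reg <- region_of(pos, greg, scheme)
    mv[i] <- length(pos)
    r_cdr[i] <- sum(rs == "R" & reg %in% c("CDR1", "CDR2"))
    tabcols <- paste(tolower(reg), tolower(rs), sep = "_")
    for (cc in tabcols) counts[i, cc] <- counts[i, cc] + 1L
    mut_str[i] <- serialize_mutations(
      data.frame(pos = pos, from = from, to = to, region = reg, rs = rs,
                 stringsAsFactors = FALSE))
  }
  out <- data.frame(id = annotations$id,
                    isotype = if ("isotype" %in% names(annotations))
                      annotations$isotype else NA_character_,
                    group = group, mv = mv, r_cdr = r_cdr,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts))
  out$n_excluded <- excl
  out$pct_mutated <- ifelse(
    !is.na(annotations$v_aligned_len) & annotations$v_aligned_len > 0L,
    100 * mv / annotations$v_aligned_len, NA_real_)
  out$mutations <- mut_str
  out
}

#' Group-level mutation summary with t-tests
#'
#' Mean mutation count and mean mutation percentage per group, with
#' pairwise Welch (default) or Student t-tests on the mutation counts.
#' Groups with fewer than two members are summarised but excluded from
#' testing, with a warning.
#'
#' @param profiles data.frame from [build_profiles()].
#' @param group_col Column defining groups (default `"group"`).
#' @param var_equal Use the classical Student test instead of Welch.
#' @return list with `groups` (n, mean_mv, mean_pct per group) and `tests`
#'   (one row per compared pair: group1, group2, t, p).
#' @export
mutation_summary <- function(profiles, group_col = "group",
                             var_equal = FALSE) {
  g <- profiles[[group_col]]
  lv <- sort(unique(g[!is.na(g)]))
  groups <- do.call(rbind, lapply(lv, function(l) {
    sub <- profiles[g %in% l, , drop = FALSE]
    data.frame(group = l, n = nrow(sub), mean_mv = mean(sub$mv),
               mean_pct = mean(sub$pct_mutated, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(lv) >= 2L) {
    pairs <- utils::combn(lv, 2L, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      x <- profiles$mv[g %in% pr[1L]]
      y <- profiles$mv[g %in% pr[2L]]
      if (length(x) < 2L || length(y) < 2L) {
        warning("group with < 2 members: t-test skipped for ",
                pr[1L], " vs ", pr[2L])
        return(data.frame(group1 = pr[1L], group2 = pr[2L], t = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(group1 = pr[1L], group2 = pr[2L],
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, rows)
  }
  list(groups = groups, tests = tests)
}
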