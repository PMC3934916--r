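#' Configuration for the synthetic 454-style repertoire generator
#'
#' Collects every knob of the simulator in one validated object. Defaults
#' describe the study conditions the pipeline is calibrated against: clonal
#' replicate amplicons with geometric replicate counts, an IgE-heavy isotype
#' mix, per-lineage mutation loads uniform on 0..30, a CDR-replacement
#' probability of 0.26 under the null (no antigen selection) inflated to
#' 0.45 under selection, 454-like substitution and homopolymer-indel error
#' rates, 5' primer truncation, and a minority of unique sequences observed
#' in both read orientations.
#'
#' @param n_clones Number of B-cell clones (unique rearranged lineages).
#' @param replicate_mean Mean amplicon count per clone; counts are
#'   `1 + Geometric`, so the minimum is 1.
#' @param isotype_mix Named proportions for `IGE`, `IGG`, `UNCERTAIN`
#'   (must sum to 1). The default mirrors the composition of a mixed
#'   IgE/IgG amplicon pool.
#' @param mutation_range Integer support of the per-lineage true V-gene
#'   mutation count (sampled uniformly).
#' @param p_rcdr_null Probability that a placed mutation is a CDR
#'   replacement under the random (null) model.
#' @param selection_mode `"NULL"` or `"SELECTED"`; under `"SELECTED"` the
#'   CDR-replacement probability is `p_rcdr_selected`.
#' @param p_rcdr_selected Inflated CDR-replacement probability emulating
#'   antigen selection.
#' @param sub_rate Per-base substitution error rate.
#' @param hp_indel_rate Per-homopolymer-run (length >= 3) indel rate.
#' @param p_bidirectional Probability that a clone's unique sequence is
#'   read in both orientations (requires >= 2 replicates to realize).
#' @param trunc_mean,trunc_max 5' truncation (missing V nucleotides) is
#'   geometric with this mean, capped at `trunc_max`.
#' @param ambiguity_rate Per-read probability of containing an `N`.
#' @param p_inframe Probability that junction lengths are adjusted to keep
#'   the rearrangement in frame.
#' @param junction_max Maximum number of N-nucleotides on each side of D.
#' @param v_families V-gene families eligible for rearrangement.
#' @param seed Integer seed; all stochastic draws flow from one generator.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_clones = 200L,
                              replicate_mean = 5,
                              isotype_mix = c(IGE = 0.582, IGG = 0.316,
                                              UNCERTAIN = 0.102),
                              mutation_range = 0:30,
                              p_rcdr_null = 0.26,
                              selection_mode = c("NULL", "SELECTED"),
                              p_rcdr_selected = 0.45,
                              sub_rate = 1e-3,
                              hp_indel_rate = 5e-3,
                              p_bidirectional = 0.1,
                              trunc_mean = 15,
                              trunc_max = 60L,
                              ambiguity_rate = 0.02,
                              p_inframe = 0.95,
                              junction_max = 10L,
                              v_families = c("IGHV1", "IGHV3", "IGHV4"),
                              seed = NULL) {
  selection_mode <- match.arg(selection_mode)
  probs <- c(p_rcdr_null, p_rcdr_selected, sub_rate, hp_indel_rate,
             p_bidirectional, ambiguity_rate, p_inframe)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!setequal(names(isotype_mix), c("IGE", "IGG", "UNCERTAIN"))) {
    stop("isotype_mix must name IGE, IGG and UNCERTAIN")
  }
  if (abs(sum(isotype_mix) - 1) > 1e-8) stop("isotype_mix must sum to 1")
  if (n_clones < 0L) stop("n_clones must be non-negative")
  structure(list(
    n_clones = as.integer(n_clones), replicate_mean = replicate_mean,
    isotype_mix = isotype_mix, mutation_range = as.integer(mutation_range),
    p_rcdr_null = p_rcdr_null, selection_mode = selection_mode,
    p_rcdr_selected = p_rcdr_selected, sub_rate = sub_rate,
    hp_indel_rate = hp_indel_rate, p_bidirectional = p_bidirectional,
    trunc_mean = trunc_mean, trunc_max = as.integer(trunc_max),
    ambiguity_rate = ambiguity_rate, p_inframe = p_inframe,
    junction_max = as.integer(junction_max), v_families = v_families,
    seed = seed), class = "simulation_config")
}

# Enumerate every possible point mutation of a V gene within [0, FR3 end):
# one row per (position, alternative base), with its union-scheme region and
# replacement/silent status judged one-at-a-time against the germline codon.
mutation_options <- function(vseq, gene_regions) {
  fr3_end <- gene_regions$UNION[["fr3_end"]]
  bases <- c("A", "C", "G", "T")
  germ <- strsplit(substr(vseq, 1L, fr3_end), "")[[1L]]
  pos <- rep(seq_len(fr3_end) - 1L, each = 3L)
  from <- rep(germ, each = 3L)
  to <- unlist(lapply(germ, function(b) setdiff(bases, b)), use.names = FALSE)
  codon_i <- pos %/% 3L
  keep <- (codon_i * 3L + 3L) <= nchar(vseq)
  pos <- pos[keep]; from <- from[keep]; to <- to[keep]; codon_i <- codon_i[keep]
  germ_codon <- substring(vseq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  off <- pos - codon_i * 3L
  obs_codon <- germ_codon
  substr(obs_codon, off + 1L, off + 1L) <- to
  rs <- ifelse(translate_codon(germ_codon) == translate_codon(obs_codon), "S", "R")
  region <- region_of(pos, gene_regions, "UNION")
  data.frame(pos = pos, from = from, to = to, region = region, rs = rs,
             stringsAsFactors = FALSE)
}

#' Place somatic point mutations on a germline V gene
#'
#' Two-stage placement that pins the marginal probability of a
#' CDR-replacement mutation to `target_p_rcdr`: with that probability the
#' mutation is drawn uniformly from the (position, base) pairs that are
#' replacements inside the broadened CDR1/CDR2; otherwise uniformly from the
#' complement (any silent change, or any framework change). Mutations occupy
#' distinct positions.
#'
#' @param vseq Germline V nucleotide sequence.
#' @param gene_regions Region map of the gene (element of
#'   `repertoire$regions`).
#' @param n_mutations Number of mutations to place.
#' @param target_p_rcdr Marginal CDR-replacement probability.
#' @param opts Optional precomputed [mutation_options()] table.
#' @return A data.frame with columns `pos` (0-based), `from`, `to`,
#'   `region`, `rs`.
#' @export
place_mutations <- function(vseq, gene_regions, n_mutations, target_p_rcdr,
                            opts = NULL) {
  if (is.null(opts)) opts <- mutation_options(vseq, gene_regions)
  n_pos <- length(unique(opts$pos))
  if (n_mutations > n_pos) {
    stop("cannot place ", n_mutations, " mutations on ", n_pos, " positions")
  }
  is_cdrR <- opts$region %in% c("CDR1", "CDR2") & opts$rs == "R"
  out <- opts[0, , drop = FALSE]
  used <- integer(0)
  for (i in seq_len(n_mutations)) {
    pick_cdrR <- stats::runif(1) < target_p_rcdr
    pool <- opts[is_cdrR == pick_cdrR & !(opts$pos %in% used), , drop = FALSE]
    if (nrow(pool) == 0L) stop("mutation option pool exhausted")
    row <- pool[sample.int(nrow(pool), 1L), , drop = FALSE]
    out <- rbind(out, row)
    used <- c(used, row$pos)
  }
  rownames(out) <- NULL
  out
}

#' Apply 454-style sequencing errors to a read
#'
#' Substitutions occur independently per base; insertions/deletions are
#' placed within homopolymer runs of length >= 3 (the characteristic 454
#' failure mode), one coin flip per run. Injected errors are recorded with
#' their 0-based position in the input coordinate system.
#'
#' @param sequence Read sequence.
#' @param sub_rate Per-base substitution probability.
#' @param hp_indel_rate Per-homopolymer-run indel probability.
#' @return A list with `sequence` (corrupted) and `errors` (data.frame with
#'   columns `pos`, `type` in sub/ins/del, `from`, `to`).
#' @export
corrupt_read <- function(sequence, sub_rate, hp_indel_rate) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  errors <- list()
  if (sub_rate > 0 && n > 0L) {
    hit <- which(stats::runif(n) < sub_rate & chars %in% bases)
    for (i in hit) {
      new <- sample(setdiff(bases, chars[i]), 1L)
      errors[[length(errors) + 1L]] <- data.frame(
        pos = i - 1L, type = "sub", from = chars[i], to = new,
        stringsAsFactors = FALSE)
      chars[i] <- new
    }
  }
  if (hp_indel_rate > 0 && n >= 3L) {
    r <- rle(chars)
    run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    runs <- which(r$lengths >= 3L & r$values %in% bases)
    indels <- list()
    for (k in runs) {
      if (stats::runif(1) >= hp_indel_rate) next
      ins <- stats::runif(1) < 0.5
      indels[[length(indels) + 1L]] <- list(start = run_start[k],
                                            base = r$values[k], ins = ins)
      errors[[length(errors) + 1L]] <- data.frame(
        pos = run_start[k] - 1L, type = if (ins) "ins" else "del",
        from = if (ins) "" else r$values[k], to = if (ins) r$values[k] else "",
        stringsAsFactors = FALSE)
    }
    if (length(indels)) {
      # right-to-left so earlier positions stay valid
      ord <- order(vapply(indels, `[[`, numeric(1), "start"), decreasing = TRUE)
      for (idl in indels[ord]) {
        if (idl$ins) {
          chars <- append(chars, idl$base, after = idl$start - 1L)
        } else {
          chars <- chars[-idl$start]
        }
      }
    }
  }
  err <- if (length(errors)) do.call(rbind, errors) else
    data.frame(pos = integer(), type = character(), from = character(),
               to = character(), stringsAsFactors = FALSE)
  list(sequence = paste(chars, collapse = ""), errors = err)
}

# 0-based offset of the conserved FR4 tryptophan codon within a J gene
# (first TGGGG motif, falling back to the first TGG).
j_trp_offset <- function(jseq) {
  m <- regexpr("TGGGG", jseq, fixed = TRUE)
  if (m < 0L) m <- regexpr("TGG", jseq, fixed = TRUE)
  if (m < 0L) return(NA_integer_)
  as.integer(m) - 1L
}

#' Simulate a 454-style amplicon repertoire with a ground-truth table
#'
#' Generates clonal VDJ rearrangements from the supplied germline
#' repertoire, places somatic mutations on the V gene with a controlled
#' CDR-replacement fraction, amplifies each clone into replicate amplicons,
#' and emits per-read sequences with 5' primer truncation, constant-region
#' primer-site tags determining isotype, forward/reverse orientations,
#' substitution and homopolymer-indel sequencing errors, and occasional
#' ambiguity characters. Every emitted read has exactly one truth record.
#'
#' @param config A [simulation_config()].
#' @param germlines A `germline_repertoire`.
#' @return A list with `reads` (data.frame: `id`, `sequence`) and `truth`
#'   (data.frame: one row per read with clone id, true genes, serialized
#'   mutation list, isotype, orientation, bidirectional flag, truncation and
#'   injected errors).
#' @export
simulate_repertoire <- function(config, germlines) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(germlines, "germline_repertoire"))
  vg <- genes_of(germlines, "V")
  vg <- vg[germlines$family[vg] %in% config$v_families]
  dg <- genes_of(germlines, "D")
  jg <- genes_of(germlines, "J")
  if (length(vg) == 0L || length(jg) == 0L) {
    stop("germline repertoire lacks eligible V or J genes")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  opts_cache <- lapply(vg, function(g)
    mutation_options(germlines$seq[[g]], germlines$regions[[g]]))
  names(opts_cache) <- vg
  trp_cache <- vapply(jg, function(g) j_trp_offset(germlines$seq[[g]]),
                      integer(1L))
  primer_rc <- revcomp(ig_primers())
  bases <- c("A", "C", "G", "T")
  p_target <- if (config$selection_mode == "SELECTED")
    config$p_rcdr_selected else config$p_rcdr_null

  reads <- list(); truth <- list(); rid <- 0L
  for (cl in seq_len(config$n_clones)) {
    v <- if (length(vg) == 1L) vg else sample(vg, 1L)
    d <- if (length(dg) == 0L) NA_character_ else
      if (length(dg) == 1L) dg else sample(dg, 1L)
    j <- if (length(jg) == 1L) jg else sample(jg, 1L)
    vseq <- germlines$seq[[v]]
    dseq <- if (is.na(d)) "" else germlines$seq[[d]]
    jseq <- germlines$seq[[j]]
    trp <- trp_cache[[j]]
    n1 <- sample.int(config$junction_max + 1L, 1L) - 1L
    n2 <- sample.int(config$junction_max + 1L, 1L) - 1L
    force_frame <- stats::runif(1) < config$p_inframe
    if (force_frame) {
      rem <- (n1 + nchar(dseq) + n2 + trp) %% 3L
      if (rem != 0L) n2 <- n2 + (3L - rem)
    }
    # junction content; for in-frame clones redraw until the junction/J head
    # introduces no stop codon in the V reading frame (expressed-repertoire
    # realism: productive rearrangements are what gets sequenced from mRNA)
    v_len <- nchar(vseq)
    for (try in 1:25) {
      n1seq <- paste(sample(bases, n1, replace = TRUE), collapse = "")
      n2seq <- paste(sample(bases, n2, replace = TRUE), collapse = "")
      core <- paste0(vseq, n1seq, dseq, n2seq, jseq)
      if (!force_frame) break
      span <- substr(core, v_len + 1L, v_len + n1 + nchar(dseq) + n2 + trp + 3L)
      cods <- substring(span, seq(1L, max(nchar(span) - 2L, 1L), 3L),
                        seq(3L, max(nchar(span), 3L), 3L))
      if (!any(cods %in% STOP_CODONS)) break
    }
    m <- if (length(config$mutation_range) == 1L) config$mutation_range else
      sample(config$mutation_range, 1L)
    muts <- place_mutations(vseq, germlines$regions[[v]], m, p_target,
                            opts = opts_cache[[v]])
    mutated <- core
    if (nrow(muts)) {
      ch <- strsplit(mutated, "")[[1L]]
      ch[muts$pos + 1L] <- muts$to
      mutated <- paste(ch, collapse = "")
    }
    isotype <- sample(names(config$isotype_mix), 1L, prob = config$isotype_mix)
    tag <- switch(isotype,
                  IGE = primer_rc[["IGE"]],
                  IGG = primer_rc[["IGG"]],
                  UNCERTAIN = substr(primer_rc[[sample(c("IGE", "IGG"), 1L)]], 1L, 8L))
    full <- paste0(mutated, tag)

    r <- 1L + stats::rgeom(1L, 1 / max(config$replicate_mean, 1))
    want_bidir <- stats::runif(1) < config$p_bidirectional
    if (want_bidir && r >= 2L) {
      orient <- sample(c("FORWARD", "REVERSE"), r, replace = TRUE)
      orient[1:2] <- c("FORWARD", "REVERSE")
    } else {
      orient <- rep(sample(c("FORWARD", "REVERSE"), 1L), r)
    }
    realized_bidir <- length(unique(orient)) == 2L

    for (k in seq_len(r)) {
      rid <- rid + 1L
      tr <- min(stats::rgeom(1L, 1 / (config$trunc_mean + 1)), config$trunc_max)
      readseq <- substr(full, tr + 1L, nchar(full))
      res <- corrupt_read(readseq, config$sub_rate, config$hp_indel_rate)
      readseq <- res$sequence
      err <- res$errors
      if (stats::runif(1) < config$ambiguity_rate && nchar(readseq) > 0L) {
        p <- sample.int(nchar(readseq), 1L)
        err <- rbind(err, data.frame(pos = p - 1L, type = "amb",
                                     from = substr(readseq, p, p), to = "N",
                                     stringsAsFactors = FALSE))
        substr(readseq, p, p) <- "N"
      }
      if (orient[k] == "REVERSE") readseq <- revcomp(readseq)
      id <- sprintf("R%06d", rid)
      reads[[rid]] <- data.frame(id = id, sequence = readseq,
                                 stringsAsFactors = FALSE)
      truth[[rid]] <- data.frame(
        read_id = id, clone_id = sprintf("C%04d", cl),
        v_gene = v, d_gene = d, j_gene = j, isotype = isotype,
        orientation = orient[k], bidirectional = realized_bidir,
        n_mutations = m, mutations = serialize_mutations(muts),
        truncation = tr, n_errors = nrow(err),
        errors = if (nrow(err)) paste(sprintf("%d:%s", err$pos, err$type),
                                      collapse = ";") else "",
        stringsAsFactors = FALSE)
    }
  }
  if (rid == 0L) {
    return(list(
      reads = data.frame(id = character(), sequence = character(),
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = character(), clone_id = character(),
                         v_gene = character(), d_gene = character(),
                         j_gene = character(), isotype = character(),
                         orientation = character(), bidirectional = logical(),
                         n_mutations = integer(), mutations = character(),
                         truncation = integer(), n_errors = integer(),
                         errors = character(), stringsAsFactors = FALSE)))
  }
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
}

#' Write simulated reads to FASTA and the truth table to TSV
#'
#' @param sim Result of [simulate_repertoire()].
#' @param fasta_path,truth_path Output paths (`NULL` to skip one).
#' @return Invisibly, `sim`.
#' @export
write_simulation <- function(sim, fasta_path = NULL, truth_path = NULL) {
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(sim$reads$sequence)
    names(ss) <- sim$reads$id
    Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  }
  if (!is.null(truth_path)) write_tsv(sim$truth, truth_path)
  invisible(sim)
}
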