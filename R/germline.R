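#' Germline gene repertoires with framework/CDR region maps
#'
#' A germline repertoire holds the IGHV, IGHD and IGHJ reference sequences
#' against which rearranged heavy-chain reads are annotated. Each V gene
#' carries a region map partitioning its sequence into FR1, CDR1, FR2, CDR2
#' and FR3 under two numbering conventions (Kabat and IMGT), from which a
#' broadened "union" CDR definition is derived: a position counts as CDR1
#' (or CDR2) under the union scheme when it falls inside the CDR1 (CDR2) of
#' either convention. The union scheme is what the downstream
#' replacement-mutation statistic uses, so that no plausibly
#' antigen-contacting position is scored as framework.
#'
#' Coordinates throughout are 0-based, half-open, in ungapped V-gene
#' nucleotide space. D and J genes have no region map.
#'
#' @param fasta_path Path to a germline FASTA file. Record identifiers must
#'   be unique; sequences must contain only A, C, G, T.
#' @param regions_path Path to a TSV with columns
#'   `gene scheme fr1_start cdr1_start fr2_start cdr2_start fr3_start fr3_end`
#'   giving, for every V gene and for both schemes `KABAT` and `IMGT`, the
#'   0-based half-open region boundaries.
#' @return An object of class `germline_repertoire`: a list with character
#'   vectors `seq`, `segment`, `family` (all named by gene) and a named list
#'   `regions` holding, per V gene, the `KABAT`, `IMGT` and derived `UNION`
#'   boundary sets.
#' @examples
#' rep <- load_repertoire(
#'   system.file("extdata", "synthetic_germline.fasta", package = "shmselect"),
#'   system.file("extdata", "synthetic_regions.tsv", package = "shmselect"))
#' rep
#' region_of(0, rep$regions[[1]], "UNION")
#' @export
load_repertoire <- function(fasta_path, regions_path) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  nm <- names(fa)
  nm <- sub("\\s.*$", "", nm)  # keep identifier up to first whitespace
  if (anyDuplicated(nm)) {
    stop("duplicate gene name(s) in repertoire FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(fa))
  names(seqs) <- nm
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGT character in reference sequence(s): ",
         paste(nm[bad], collapse = ", "))
  }
  segment <- ifelse(grepl("^IGHV", nm), "V",
                    ifelse(grepl("^IGHD", nm), "D",
                           ifelse(grepl("^IGHJ", nm), "J", NA_character_)))
  if (anyNA(segment)) {
    stop("cannot infer segment (IGHV/IGHD/IGHJ prefix) for: ",
         paste(nm[is.na(segment)], collapse = ", "))
  }
  names(segment) <- nm
  family <- sub("[-*].*$", "", nm)
  names(family) <- nm

  rt <- read_tsv(regions_path)
  needed <- c("gene", "scheme", "fr1_start", "cdr1_start", "fr2_start",
              "cdr2_start", "fr3_start", "fr3_end")
  if (!all(needed %in% names(rt))) {
    stop("regions table missing column(s): ",
         paste(setdiff(needed, names(rt)), collapse = ", "))
  }
  unknown <- setdiff(rt$gene, nm)
  if (length(unknown)) {
    stop("regions table references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  vgenes <- nm[segment == "V"]
  regions <- list()
  for (g in vgenes) {
    sub <- rt[rt$gene == g, , drop = FALSE]
    schemes <- list()
    for (sc in c("KABAT", "IMGT")) {
      row <- sub[sub$scheme == sc, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop("V gene ", g, " must have exactly one ", sc, " region row")
      }
      b <- as.integer(row[1L, c("fr1_start", "cdr1_start", "fr2_start",
                                "cdr2_start", "fr3_start", "fr3_end")])
      names(b) <- c("fr1_start", "cdr1_start", "fr2_start", "cdr2_start",
                    "fr3_start", "fr3_end")
      if (b[["fr1_start"]] != 0L) stop("FR1 of ", g, " must start at 0")
      if (any(diff(b) <= 0L)) {
        stop("region boundaries of ", g, " (", sc, ") must be strictly increasing")
      }
      if (b[["fr3_end"]] > nchar(seqs[[g]])) {
        stop("FR3 end of ", g, " (", sc, ") exceeds sequence length")
      }
      schemes[[sc]] <- b
    }
    if (schemes$KABAT[["fr3_end"]] != schemes$IMGT[["fr3_end"]]) {
      stop("KABAT and IMGT FR3 ends differ for ", g)
    }
    schemes$UNION <- union_scheme(schemes$KABAT, schemes$IMGT)
    regions[[g]] <- schemes
  }
  missing_map <- setdiff(vgenes, names(regions))
  if (length(missing_map)) {
    stop("V gene(s) missing region annotation: ",
         paste(missing_map, collapse = ", "))
  }
  structure(
    list(seq = seqs, segment = segment, family = family, regions = regions),
    class = "germline_repertoire")
}

# Broadened CDR boundaries: each union CDR is the smallest interval
# containing the Kabat and IMGT CDRs.
union_scheme <- function(kabat, imgt) {
  c(fr1_start = 0L,
    cdr1_start = min(kabat[["cdr1_start"]], imgt[["cdr1_start"]]),
    fr2_start = max(kabat[["fr2_start"]], imgt[["fr2_start"]]),
    cdr2_start = min(kabat[["cdr2_start"]], imgt[["cdr2_start"]]),
    fr3_start = max(kabat[["fr3_start"]], imgt[["fr3_start"]]),
    fr3_end = kabat[["fr3_end"]])
}

#' @export
print.germline_repertoire <- function(x, ...) {
  tab <- table(factor(x$segment, levels = c("V", "D", "J")))
  cat("Germline repertoire:", length(x$seq), "genes (",
      tab[["V"]], "V,", tab[["D"]], "D,", tab[["J"]], "J )\n")
  if (tab[["V"]] > 0L) {
    cat("Families:", paste(sort(unique(x$family[x$segment == "V"])),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Region label of a V-gene position
#'
#' Maps 0-based V-gene nucleotide positions to region labels FR1, CDR1, FR2,
#' CDR2 or FR3 under a chosen numbering scheme. Under `UNION`, a position
#' inside either the Kabat or the IMGT CDR1 (resp. CDR2) is labelled CDR1
#' (CDR2). Positions at or beyond the FR3 end (i.e. in the CDR3/junction)
#' are an error: mutations 3' of the V gene are not regioned.
#'
#' @param position Integer vector of 0-based positions.
#' @param gene_regions The per-gene region map, i.e. one element of
#'   `repertoire$regions` (a list with `KABAT`, `IMGT`, `UNION` boundary sets).
#' @param scheme One of `"KABAT"`, `"IMGT"`, `"UNION"`.
#' @return Character vector of region labels, same length as `position`.
#' @export
region_of <- function(position, gene_regions, scheme = c("UNION", "KABAT", "IMGT")) {
  scheme <- match.arg(scheme)
  b <- gene_regions[[scheme]]
  if (any(position < 0L) || any(position >= b[["fr3_end"]])) {
    stop("position outside the annotated V span [0, ", b[["fr3_end"]], ")")
  }
  labs <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")
  idx <- findInterval(position, b[-length(b)])
  labs[idx]
}

#' Write a germline repertoire back to FASTA + regions TSV
#'
#' Inverse of [load_repertoire()]; reloading the written files reproduces an
#' identical repertoire (including derived union region maps).
#'
#' @param repertoire A `germline_repertoire`.
#' @param fasta_path,regions_path Output paths.
#' @return Invisibly, the repertoire.
#' @export
write_repertoire <- function(repertoire, fasta_path, regions_path) {
  ss <- Biostrings::DNAStringSet(repertoire$seq)
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  rows <- list()
  for (g in names(repertoire$regions)) {
    for (sc in c("KABAT", "IMGT")) {
      b <- repertoire$regions[[g]][[sc]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, scheme = sc,
        fr1_start = b[["fr1_start"]], cdr1_start = b[["cdr1_start"]],
        fr2_start = b[["fr2_start"]], cdr2_start = b[["cdr2_start"]],
        fr3_start = b[["fr3_start"]], fr3_end = b[["fr3_end"]],
        stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, rows), regions_path)
  invisible(repertoire)
}

# Names of genes of a given segment.
genes_of <- function(repertoire, segment) {
  names(repertoire$seq)[repertoire$segment == segment]
}

#' Default packaged germline repertoire
#'
#' Loads the small synthetic repertoire shipped with the package
#' (8 V genes from the IGHV1/3/4/5 families, 4 D, 4 J, with realistic
#' FR/CDR lengths). It exists because curated germline databases cannot be
#' redistributed; analyses of real data should point [load_repertoire()] at
#' a proper reference.
#'
#' @return A `germline_repertoire`.
#' @export
default_repertoire <- function() {
  load_repertoire(
    system.file("extdata", "synthetic_germline.fasta", package = "shmselect"),
    system.file("extdata", "synthetic_regions.tsv", package = "shmselect"))
}
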