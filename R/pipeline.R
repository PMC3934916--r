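#' Pipeline configuration
#'
#' Bundles all inputs and parameters of [run_pipeline()]. Reads come either
#' from a FASTA file (`reads_fasta`) or from the synthetic generator
#' (`sim_config`); the germline reference either from files or from an
#' in-memory repertoire.
#'
#' @param germline_fasta,regions_tsv Paths to the germline reference (both
#'   `NULL` to use `repertoire`).
#' @param repertoire A `germline_repertoire` (default: the packaged
#'   synthetic reference).
#' @param reads_fasta Path to a reads FASTA (`NULL` when simulating).
#' @param sim_config A [simulation_config()] (`NULL` when reading FASTA).
#' @param max_offset,max_mutations Dataset A filter caps.
#' @param p_rcdr,alpha_upper Random-mutation model parameters.
#' @param on_boundary_selected,yates Boundary and chi-square switches.
#' @param group_map Optional named vector mapping sequence/read ids to
#'   donor groups; by default groups are isotypes.
#' @param seed Seed for the simulation branch.
#' @param out_dir Directory for the report bundle files (`NULL`: in-memory
#'   only).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(germline_fasta = NULL, regions_tsv = NULL,
                            repertoire = NULL, reads_fasta = NULL,
                            sim_config = NULL, max_offset = 45L,
                            max_mutations = 45L, p_rcdr = 0.26,
                            alpha_upper = 0.025,
                            on_boundary_selected = FALSE, yates = FALSE,
                            group_map = NULL, seed = NULL, out_dir = NULL) {
  if (!is.null(germline_fasta) || !is.null(regions_tsv)) {
    stopifnot(file.exists(germline_fasta), file.exists(regions_tsv))
  }
  if (!is.null(reads_fasta)) stopifnot(file.exists(reads_fasta))
  if (is.null(reads_fasta) && is.null(sim_config)) {
    stop("either reads_fasta or sim_config must be given")
  }
  stopifnot(p_rcdr > 0, p_rcdr < 1, alpha_upper > 0, alpha_upper < 0.5,
            max_offset >= 0, max_mutations >= 0)
  structure(list(germline_fasta = germline_fasta, regions_tsv = regions_tsv,
                 repertoire = repertoire, reads_fasta = reads_fasta,
                 sim_config = sim_config, max_offset = max_offset,
                 max_mutations = max_mutations, p_rcdr = p_rcdr,
                 alpha_upper = alpha_upper,
                 on_boundary_selected = on_boundary_selected, yates = yates,
                 group_map = group_map, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full repertoire analysis pipeline
#'
#' End to end: load (or simulate) reads, assign isotypes, orient and
#' deduplicate, annotate V(D)J, apply the Dataset A filter cascade, the
#' bidirectional filter (Dataset B) and clonal collapsing (Dataset C),
#' build mutation profiles, fit the antigen-selection model, and summarise
#' per group. When `config$out_dir` is set, the bundle is also written as
#' TSV tables, a JSON-lines run log, and a selection scatter figure.
#'
#' @param config A [pipeline_config()].
#' @return A list (class `shm_report`): `datasets` (A, B, C), `tallies`,
#'   `sizes` (per-dataset x isotype counts), `quality` (stop/OOF tallies
#'   per dataset), `profiles`, `mutation_summary`, `fit`
#'   (`antigen_selection` on Dataset C), `selection_summary`, `clones`,
#'   `truth` (simulation branch only), `log` (parameters).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  germ <- if (!is.null(config$repertoire)) config$repertoire
          else if (!is.null(config$germline_fasta))
            load_repertoire(config$germline_fasta, config$regions_tsv)
          else default_repertoire()
  truth <- NULL
  if (!is.null(config$sim_config)) {
    sc <- config$sim_config
    if (!is.null(config$seed)) sc$seed <- config$seed
    sim <- simulate_repertoire(sc, germ)
    reads <- sim$reads
    truth <- sim$truth
  } else {
    fa <- Biostrings::readDNAStringSet(config$reads_fasta)
    reads <- data.frame(id = sub("\\s.*$", "", names(fa)),
                        sequence = toupper(as.character(fa)),
                        stringsAsFactors = FALSE)
  }
  message(sprintf("[reads] %d raw reads", nrow(reads)))
  uniq <- orient_and_deduplicate(reads, germ)
  n_dup <- nrow(reads) - nrow(uniq)
  message(sprintf("[dedup] %d unique sequences (%d duplicates collapsed)",
                  nrow(uniq), n_dup))
  ann <- annotate_vdj(uniq, germ)
  fa_res <- filter_dataset_a(ann, config$max_offset, config$max_mutations,
                             n_duplicates = n_dup)
  dsA <- fa_res$dataset
  message(sprintf("[dataset A] %d sequences", nrow(dsA)))
  dsB <- filter_bidirectional(dsA)
  message(sprintf("[dataset B] %d sequences", nrow(dsB)))
  cc <- collapse_clones(dsB)
  dsC <- cc$dataset
  message(sprintf("[dataset C] %d sequences (%d clone groups)",
                  nrow(dsC), nrow(cc$clones)))

  iso_levels <- c("IGE", "IGG", "UNCERTAIN")
  size_row <- function(ds) {
    tab <- table(factor(ds$isotype, levels = iso_levels))
    data.frame(IGE = tab[["IGE"]], IGG = tab[["IGG"]],
               UNCERTAIN = tab[["UNCERTAIN"]], total = nrow(ds))
  }
  sizes <- cbind(data.frame(dataset = c("A", "B", "C"),
                            stringsAsFactors = FALSE),
                 rbind(size_row(dsA), size_row(dsB), size_row(dsC)))
  quality <- do.call(rbind, lapply(list(A = dsA, B = dsB, C = dsC),
    function(ds) quality_tally(ds)))
  quality$dataset <- rep(c("A", "B", "C"), each = 2L)
  rownames(quality) <- NULL

  grp <- NULL
  if (!is.null(config$group_map)) {
    grp <- unname(config$group_map[dsA$id])
  }
  profiles <- if (nrow(dsA)) build_profiles(dsA, germ, group = grp)
              else build_profiles(dsA, germ)
  mut_sum <- if (nrow(profiles) >= 2L)
    suppressWarnings(mutation_summary(profiles)) else NULL
  prof_c <- profiles[profiles$id %in% dsC$id, , drop = FALSE]
  fit <- NULL; sel_sum <- NULL
  if (nrow(prof_c)) {
    fit <- antigen_selection(prof_c, config$p_rcdr, config$alpha_upper,
                             config$on_boundary_selected)
    sel_sum <- suppressWarnings(group_selection_summary(
      fit$results, fit$results$group, yates = config$yates))
  }

  bundle <- structure(list(
    datasets = list(A = dsA, B = dsB, C = dsC),
    tallies = fa_res$tally, sizes = sizes, quality = quality,
    profiles = profiles, mutation_summary = mut_sum, fit = fit,
    selection_summary = sel_sum, clones = cc$clones, truth = truth,
    log = list(parameters = list(
      max_offset = config$max_offset, max_mutations = config$max_mutations,
      p_rcdr = config$p_rcdr, alpha_upper = config$alpha_upper,
      on_boundary_selected = config$on_boundary_selected,
      yates = config$yates, seed = config$seed),
      n_raw_reads = nrow(reads), n_unique = nrow(uniq),
      n_duplicates = n_dup,
      package_version = as.character(utils::packageVersion("shmselect")))),
    class = "shm_report")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' @export
print.shm_report <- function(x, ...) {
  cat("Repertoire analysis report\n")
  cat(sprintf("  raw reads: %d; unique: %d\n", x$log$n_raw_reads,
              x$log$n_unique))
  cat("  dataset sizes:\n")
  print(x$sizes, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat("\n")
    print(x$fit)
  }
  invisible(x)
}

# Serialize a report bundle to TSV tables + JSON-lines log + figure.
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  drop_cols <- function(df) df[, setdiff(names(df), "sequence"), drop = FALSE]
  for (nm in names(bundle$datasets)) {
    write_tsv(drop_cols(bundle$datasets[[nm]]),
              file.path(out_dir, paste0("dataset_", nm, ".tsv")))
  }
  write_tsv(bundle$sizes, file.path(out_dir, "dataset_sizes.tsv"))
  write_tsv(bundle$quality, file.path(out_dir, "quality.tsv"))
  write_tsv(data.frame(rule = names(bundle$tallies),
                       removed = as.integer(bundle$tallies)),
            file.path(out_dir, "filter_tally.tsv"))
  write_tsv(bundle$profiles, file.path(out_dir, "profiles.tsv"))
  if (!is.null(bundle$fit)) {
    write_tsv(bundle$fit$results, file.path(out_dir, "selection.tsv"))
    write_tsv(bundle$fit$boundary, file.path(out_dir, "boundary.tsv"))
    if (!is.null(bundle$selection_summary)) {
      write_tsv(bundle$selection_summary$groups,
                file.path(out_dir, "selection_groups.tsv"))
    }
    plot_selection_scatter(bundle$fit,
                           file = file.path(out_dir, "selection_scatter.pdf"))
  }
  log_lines <- c(
    jsonlite::toJSON(c(list(record = "parameters"),
                       bundle$log$parameters), auto_unbox = TRUE),
    jsonlite::toJSON(list(record = "counts",
                          n_raw_reads = bundle$log$n_raw_reads,
                          n_unique = bundle$log$n_unique,
                          n_duplicates = bundle$log$n_duplicates,
                          tally = as.list(bundle$tallies)),
                     auto_unbox = TRUE),
    jsonlite::toJSON(list(record = "versions",
                          shmselect = bundle$log$package_version,
                          R = paste(R.version$major, R.version$minor,
                                    sep = ".")), auto_unbox = TRUE))
  writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  invisible(bundle)
}

#' Scatter of CDR replacement load against mutation count
#'
#' Plots r_cdr/mv against mv for every mutated sequence, with the model's
#' 97.5% boundary line (k*/mv); selected points are drawn filled. Optional
#' deterministic jitter separates overplotted points; with jitter disabled
#' the coordinates are the raw values. When `file` is given the figure is
#' written there (PDF) along with a sidecar TSV of the plotted points and
#' their selection flags.
#'
#' @param fit An `antigen_selection` object (or a list with `results` and
#'   `boundary`).
#' @param file Optional output PDF path.
#' @param jitter Apply small deterministic jitter.
#' @param jitter_seed Seed for the jitter.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted coordinates data.frame.
#' @export
plot_selection_scatter <- function(fit, file = NULL, jitter = TRUE,
                                   jitter_seed = 1L,
                                   main = "CDR replacement load vs mutation count",
                                   ...) {
  res <- fit$results[fit$results$mv >= 1L, , drop = FALSE]
  if (nrow(res) == 0L) stop("no mutated sequences to plot")
  x <- res$mv
  y <- res$r_cdr / res$mv
  if (jitter) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(jitter_seed)
    x <- x + stats::runif(length(x), -0.25, 0.25)
    y <- y + stats::runif(length(y), -0.008, 0.008)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (!is.null(file)) grDevices::pdf(file, width = 7, height = 5)
  bd <- fit$boundary
  graphics::plot(x, y, pch = ifelse(res$selected, 16L, 1L),
                 col = ifelse(res$selected, "firebrick", "grey30"),
                 xlab = "Total IGHV mutations (Mv)",
                 ylab = expression(R[CDR] / M[v]),
                 ylim = c(0, max(1, y)), main = main, ...)
  graphics::lines(bd$mv, bd$ratio, lwd = 2)
  graphics::legend("topright", pch = c(16L, 1L),
                   col = c("firebrick", "grey30"),
                   legend = c("selected", "not selected"), bty = "n")
  if (!is.null(file)) {
    grDevices::dev.off()
    write_tsv(data.frame(id = res$id, mv = res$mv, r_cdr = res$r_cdr,
                         selected = res$selected),
              paste0(sub("\\.pdf$", "", file), "_points.tsv"))
  }
  invisible(data.frame(x = x, y = y, selected = res$selected))
}
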