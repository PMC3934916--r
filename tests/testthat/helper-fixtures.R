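# Shared fixtures, memoized so expensive simulations run once per session.

fixture_env <- new.env(parent = emptyenv())

test_repertoire <- function() {
  if (is.null(fixture_env$rep)) fixture_env$rep <- default_repertoire()
  fixture_env$rep
}

# Noise-free study conditions: single replicate, no truncation, no errors.
noiseless_config <- function(n_clones, seed, ...) {
  simulation_config(n_clones = n_clones, sub_rate = 0, hp_indel_rate = 0,
                    ambiguity_rate = 0, trunc_mean = 0, trunc_max = 0L,
                    replicate_mean = 1, p_bidirectional = 0, seed = seed, ...)
}

# Medium noiseless repertoire, simulated + deduplicated + annotated once.
noiseless_run <- function() {
  if (is.null(fixture_env$nr)) {
    rep <- test_repertoire()
    sim <- simulate_repertoire(noiseless_config(120L, seed = 101L), rep)
    uniq <- orient_and_deduplicate(sim$reads, rep)
    ann <- annotate_vdj(uniq, rep)
    truth <- sim$truth[match(uniq$id, sim$truth$read_id), ]
    fixture_env$nr <- list(sim = sim, uniq = uniq, ann = ann, truth = truth)
  }
  fixture_env$nr
}

# Noisy repertoire with replicates, orientation mix and errors, run end to
# end through dedup + annotation + the filter cascade.
noisy_run <- function() {
  if (is.null(fixture_env$noisy)) {
    rep <- test_repertoire()
    cfg <- simulation_config(n_clones = 100L, replicate_mean = 4,
                             p_bidirectional = 0.5, seed = 202L)
    sim <- simulate_repertoire(cfg, rep)
    uniq <- orient_and_deduplicate(sim$reads, rep)
    ann <- annotate_vdj(uniq, rep)
    fa <- filter_dataset_a(ann, n_duplicates = nrow(sim$reads) - nrow(uniq))
    fixture_env$noisy <- list(sim = sim, uniq = uniq, ann = ann, fa = fa)
  }
  fixture_env$noisy
}

# Independent brute-force threshold oracle: enumerate the binomial pmf with
# choose() and scan tails from the top.
oracle_threshold <- function(mv, p, alpha) {
  pmf <- choose(mv, 0:mv) * p^(0:mv) * (1 - p)^(mv - (0:mv))
  tails <- rev(cumsum(rev(pmf)))
  k <- which(tails <= alpha)
  if (length(k)) k[1L] - 1L else mv + 1L
}

# Parse one serialized mutation/mismatch token list into position strings.
mismatch_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}

# Build a read from germline parts: V (optionally mutated/truncated) +
# junction + J + isotype tag.
build_read <- function(rep, v, j, n1 = "ACA", isotype = "IGE") {
  tag <- revcomp_str(ig_primers()[[isotype]])
  paste0(rep$seq[[v]], n1, rep$seq[[j]], tag)
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
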