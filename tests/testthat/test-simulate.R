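test_that("simulation is reproducible and truth records are in bijection with reads", {
  rep <- test_repertoire()
  cfg <- simulation_config(n_clones = 25L, seed = 55L)
  s1 <- simulate_repertoire(cfg, rep)
  s2 <- simulate_repertoire(cfg, rep)
  expect_identical(s1, s2)
  expect_identical(sort(s1$reads$id), sort(s1$truth$read_id))
  expect_false(anyDuplicated(s1$reads$id) > 0L)
  # empty and error cases
  s0 <- simulate_repertoire(simulation_config(n_clones = 0L, seed = 1L), rep)
  expect_equal(nrow(s0$reads), 0L)
  expect_equal(nrow(s0$truth), 0L)
  empty_rep <- structure(list(seq = character(), segment = character(),
                              family = character(), regions = list()),
                         class = "germline_repertoire")
  expect_error(simulate_repertoire(cfg, empty_rep), "lacks eligible")
})

test_that("mutation placement hits boundary parameters and occupies distinct positions", {
  rep <- test_repertoire()
  g <- names(rep$regions)[1L]
  vseq <- rep$seq[[g]]; greg <- rep$regions[[g]]
  expect_equal(nrow(place_mutations(vseq, greg, 0L, 0.26)), 0L)
  set.seed(1)
  m5 <- place_mutations(vseq, greg, 5L, 1.0)
  expect_true(all(m5$region %in% c("CDR1", "CDR2")))
  expect_true(all(m5$rs == "R"))
  expect_false(anyDuplicated(m5$pos) > 0L)
  expect_error(place_mutations(vseq, greg, 10000L, 0.26), "cannot place")
})

test_that("placed mutations hit the target CDR-replacement fraction", {
  rep <- test_repertoire()
  g <- names(rep$regions)[2L]
  set.seed(7)
  draws <- replicate(800L, {
    m <- place_mutations(rep$seq[[g]], rep$regions[[g]], 15L, 0.26)
    sum(m$region %in% c("CDR1", "CDR2") & m$rs == "R")
  })
  n_mut <- 800L * 15L
  frac <- sum(draws) / n_mut
  se <- sqrt(0.26 * 0.74 / n_mut)
  expect_lt(abs(frac - 0.26), 3 * se)
})

test_that("null mutation counts follow Binomial(Mv, 0.26) by chi-square fit", {
  rep <- test_repertoire()
  g <- names(rep$regions)[1L]
  vseq <- rep$seq[[g]]; greg <- rep$regions[[g]]
  opts <- shmselect:::mutation_options(vseq, greg)
  set.seed(42)
  for (mv in c(5L, 10L, 20L)) {
    r_cdr <- replicate(2000L, {
      m <- place_mutations(vseq, greg, mv, 0.26, opts = opts)
      sum(m$region %in% c("CDR1", "CDR2") & m$rs == "R")
    })
    expected <- dbinom(0:mv, mv, 0.26)
    # pool tail bins with small expected counts for a valid chi-square
    keep <- expected * 2000 >= 5
    obs <- tabulate(r_cdr + 1L, nbins = mv + 1L)
    o <- c(obs[keep], sum(obs[!keep]))
    e <- c(expected[keep], sum(expected[!keep]))
    pval <- suppressWarnings(chisq.test(o, p = e / sum(e))$p.value)
    expect_gt(pval, 0.001)
  }
})

test_that("read corruption matches its error model", {
  # identity at zero rates
  s <- "ACGTACGTAAAACGT"
  expect_identical(corrupt_read(s, 0, 0)$sequence, s)
  # forced homopolymer indel changes length
  set.seed(3)
  out <- corrupt_read("ACGTAAAACGT", 0, 1.0)
  expect_true(nchar(out$sequence) != 11L)
  expect_true(all(out$errors$type %in% c("ins", "del")))
  # substitution count is binomial: 2,000 reads x 300 nt at 1% per base
  set.seed(9)
  reads <- vapply(1:2000, function(i)
    paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE), collapse = ""),
    character(1L))
  total <- sum(vapply(reads, function(r)
    nrow(corrupt_read(r, 0.01, 0)$errors), integer(1L)))
  n <- 2000L * 300L
  expect_lt(abs(total - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
})

test_that("pooled truth mutations under the null carry the 0.26 CDR-replacement fraction", {
  rep <- test_repertoire()
  sim <- simulate_repertoire(simulation_config(n_clones = 700L,
                                               replicate_mean = 1,
                                               seed = 77L), rep)
  muts <- do.call(rbind, lapply(sim$truth$mutations[!duplicated(sim$truth$clone_id) &
                                                      nzchar(sim$truth$mutations)],
                                shmselect:::parse_mutations))
  expect_gt(nrow(muts), 8000L)
  frac <- mean(muts$region %in% c("CDR1", "CDR2") & muts$rs == "R")
  se <- sqrt(0.26 * 0.74 / nrow(muts))
  expect_lt(abs(frac - 0.26), 3 * se)
})

test_that("simulated reads carry the structural features the pipeline expects", {
  nr <- noiseless_run()
  tr <- nr$sim$truth
  # orientations mixed, isotypes from the configured mix
  expect_setequal(unique(tr$orientation), c("FORWARD", "REVERSE"))
  expect_true(all(tr$isotype %in% c("IGE", "IGG", "UNCERTAIN")))
  # forward IgE reads end with the reverse complement of the IgE primer site
  fwd_ige <- tr$orientation == "FORWARD" & tr$isotype == "IGE"
  reads <- nr$sim$reads$sequence[match(tr$read_id[fwd_ige], nr$sim$reads$id)]
  site_rc <- revcomp_str(ig_primers()[["IGE"]])
  expect_true(all(substr(reads, nchar(reads) - nchar(site_rc) + 1L,
                         nchar(reads)) == site_rc))
  # truncation recorded equals missing 5' nucleotides under noise-free settings
  expect_true(all(tr$truncation == 0L))
})
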