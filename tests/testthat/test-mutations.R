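test_that("replacement/silent calls match an independent translation oracle over all codons", {
  expect_equal(classify_rs("GAG", "GAA"), "S")   # Glu -> Glu
  expect_equal(classify_rs("GAG", "AAG"), "R")   # Glu -> Lys
  expect_equal(classify_rs("TGG", "TGA"), "R")   # Trp -> stop counts as R
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  for (cod in codons) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        obs <- cod
        substr(obs, p, p) <- b
        aa_g <- seqinr::translate(strsplit(cod, "")[[1L]])
        aa_o <- seqinr::translate(strsplit(obs, "")[[1L]])
        expect_equal(classify_rs(cod, obs),
                     if (identical(aa_g, aa_o)) "S" else "R",
                     info = paste(cod, "->", obs))
      }
    }
  }
})

test_that("profiles reproduce truth labels on noiseless data", {
  nr <- noiseless_run()
  rep <- test_repertoire()
  prof <- build_profiles(nr$ann, rep)
  for (i in seq_len(nrow(prof))) {
    truth_m <- shmselect:::parse_mutations(nr$truth$mutations[i])
    got <- shmselect:::parse_mutations(prof$mutations[i])
    expect_setequal(sprintf("%d:%s:%s", got$pos, got$region, got$rs),
                    sprintf("%d:%s:%s", truth_m$pos, truth_m$region, truth_m$rs))
    expect_equal(prof$mv[i], nr$truth$n_mutations[i])
    expect_equal(prof$r_cdr[i],
                 sum(truth_m$region %in% c("CDR1", "CDR2") & truth_m$rs == "R"))
  }
  # bookkeeping invariants
  region_cols <- c("fr1_r", "fr1_s", "cdr1_r", "cdr1_s", "fr2_r", "fr2_s",
                   "cdr2_r", "cdr2_s", "fr3_r", "fr3_s")
  expect_equal(prof$mv, rowSums(prof[, region_cols]))
  expect_true(all(prof$r_cdr >= 0 & prof$r_cdr <= prof$mv))
})

test_that("empty mismatch lists and indel input are handled", {
  rep <- test_repertoire()
  ann <- data.frame(id = "x", v_gene = "IGHV1-S1*01", v_start_offset = 0L,
                    mismatches = "", has_indel_in_v = FALSE,
                    has_ambiguity = FALSE, v_aligned_len = 294L,
                    isotype = "IGE", stringsAsFactors = FALSE)
  p <- build_profiles(ann, rep)
  expect_equal(p$mv, 0L)
  expect_equal(p$r_cdr, 0L)
  ann$has_indel_in_v <- TRUE
  expect_error(build_profiles(ann, rep), "indel")
})

test_that("mutations in primer-truncated codons are excluded from Mv", {
  rep <- test_repertoire()
  # offset 10 truncates codons 0..3; a mismatch at position 11 sits in the
  # partially missing codon 3 and must be excluded, one at 12 kept
  ann <- data.frame(id = "x", v_gene = "IGHV1-S1*01", v_start_offset = 11L,
                    mismatches = "11:A>G;14:C>A",
                    has_indel_in_v = FALSE, has_ambiguity = FALSE,
                    v_aligned_len = 283L, isotype = "IGE",
                    stringsAsFactors = FALSE)
  p <- build_profiles(ann, rep)
  expect_equal(p$mv, 1L)
  expect_equal(p$n_excluded, 1L)
})

test_that("r_cdr under the union scheme dominates either single scheme", {
  nr <- noiseless_run()
  rep <- test_repertoire()
  pu <- build_profiles(nr$ann, rep, scheme = "UNION")
  pk <- build_profiles(nr$ann, rep, scheme = "KABAT")
  pi <- build_profiles(nr$ann, rep, scheme = "IMGT")
  expect_true(all(pu$r_cdr >= pk$r_cdr))
  expect_true(all(pu$r_cdr >= pi$r_cdr))
  expect_true(any(pu$r_cdr > pk$r_cdr | pu$r_cdr > pi$r_cdr))
})

test_that("group mutation summaries recover simulated means and test power", {
  set.seed(31)
  mk <- function(n, mean, grp) data.frame(
    id = paste0(grp, seq_len(n)), group = grp,
    mv = pmax(0L, round(rnorm(n, mean, 6))),
    pct_mutated = NA_real_)
  prof <- rbind(mk(500L, 11, "IGE"), mk(500L, 17.7, "IGG"))
  ms <- mutation_summary(prof)
  expect_lt(abs(ms$groups$mean_mv[ms$groups$group == "IGE"] - 11), 0.5)
  expect_lt(abs(ms$groups$mean_mv[ms$groups$group == "IGG"] - 17.7), 0.5)
  expect_lt(ms$tests$p, 0.01)
  # identical groups: p near 1
  a <- mk(200L, 10, "A")
  b <- transform(a, group = "B", id = paste0("B", seq_len(200L)))
  prof2 <- rbind(a, b)
  ms2 <- mutation_summary(prof2)
  expect_equal(ms2$tests$p, 1.0, tolerance = 1e-8)
  # undersized group: summarised but not tested
  prof3 <- rbind(mk(10L, 10, "A"), mk(1L, 10, "B"))
  expect_warning(ms3 <- mutation_summary(prof3), "2 members")
  expect_true(is.na(ms3$tests$p))
  expect_equal(nrow(ms3$groups), 2L)
})
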