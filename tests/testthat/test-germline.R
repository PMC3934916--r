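test_that("repertoire loads with complete region maps and validates input", {
  rep <- test_repertoire()
  expect_s3_class(rep, "germline_repertoire")
  expect_length(rep$seq, 16L)
  expect_equal(sum(rep$segment == "V"), 8L)
  expect_setequal(names(rep$regions), names(rep$seq)[rep$segment == "V"])
  for (g in names(rep$regions)) {
    expect_setequal(names(rep$regions[[g]]), c("KABAT", "IMGT", "UNION"))
  }
  # D and J genes carry no region map
  expect_false(any(names(rep$seq)[rep$segment != "V"] %in% names(rep$regions)))
})

test_that("loading errors on duplicate names, unknown genes, bad characters", {
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fa, tsv)))
  regions <- data.frame(
    gene = rep("IGHV1-X*01", 2), scheme = c("KABAT", "IMGT"),
    fr1_start = 0L, cdr1_start = c(12L, 9L), fr2_start = c(18L, 15L),
    cdr2_start = c(24L, 21L), fr3_start = c(30L, 27L), fr3_end = 36L)
  write.table(regions, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  vseq <- strrep("ACG", 12L)

  writeLines(c(">IGHV1-X*01", vseq, ">IGHV1-X*01", vseq), fa)
  expect_error(load_repertoire(fa, tsv), "duplicate")

  writeLines(c(">IGHV1-Y*01", vseq), fa)
  expect_error(load_repertoire(fa, tsv), "unknown gene")

  writeLines(c(">IGHV1-X*01", sub("A", "N", vseq)), fa)
  expect_error(load_repertoire(fa, tsv), "non-ACGT")

  # empty FASTA: empty collection, no error
  writeLines(character(0), fa)
  empty_tsv <- tempfile(fileext = ".tsv"); on.exit(unlink(empty_tsv), add = TRUE)
  write.table(regions[0, ], empty_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rep0 <- load_repertoire(fa, empty_tsv)
  expect_length(rep0$seq, 0L)
})

test_that("region_of follows the scheme and broadens CDRs under UNION", {
  rep <- test_repertoire()
  g <- rep$regions[[1L]]
  expect_equal(region_of(0L, g, "UNION"), "FR1")
  # position inside IMGT CDR1 but before the Kabat CDR1 start
  p1 <- g$IMGT[["cdr1_start"]]
  expect_true(p1 < g$KABAT[["cdr1_start"]])
  expect_equal(region_of(p1, g, "IMGT"), "CDR1")
  expect_equal(region_of(p1, g, "KABAT"), "FR1")
  expect_equal(region_of(p1, g, "UNION"), "CDR1")
  # position inside the Kabat CDR2 only: IMGT scheme labels it framework
  p2 <- g$IMGT[["fr3_start"]]
  expect_true(p2 >= g$KABAT[["cdr2_start"]] && p2 < g$KABAT[["fr3_start"]])
  expect_equal(region_of(p2, g, "KABAT"), "CDR2")
  expect_equal(region_of(p2, g, "IMGT"), "FR3")
  expect_equal(region_of(p2, g, "UNION"), "CDR2")
  # positions past FR3 are not regioned
  expect_error(region_of(g$UNION[["fr3_end"]], g, "UNION"), "outside")
})

test_that("union CDRs contain both schemes' CDRs and labels partition the V gene", {
  rep <- test_repertoire()
  for (g in names(rep$regions)) {
    r <- rep$regions[[g]]
    for (cdr in 1:2) {
      cs <- paste0("cdr", cdr, "_start")
      ce <- c("fr2_start", "fr3_start")[cdr]
      len <- function(sch) r[[sch]][[ce]] - r[[sch]][[cs]]
      expect_gte(len("UNION"), max(len("KABAT"), len("IMGT")))
      expect_equal(r$UNION[[cs]], min(r$KABAT[[cs]], r$IMGT[[cs]]))
      expect_equal(r$UNION[[ce]], max(r$KABAT[[ce]], r$IMGT[[ce]]))
    }
    pos <- 0:(r$UNION[["fr3_end"]] - 1L)
    for (sch in c("KABAT", "IMGT", "UNION")) {
      labs <- region_of(pos, r, sch)
      expect_false(anyNA(labs))
      # ordered blocks FR1 < CDR1 < FR2 < CDR2 < FR3 cover the gene
      expect_equal(rle(labs)$values, c("FR1", "CDR1", "FR2", "CDR2", "FR3"))
    }
  }
})

test_that("writing and reloading a repertoire reproduces region maps", {
  rep <- test_repertoire()
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fa, tsv)))
  write_repertoire(rep, fa, tsv)
  rep2 <- load_repertoire(fa, tsv)
  expect_identical(rep$seq, rep2$seq)
  expect_identical(rep$segment, rep2$segment)
  expect_identical(rep$regions, rep2$regions)
})
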