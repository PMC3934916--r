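test_that("binomial thresholds match brute-force pmf enumeration for Mv 1..45", {
  for (mv in 1:45) {
    expect_equal(rcdr_threshold(mv), oracle_threshold(mv, 0.26, 0.025),
                 info = paste("mv =", mv))
  }
  # frozen worked examples
  expect_equal(rcdr_threshold(10L), 6L)      # P(X>=6)=0.0239 <= 0.025 < P(X>=5)
  expect_equal(rcdr_threshold(1L), 2L)       # P(X>=1)=0.26: unreachable
  # p -> 0 limit: any CDR replacement is already improbable
  expect_true(all(rcdr_threshold(c(1L, 5L, 45L), p_rcdr = 1e-9) == 1L))
  expect_error(rcdr_threshold(0L), "mv")
})

test_that("threshold boundary is monotone and its ratio approaches p", {
  bd <- rcdr_boundary(45L)
  expect_true(all(diff(bd$k_star) >= 0L))
  # k*/mv stays above p and trends down toward it (sawtooth locally:
  # integer thresholds make the ratio jump up whenever k* increments)
  expect_gt(min(bd$ratio), 0.26)
  expect_lt(bd$ratio[45L], bd$ratio[2L])
  expect_true(all(diff(cummin(bd$ratio)) <= 0))
  expect_lt(bd$ratio[45L], 0.45)
})

test_that("selection classification follows the threshold and mv = 0 is never flagged", {
  prof <- data.frame(id = c("a", "b", "c", "d"),
                     mv = c(0L, 10L, 10L, 45L),
                     r_cdr = c(0L, 6L, 5L, 45L))
  res <- classify_selection(prof)
  expect_equal(res$selected, c(FALSE, TRUE, FALSE, TRUE))
  expect_true(is.na(res$threshold_count[1L]))
  expect_equal(res$threshold_count[2:3], c(6L, 6L))
  # invariant: selected <=> mv > 0 and r_cdr >= threshold
  expect_equal(res$selected,
               res$mv > 0L & !is.na(res$threshold_count) &
                 res$r_cdr >= res$threshold_count)
  # the boundary-inclusive variant also flags points on the plotted line
  res_inc <- classify_selection(prof, on_boundary_selected = TRUE)
  expect_true(res_inc$selected[3L])
})

test_that("null simulations stay below the nominal flagging rate", {
  set.seed(19)
  mv <- sample(1:45, 10000L, replace = TRUE)
  prof <- data.frame(mv = mv, r_cdr = rbinom(10000L, mv, 0.26))
  res <- classify_selection(prof)
  # per-mv flagged fraction bounded by the tail mass alpha (within 3 SE)
  for (m in c(5L, 15L, 30L, 45L)) {
    sel <- res$selected[mv == m]
    expect_lte(mean(sel), 0.025 + 3 * sqrt(0.025 * 0.975 / length(sel)))
  }
  # overall the test is conservative: >= 97.5% unflagged
  expect_gte(mean(!res$selected), 0.975)
})

test_that("inflated CDR-replacement placement raises the flagged fraction", {
  rep <- test_repertoire()
  g <- names(rep$regions)[3L]
  opts <- shmselect:::mutation_options(rep$seq[[g]], rep$regions[[g]])
  set.seed(8)
  arm <- function(p, mv, n = 2000L) {
    r <- replicate(n, {
      m <- place_mutations(rep$seq[[g]], rep$regions[[g]], mv, p, opts = opts)
      sum(m$region %in% c("CDR1", "CDR2") & m$rs == "R")
    })
    mean(classify_selection(data.frame(mv = mv, r_cdr = r))$selected)
  }
  for (mv in c(10L, 20L)) {
    expect_gt(arm(0.45, mv), arm(0.26, mv))
  }
})

test_that("the fitted selection model exposes the usual S3 surface", {
  prof <- data.frame(id = sprintf("s%d", 1:6),
                     mv = c(0L, 10L, 10L, 20L, 30L, 12L),
                     r_cdr = c(0L, 6L, 2L, 10L, 5L, 7L),
                     group = c("IGE", "IGE", "IGE", "IGG", "IGG", "IGG"))
  fit <- antigen_selection(prof)
  expect_s3_class(fit, "antigen_selection")
  expect_equal(unname(coef(fit)), c(0.26, 0.025))
  expect_output(print(fit), "evidence of selection")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.antigen_selection")
  expect_equal(sort(sm$groups$group), c("IGE", "IGG"))
  pred <- predict(fit, data.frame(mv = 10L, r_cdr = 6L))
  expect_true(pred)
  simd <- simulate(fit, seed = 4L)
  expect_equal(nrow(simd), 6L)
  expect_true(all(simd$r_cdr <= simd$mv))
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  co <- plot(fit, jitter = FALSE)
  expect_equal(co$x, fit$results$mv[fit$results$mv >= 1L])
})

test_that("group selection summaries and chi-square comparisons behave", {
  mk <- function(grp, n, k) data.frame(
    id = paste0(grp, seq_len(n)), selected = rep(c(TRUE, FALSE), c(k, n - k)),
    stringsAsFactors = FALSE)
  # identical proportions: no difference
  res <- rbind(mk("A", 100L, 10L), mk("B", 100L, 10L))
  gs <- group_selection_summary(res, sub("[0-9]+", "", res$id))
  expect_equal(gs$groups$pct_selected, c(10.0, 10.0))
  expect_equal(gs$tests$p, 1.0, tolerance = 1e-8)
  # degenerate table (no selected anywhere): skipped with warning
  res0 <- rbind(mk("A", 50L, 0L), mk("B", 40L, 0L))
  expect_warning(
    gs0 <- group_selection_summary(res0, sub("[0-9]+", "", res0$id)),
    "degenerate")
  expect_true(is.na(gs0$tests$p))
})
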