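#' Minimal CDR-replacement count flagged as antigen-selected
#'
#' Under the random-mutation model, the number of CDR replacement
#' mutations among Mv total V-gene mutations is Binomial(Mv, p). The
#' threshold k* is the smallest count whose upper tail mass
#' P(X >= k) does not exceed `alpha` — i.e. the first count strictly above
#' the 97.5% confidence limit when `alpha = 0.025`. Computed by exact tail
#' summation of the probability mass function (no normal approximation;
#' with at most 45 mutations per sequence this is cheap and unambiguous).
#' When even P(X >= mv) exceeds `alpha`, k* = mv + 1: the sequence can
#' never be flagged (so single-mutation sequences, where
#' P(X >= 1) = p > alpha, are never flagged).
#'
#' @param mv Integer vector of total mutation counts (all >= 1).
#' @param p_rcdr Probability a random mutation is a CDR replacement.
#' @param alpha_upper One-sided tail mass defining the upper limit.
#' @return Integer vector of thresholds k*, same length as `mv`.
#' @export
rcdr_threshold <- function(mv, p_rcdr = 0.26, alpha_upper = 0.025) {
  stopifnot(p_rcdr > 0, p_rcdr < 1, alpha_upper > 0, alpha_upper < 0.5)
  if (any(mv < 1L)) stop("mv must be >= 1; unmutated sequences carry no evidence")
  vapply(as.integer(mv), function(m) {
    pmf <- stats::dbinom(0:m, m, p_rcdr)
    tail <- rev(cumsum(rev(pmf)))   # tail[k+1] = P(X >= k)
    k <- which(tail <= alpha_upper)
    if (length(k)) k[1L] - 1L else m + 1L
  }, integer(1L))
}

#' Boundary table of the random-mutation model
#'
#' The "line" separating selected from unselected sequences: for each Mv,
#' the threshold count k* (non-decreasing in Mv) and the ratio k*/Mv,
#' which trends down toward `p_rcdr` as Mv grows (with a local sawtooth:
#' the ratio jumps up at each Mv where the integer threshold increments).
#'
#' @param max_mv Largest Mv tabulated (45, the mutation-count filter cap).
#' @inheritParams rcdr_threshold
#' @return data.frame with columns `mv`, `k_star`, `ratio`.
#' @export
rcdr_boundary <- function(max_mv = 45L, p_rcdr = 0.26, alpha_upper = 0.025) {
  mv <- seq_len(max_mv)
  k <- rcdr_threshold(mv, p_rcdr, alpha_upper)
  data.frame(mv = mv, k_star = k, ratio = k / mv)
}

#' Classify sequences as showing or lacking evidence of antigen selection
#'
#' Applies the binomial threshold to each mutation profile: a sequence is
#' flagged as selected when it has at least one mutation and its CDR
#' replacement count reaches the threshold for its Mv (equivalently, its
#' point lies strictly above the plotted 97.5% boundary). Unmutated
#' sequences are never flagged. With `on_boundary_selected = TRUE`, points
#' exactly on the plotted boundary (the largest count still inside the
#' confidence band) are also flagged.
#'
#' @param profiles data.frame with columns `mv` and `r_cdr` (and
#'   optionally `id`).
#' @inheritParams rcdr_threshold
#' @param on_boundary_selected Also flag boundary-equal points.
#' @return data.frame: `id`, `mv`, `r_cdr`, `threshold_count`, `selected`.
#' @export
classify_selection <- function(profiles, p_rcdr = 0.26, alpha_upper = 0.025,
                               on_boundary_selected = FALSE) {
  mv <- profiles$mv
  thr <- rep(NA_integer_, length(mv))
  pos <- mv >= 1L
  if (any(pos)) thr[pos] <- rcdr_threshold(mv[pos], p_rcdr, alpha_upper)
  eff <- if (on_boundary_selected) thr - 1L else thr
  sel <- pos & !is.na(thr) & profiles$r_cdr >= pmax(eff, 1L)
  data.frame(id = if ("id" %in% names(profiles)) profiles$id else
               seq_along(mv),
             mv = mv, r_cdr = profiles$r_cdr, threshold_count = thr,
             selected = sel, stringsAsFactors = FALSE)
}

#' Fit the random-mutation selection model to a set of mutation profiles
#'
#' The central analysis: each sequence's CDR replacement count `r_cdr` is
#' compared with its exact Binomial(`mv`, `p_rcdr`) upper confidence limit;
#' sequences strictly above the limit show mutational evidence of antigen
#' selection. The returned object carries per-sequence results, the model
#' boundary, and group assignments for selection-percentage comparisons.
#'
#' @param profiles data.frame from [build_profiles()] (needs `mv`,
#'   `r_cdr`; `id` and `group` used when present).
#' @inheritParams rcdr_threshold
#' @param on_boundary_selected Also flag boundary-equal points.
#' @param group Optional grouping vector overriding `profiles$group`.
#' @return An object of class `antigen_selection` with components
#'   `results`, `boundary`, `p_rcdr`, `alpha_upper`, `group`, `call`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `simulate`.
#' @examples
#' prof <- data.frame(id = c("a", "b"), mv = c(10, 10), r_cdr = c(6, 5))
#' fit <- antigen_selection(prof)
#' fit$results$selected  # TRUE, FALSE: k*(10) = 6
#' @export
antigen_selection <- function(profiles, p_rcdr = 0.26, alpha_upper = 0.025,
                              on_boundary_selected = FALSE, group = NULL) {
  res <- classify_selection(profiles, p_rcdr, alpha_upper,
                            on_boundary_selected)
  if (is.null(group)) {
    group <- if ("group" %in% names(profiles)) profiles$group else
      rep("all", nrow(profiles))
  }
  res$group <- rep_len(group, nrow(res))
  max_mv <- max(45L, res$mv, na.rm = TRUE)
  structure(list(results = res,
                 boundary = rcdr_boundary(max_mv, p_rcdr, alpha_upper),
                 p_rcdr = p_rcdr, alpha_upper = alpha_upper,
                 on_boundary_selected = on_boundary_selected,
                 call = match.call()),
            class = "antigen_selection")
}

#' @export
print.antigen_selection <- function(x, ...) {
  n <- nrow(x$results)
  ns <- sum(x$results$selected)
  cat("Antigen-selection analysis (binomial random-mutation model)\n")
  cat(sprintf("  p(R_CDR) = %.2f, upper tail alpha = %.3f\n",
              x$p_rcdr, x$alpha_upper))
  cat(sprintf("  %d sequences; %d (%.1f%%) show evidence of selection\n",
              n, ns, if (n > 0) 100 * ns / n else 0))
  invisible(x)
}

#' @export
coef.antigen_selection <- function(object, ...) {
  c(p_rcdr = object$p_rcdr, alpha_upper = object$alpha_upper)
}

#' @export
summary.antigen_selection <- function(object, yates = FALSE, ...) {
  gs <- group_selection_summary(object$results, object$results$group,
                                yates = yates)
  structure(list(fit = object, groups = gs$groups, tests = gs$tests),
            class = "summary.antigen_selection")
}

#' @export
print.summary.antigen_selection <- function(x, ...) {
  print(x$fit)
  cat("\nPer-group selection:\n")
  print(x$groups, row.names = FALSE)
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("\nPairwise chi-square tests (selected vs not):\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' @export
predict.antigen_selection <- function(object, newdata,
                                      type = c("selected", "threshold"), ...) {
  type <- match.arg(type)
  res <- classify_selection(newdata, object$p_rcdr, object$alpha_upper,
                            object$on_boundary_selected)
  if (type == "selected") res$selected else res$threshold_count
}

#' @export
simulate.antigen_selection <- function(object, nsim = 1, seed = NULL,
                                       mv = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mv)) mv <- object$results$mv
  out <- lapply(seq_len(nsim), function(s) {
    r <- integer(length(mv))
    pos <- mv >= 1L
    r[pos] <- stats::rbinom(sum(pos), mv[pos], object$p_rcdr)
    data.frame(mv = mv, r_cdr = r)
  })
  if (nsim == 1L) out[[1L]] else out
}

#' @export
plot.antigen_selection <- function(x, jitter = TRUE, jitter_seed = 1L,
                                   main = "CDR replacement load vs mutation count",
                                   ...) {
  plot_selection_scatter(x, jitter = jitter, jitter_seed = jitter_seed,
                         main = main, ...)
}

#' Per-group selection percentages with pairwise chi-square tests
#'
#' For each group, the percentage of sequences flagged as selected
#' (1 decimal); for each pair of groups a 2x2 chi-square test on
#' selected/not-selected counts, without continuity correction by default.
#' Empty groups are excluded with a warning; tables with a zero margin are
#' reported with `p = NA` and a warning (the statistic is undefined).
#'
#' @param results data.frame with a logical `selected` column (e.g.
#'   `fit$results`).
#' @param group Grouping vector aligned with `results`.
#' @param yates Apply Yates continuity correction.
#' @return list with `groups` (group, n, n_selected, pct_selected) and
#'   `tests` (group1, group2, statistic, p).
#' @export
group_selection_summary <- function(results, group, yates = FALSE) {
  keep <- !is.na(group)
  results <- results[keep, , drop = FALSE]
  group <- group[keep]
  lv <- sort(unique(group))
  if (length(lv) == 0L) {
    return(list(groups = data.frame(group = character(), n = integer(),
                                    n_selected = integer(),
                                    pct_selected = numeric(),
                                    stringsAsFactors = FALSE),
                tests = NULL))
  }
  groups <- do.call(rbind, lapply(lv, function(l) {
    sel <- results$selected[group == l]
    data.frame(group = l, n = length(sel), n_selected = sum(sel),
               pct_selected = if (length(sel)) round(100 * mean(sel), 1L)
                              else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(lv) >= 2L) {
    pairs <- utils::combn(lv, 2L, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      s1 <- results$selected[group == pr[1L]]
      s2 <- results$selected[group == pr[2L]]
      tab <- rbind(c(sum(s1), length(s1) - sum(s1)),
                   c(sum(s2), length(s2) - sum(s2)))
      if (any(colSums(tab) == 0L) || any(rowSums(tab) == 0L)) {
        warning("degenerate 2x2 table for ", pr[1L], " vs ", pr[2L],
                ": chi-square skipped")
        return(data.frame(group1 = pr[1L], group2 = pr[2L],
                          statistic = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
      data.frame(group1 = pr[1L], group2 = pr[2L],
                 statistic = unname(ct$statistic), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(groups = groups, tests = tests)
}
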