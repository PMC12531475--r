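#' The CTG worked example: published summary statistics
#'
#' Five obstetricians (A to E) each classified twenty cardiotocographs (CTGs)
#' as normal or abnormal. The raw 20 x 5 matrix was not published; what is
#' available are the per-observer numbers of "abnormal" ratings
#' (6, 6, 9, 7, 12) and the proportion of agreement for each of the ten
#' observer pairs. `ctg_marginals()` and `ctg_pairwise_po()` return those
#' summaries.
#'
#' @return `ctg_marginals()`: a named integer vector. `ctg_pairwise_po()`: a
#'   tibble with columns `rater_a`, `rater_b`, `po`.
#' @seealso [ctg_fixture()], [build_ctg_fixture()]
#' @export
ctg_marginals <- function() {
  c(A = 6L, B = 6L, C = 9L, D = 7L, E = 12L)
}

#' @rdname ctg_marginals
#' @export
ctg_pairwise_po <- function() {
  tibble::tibble(
    rater_a = c("A", "A", "A", "A", "B", "B", "B", "C", "C", "D"),
    rater_b = c("B", "C", "D", "E", "C", "D", "E", "D", "E", "E"),
    po = c(0.90, 0.85, 0.85, 0.60, 0.85, 0.95, 0.50, 0.90, 0.45, 0.45)
  )
}

#' Reconstruct a rating matrix consistent with the CTG summaries
#'
#' Finds, by deterministic backtracking search over per-patient rating
#' patterns, a 20 x 5 binary matrix whose per-observer positive counts equal
#' the published marginals and whose ten pairwise 2x2 tables equal the tables
#' recovered by [reconstruct_pair_tables()]. Every agreement point estimate
#' implemented in this package depends on the data only through these
#' sufficient statistics, so any such matrix reproduces the published
#' estimates exactly; multi-observer standard errors additionally depend on
#' the per-patient counts and are therefore fixture-dependent (see the
#' package vignette).
#'
#' The search is deterministic, so repeated calls return the same matrix; a
#' copy is shipped as `inst/extdata/ctg_synthetic.csv` and returned by
#' [ctg_fixture()] without searching.
#'
#' @return A [ratings] object (20 patients, observers A to E).
#' @export
build_ctg_fixture <- function() {
  marg <- ctg_marginals()
  n <- 20L
  rec <- reconstruct_pair_tables(marg, ctg_pairwise_po(), n)
  raters <- names(marg)
  k <- length(raters)
  target <- matrix(0L, k, k, dimnames = list(raters, raters))
  for (i in seq_len(nrow(rec))) {
    target[rec$rater_a[i], rec$rater_b[i]] <- rec$n11[i]
  }
  # candidate patterns, heavy (many positives) first so pair targets bind early
  pats <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  pats <- pats[order(-rowSums(pats)), , drop = FALSE]
  found <- NULL
  dfs <- function(i, colrem, pairrem, rows) {
    if (!is.null(found)) return()
    left <- n - i + 1L
    if (any(colrem > left) || any(colrem < 0)) return()
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      pr <- pairrem[a, b]
      if (pr < 0 || pr > min(colrem[a], colrem[b]) || pr > left ||
          pr < colrem[a] + colrem[b] - left) return()
    }
    if (i > n) { found <<- rows; return() }
    for (p in seq_len(nrow(pats))) {
      v <- pats[p, ]
      nc <- colrem - v
      if (any(nc < 0)) next
      np <- pairrem - outer(v, v) * upper.tri(pairrem)
      if (any(np[upper.tri(np)] < 0)) next
      dfs(i + 1L, nc, np, rbind(rows, v))
      if (!is.null(found)) return()
    }
  }
  dfs(1L, marg, target, NULL)
  if (is.null(found)) {
    abort("no rating matrix satisfies the CTG summary constraints.")
  }
  m <- unname(found)
  dimnames(m) <- list(sprintf("P%02d", seq_len(n)), raters)
  as_ratings(tibble::as_tibble(m, rownames = "patient"), format = "wide")
}

#' The CTG worked-example rating matrix
#'
#' Returns the reconstructed (synthetic) 20 x 5 rating matrix shipped with
#' the package; see [build_ctg_fixture()] for how it was obtained and in
#' which sense it is equivalent to the unpublished original.
#'
#' @return A [ratings] object.
#' @examples
#' po_multi(ctg_fixture())   # 0.73
#' @export
ctg_fixture <- function() {
  path <- system.file("extdata", "ctg_synthetic.csv", package = "agreebin")
  if (!nzchar(path)) abort("fixture file not found; reinstall the package.")
  read_ratings_wide(path)
}
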