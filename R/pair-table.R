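#' Two-by-two classification table for a pair of observers
#'
#' The atom of all pairwise agreement statistics: the cross-classification of
#' `N` patients (or objects) by two observers on a binary scale. Cell `n11`
#' counts patients rated positive (e.g., "abnormal") by both observers, `n12`
#' positive by the first only, `n21` positive by the second only, and `n22`
#' negative by both.
#'
#' @param n11,n12,n21,n22 Non-negative integer counts. Alternatively, pass a
#'   single numeric vector of length four as `n11`.
#' @param raters Optional character vector of length two naming the observers.
#' @return An object of class `pair_table`: a list with the four counts, the
#'   total `n`, and the rater labels.
#' @examples
#' pair_table(6, 0, 3, 11)          # obstetricians A and C, CTG example
#' pair_proportions(pair_table(6, 0, 3, 11))
#' @export
pair_table <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL, raters = NULL) {
  if (is.null(n12) && length(n11) == 4L) {
    n22 <- n11[[4]]; n21 <- n11[[3]]; n12 <- n11[[2]]; n11 <- n11[[1]]
  }
  counts <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("pair_table counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n == 0) abort("pair_table must contain at least one rated patient.")
  if (!is.null(raters) && length(raters) != 2L) {
    abort("`raters` must have length 2.")
  }
  structure(
    list(n11 = as.integer(n11), n12 = as.integer(n12),
         n21 = as.integer(n21), n22 = as.integer(n22),
         n = as.integer(n), raters = raters),
    class = "pair_table"
  )
}

#' @export
print.pair_table <- function(x, ...) {
  lab <- x$raters %||% c("Observer 1", "Observer 2")
  cat("2x2 classification table (", lab[1], " x ", lab[2], "), N = ", x$n,
      "\n", sep = "")
  m <- matrix(c(x$n11, x$n21, x$n12, x$n22), 2, 2,
              dimnames = list(c("positive", "negative"),
                              c("positive", "negative")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.pair_table <- function(x, ...) {
  matrix(c(x$n11, x$n21, x$n12, x$n22), 2, 2,
         dimnames = list(c("positive", "negative"),
                         c("positive", "negative")))
}

#' Cell and marginal proportions of a pair table
#'
#' @param x A [pair_table()].
#' @return A named list with the cell proportions `p11`, `p12`, `p21`, `p22`
#'   and marginals `p1.`, `p2.` (observer 1) and `p.1`, `p.2` (observer 2).
#' @export
pair_proportions <- function(x) {
  stopifnot(inherits(x, "pair_table"))
  n <- x$n
  list(p11 = x$n11 / n, p12 = x$n12 / n, p21 = x$n21 / n, p22 = x$n22 / n,
       p1. = (x$n11 + x$n12) / n, p2. = (x$n21 + x$n22) / n,
       p.1 = (x$n11 + x$n21) / n, p.2 = (x$n12 + x$n22) / n)
}

#' Cross-classify two observers from a ratings object
#'
#' Builds the 2x2 [pair_table()] for two observers, restricted to patients
#' rated by both (available-case analysis). Ratings must contain a single
#' assessment per patient and observer; use [select_occasion()] first when
#' replicate assessments are present.
#'
#' @param x A [ratings] object or a data frame accepted by [as_ratings()].
#' @param rater_a,rater_b Observer identifiers (character).
#' @return A [pair_table()].
#' @examples
#' crosstab(ctg_fixture(), "A", "C")
#' @export
crosstab <- function(x, rater_a, rater_b) {
  x <- as_ratings(x)
  if (max(table(paste(x$patient, x$rater))) > 1L) {
    abort("ratings contain replicate assessments; apply select_occasion() first.")
  }
  for (r in c(rater_a, rater_b)) {
    if (!r %in% x$rater) abort(paste0("unknown rater: '", r, "'"))
  }
  a <- x[x$rater == rater_a, c("patient", "rating")]
  b <- x[x$rater == rater_b, c("patient", "rating")]
  names(a)[2] <- "ra"; names(b)[2] <- "rb"
  ab <- dplyr::inner_join(a, b, by = "patient")
  ab <- ab[!is.na(ab$ra) & !is.na(ab$rb), ]
  if (nrow(ab) == 0) {
    abort(paste0("no patient was rated by both '", rater_a, "' and '",
                 rater_b, "'."))
  }
  pair_table(sum(ab$ra == 1 & ab$rb == 1), sum(ab$ra == 1 & ab$rb == 0),
             sum(ab$ra == 0 & ab$rb == 1), sum(ab$ra == 0 & ab$rb == 0),
             raters = c(rater_a, rater_b))
}

#' Reconstruct pairwise tables from per-rater totals and pairwise agreement
#'
#' Published agreement studies often report, instead of raw data, the number
#' of positive ratings per observer together with the proportion of agreement
#' for every observer pair. For binary ratings those summaries determine each
#' pairwise 2x2 table uniquely: with `na`, `nb` positive counts and agreement
#' `po` on `n` patients, the joint positive cell is
#' `n11 = (n * po - n + na + nb) / 2` and the remaining cells follow from the
#' marginals. The function solves every pair and validates integrality
#' (parity) and range, so inconsistent summaries are detected rather than
#' silently rounded.
#'
#' @param marginal_positive Named integer vector: positive ratings per
#'   observer.
#' @param pairwise_po Data frame with columns `rater_a`, `rater_b`, `po`, one
#'   row per observer pair.
#' @param n Number of patients rated by every observer.
#' @return A tibble with one row per pair: rater labels, the four cell
#'   counts, and the (exactly recovered) proportion of agreement.
#' @examples
#' reconstruct_pair_tables(
#'   c(A = 6, C = 9),
#'   data.frame(rater_a = "A", rater_b = "C", po = 0.85),
#'   n = 20
#' )
#' @export
reconstruct_pair_tables <- function(marginal_positive, pairwise_po, n) {
  stopifnot(is.numeric(marginal_positive), !is.null(names(marginal_positive)))
  pairwise_po <- as.data.frame(pairwise_po)
  need <- c("rater_a", "rater_b", "po")
  if (!all(need %in% names(pairwise_po))) {
    abort("`pairwise_po` needs columns rater_a, rater_b, po.")
  }
  rows <- purrr::pmap(pairwise_po[need], function(rater_a, rater_b, po) {
    na <- marginal_positive[[rater_a]]
    nb <- marginal_positive[[rater_b]]
    if (is.null(na) || is.null(nb)) {
      abort(paste0("pair (", rater_a, ",", rater_b,
                   "): marginal positive count missing."))
    }
    agree <- n * po
    if (abs(agree - round(agree)) > 1e-8) {
      abort(paste0("pair (", rater_a, ",", rater_b, "): n * po = ", agree,
                   " is not an integer count."))
    }
    agree <- round(agree)
    num <- agree - n + na + nb
    if (num %% 2L != 0L) {
      abort(paste0("pair (", rater_a, ",", rater_b,
                   "): inconsistent summaries (parity violation)."))
    }
    n11 <- num %/% 2L
    if (n11 < max(0, na + nb - n) || n11 > min(na, nb)) {
      abort(paste0("pair (", rater_a, ",", rater_b,
                   "): implied n11 = ", n11, " outside the feasible range."))
    }
    tibble::tibble(rater_a = rater_a, rater_b = rater_b,
                   n11 = n11, n12 = na - n11, n21 = nb - n11,
                   n22 = n - na - nb + n11, po = (n11 + n - na - nb + n11) / n)
  })
  dplyr::bind_rows(rows)
}
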