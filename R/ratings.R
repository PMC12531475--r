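#' Binary ratings of patients by observers
#'
#' The central data container: a tidy (long) tibble with one row per
#' assessment, columns `patient`, `rater`, `occasion` and `rating`
#' (`0` = negative/normal, `1` = positive/abnormal, `NA` = missing), carrying
#' class `ratings`. Wide tables (patients in rows, observers in columns) are
#' accepted and pivoted automatically.
#'
#' Patients with fewer than two non-missing ratings cannot contribute to any
#' agreement statistic; they are flagged with a warning at construction but
#' kept, so the analyst decides whether to drop them.
#'
#' @param data A data frame. Either long, with columns `patient` (or
#'   `patient_id`), `rater` (or `rater_id`), `rating` and optionally
#'   `occasion`; or wide, with patient identifiers in the first column and
#'   one column of 0/1/NA ratings per observer.
#' @param format `"auto"` (default) detects long input by its column names;
#'   `"wide"`/`"long"` force the interpretation.
#' @return A `ratings` tibble.
#' @examples
#' wide <- data.frame(patient = c("p1", "p2"), A = c(1, 0), B = c(1, 1))
#' as_ratings(wide)
#' @export
as_ratings <- function(data, format = c("auto", "wide", "long")) {
  if (inherits(data, "ratings")) return(data)
  if (inherits(data, "pair_table")) {
    lab <- data$raters %||% c("R1", "R2")
    a <- rep(c(1L, 1L, 0L, 0L), c(data$n11, data$n12, data$n21, data$n22))
    b <- rep(c(1L, 0L, 1L, 0L), c(data$n11, data$n12, data$n21, data$n22))
    wide <- tibble::tibble(patient = sprintf("p%03d", seq_along(a)))
    wide[[lab[1]]] <- a
    wide[[lab[2]]] <- b
    return(as_ratings(wide, format = "wide"))
  }
  format <- match.arg(format)
  stopifnot(is.data.frame(data))
  nm <- names(data)
  long_like <- any(c("patient", "patient_id") %in% nm) &&
    any(c("rater", "rater_id") %in% nm) && "rating" %in% nm
  if (format == "auto") format <- if (long_like) "long" else "wide"
  if (format == "long") {
    if (!long_like) abort("long ratings need patient, rater and rating columns.")
    x <- tibble::as_tibble(data)
    if ("patient_id" %in% nm) x <- dplyr::rename(x, patient = "patient_id")
    if ("rater_id" %in% nm) x <- dplyr::rename(x, rater = "rater_id")
    if (!"occasion" %in% names(x)) x$occasion <- 1L
    x <- x[, c("patient", "rater", "occasion", "rating")]
  } else {
    if (ncol(data) < 2L) abort("wide ratings need a patient column and at least one rater column.")
    if (anyDuplicated(data[[1]])) {
      abort(paste0("duplicate patient id(s): ",
                   paste(unique(data[[1]][duplicated(data[[1]])]), collapse = ", ")))
    }
    x <- tibble::as_tibble(data)
    names(x)[1] <- "patient"
    x <- tidyr::pivot_longer(x, -"patient", names_to = "rater",
                             values_to = "rating")
    x$occasion <- 1L
    x <- x[, c("patient", "rater", "occasion", "rating")]
  }
  x$patient <- as.character(x$patient)
  x$rater <- as.character(x$rater)
  x$occasion <- as.integer(x$occasion)
  bad <- !is.na(x$rating) & !x$rating %in% c(0, 1)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("non-binary rating '", x$rating[i], "' for patient '",
                 x$patient[i], "', rater '", x$rater[i], "'."))
  }
  x$rating <- as.integer(x$rating)
  key <- paste(x$patient, x$rater, x$occasion)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (patient, rater, occasion) entries: ",
                 paste(head(unique(key[duplicated(key)]), 3), collapse = "; ")))
  }
  x <- new_ratings(x)
  flag_underrated(x)
}

new_ratings <- function(x) {
  class(x) <- c("ratings", class(tibble::tibble()))
  x
}

flag_underrated <- function(x) {
  cc <- category_counts(x, warn = FALSE)
  under <- cc$patient[cc$n_rated < 2]
  if (length(under)) {
    warn(paste0("patient(s) with fewer than two non-missing ratings: ",
                paste(under, collapse = ", ")))
  }
  x
}

#' @export
print.ratings <- function(x, ...) {
  cat("<ratings> ", dplyr::n_distinct(x$patient), " patients x ",
      dplyr::n_distinct(x$rater), " raters",
      if (max(x$occasion) > 1L) paste0(" x ", max(x$occasion), " occasions"),
      "\n", sep = "")
  NextMethod()
}

#' Read binary ratings from CSV files
#'
#' `read_ratings_wide()` expects a header row naming the observers, patient
#' identifiers in the first column, and one 0/1/missing cell per assessment.
#' `read_ratings_long()` expects columns `patient_id`, `rater_id`, `rating`
#' and optionally `occasion`. Cells are compared as text against the
#' `positive`, `negative` and `missing` tokens, so files coded e.g.
#' "abnormal"/"normal" can be read by remapping.
#'
#' @param path Path to a CSV file.
#' @param positive,negative,missing Tokens for the three cell states
#'   (defaults `"1"`, `"0"`, `"NA"`; an empty cell always counts as missing).
#' @param delim Field separator.
#' @return A [ratings] object.
#' @export
read_ratings_wide <- function(path, positive = "1", negative = "0",
                              missing = "NA", delim = ",") {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(), progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("empty ratings file: ", path))
  for (j in seq(2, ncol(raw))) {
    v <- trimws(raw[[j]])
    out <- rep(NA_integer_, length(v))
    out[v == positive] <- 1L
    out[v == negative] <- 0L
    unknown <- !(v %in% c(positive, negative, missing, "", NA))
    if (any(unknown)) {
      i <- which(unknown)[1]
      abort(paste0("cannot parse cell '", v[i], "' (row ", i, ", column '",
                   names(raw)[j], "') as a binary rating."))
    }
    raw[[j]] <- out
  }
  as_ratings(raw, format = "wide")
}

#' @rdname read_ratings_wide
#' @export
read_ratings_long <- function(path, positive = "1", negative = "0",
                              missing = "NA", delim = ",") {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(), progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("empty ratings file: ", path))
  need <- c("patient_id", "rater_id", "rating")
  if (!all(need %in% names(raw))) {
    abort("long ratings file needs columns patient_id, rater_id, rating.")
  }
  v <- trimws(raw$rating)
  out <- rep(NA_integer_, length(v))
  out[v == positive] <- 1L
  out[v == negative] <- 0L
  unknown <- !(v %in% c(positive, negative, missing, "", NA))
  if (any(unknown)) {
    i <- which(unknown)[1]
    abort(paste0("cannot parse rating '", v[i], "' (row ", i,
                 ") as a binary rating."))
  }
  raw$rating <- out
  if ("occasion" %in% names(raw)) raw$occasion <- as.integer(raw$occasion)
  as_ratings(raw, format = "long")
}

#' Write ratings as a wide CSV
#'
#' Inverse of [read_ratings_wide()]: one row per patient, one column per
#' observer. Requires a single assessment per patient and observer.
#'
#' @param x A [ratings] object.
#' @param path Output file.
#' @param missing Token written for missing cells.
#' @return `path`, invisibly.
#' @export
write_ratings_wide <- function(x, path, missing = "NA") {
  x <- as_ratings(x)
  w <- ratings_wide(x)
  df <- tibble::as_tibble(w, rownames = "patient")
  out <- df
  for (j in seq(2, ncol(out))) {
    out[[j]] <- as.character(out[[j]])
    out[[j]][is.na(out[[j]])] <- missing
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# wide numeric matrix, patients x raters; requires one occasion per cell
ratings_wide <- function(x) {
  x <- as_ratings(x)
  if (max(table(paste(x$patient, x$rater))) > 1L) {
    abort("ratings contain replicate assessments; apply select_occasion() first.")
  }
  pats <- unique(x$patient)
  rts <- unique(x$rater)
  m <- matrix(NA_integer_, length(pats), length(rts),
              dimnames = list(pats, rts))
  m[cbind(match(x$patient, pats), match(x$rater, rts))] <- x$rating
  m
}

#' Reduce replicate assessments to one rating per observer
#'
#' Designs in which each observer assesses every patient on several occasions
#' support both intra- and inter-observer analyses. For an inter-observer
#' analysis one assessment per observer must be selected; under the
#' interchangeable-ratings assumption (replicates exchangeable within
#' observer) the choice of rule does not affect the analysis in expectation.
#'
#' @param x A [ratings] object with occasion indices.
#' @param rule `"first"` keeps the lowest occasion with a non-missing rating;
#'   `"random"` draws one non-missing assessment per (patient, rater).
#' @param seed Integer seed, required for `rule = "random"` so the selection
#'   is reproducible.
#' @return A [ratings] object with a single occasion per (patient, rater).
#' @export
select_occasion <- function(x, rule = c("first", "random"), seed = NULL) {
  x <- as_ratings(x)
  rule <- match.arg(rule)
  if (rule == "random" && is.null(seed)) {
    abort("rule = \"random\" requires a `seed` for reproducibility.")
  }
  pick <- function(d) {
    avail <- d[!is.na(d$rating), , drop = FALSE]
    if (nrow(avail) == 0) return(d[order(d$occasion)[1], , drop = FALSE])
    avail <- avail[order(avail$occasion), , drop = FALSE]
    if (rule == "first") avail[1, , drop = FALSE]
    else avail[sample.int(nrow(avail), 1L), , drop = FALSE]
  }
  run <- function() {
    out <- dplyr::group_modify(dplyr::group_by(x, .data$patient, .data$rater),
                               function(d, key) pick(d))
    out <- dplyr::ungroup(out)
    out$occasion <- 1L
    new_ratings(out[, c("patient", "rater", "occasion", "rating")])
  }
  if (rule == "random") with_seed(seed, run()) else run()
}

#' Per-patient category counts
#'
#' The sufficient statistics of all multi-observer agreement formulas: for
#' each patient, the number of positive ratings `m_pos`, the number of
#' non-missing ratings `n_rated`, and the implied `m_neg = n_rated - m_pos`.
#'
#' @param x A [ratings] object or data frame accepted by [as_ratings()].
#' @param warn Warn about patients with fewer than two non-missing ratings?
#' @return A tibble with columns `patient`, `m_pos`, `m_neg`, `n_rated`.
#' @examples
#' category_counts(ctg_fixture())
#' @export
category_counts <- function(x, warn = TRUE) {
  x <- if (warn) as_ratings(x) else x
  cc <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$patient),
                         m_pos = sum(.data$rating == 1, na.rm = TRUE),
                         n_rated = sum(!is.na(.data$rating)),
                         .groups = "drop")
  cc$m_neg <- cc$n_rated - cc$m_pos
  cc[, c("patient", "m_pos", "m_neg", "n_rated")]
}

#' Recode replicate occasions as pseudo-raters
#'
#' For intra-observer analyses the replicate assessments play the role of
#' observers: this helper relabels each (rater, occasion) combination as a
#' distinct rater with a single occasion, after which all multi-observer
#' coefficients apply directly.
#'
#' @param x A [ratings] object with occasion indices.
#' @return A [ratings] object with one occasion per rater.
#' @export
occasions_as_raters <- function(x) {
  x <- as_ratings(x)
  x$rater <- paste0(x$rater, ".", x$occasion)
  x$occasion <- 1L
  new_ratings(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
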