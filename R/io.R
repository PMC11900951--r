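# Long-format response I/O, bulk scoring, matched-pair construction.

#' Read long-format item responses
#'
#' Reads the pipeline's input format: one row per patient x visit x
#' instrument x item, header `patient_id,timepoint,instrument,item_id,code`,
#' empty `code` = missing.  Timepoint labels must be one of `preop`, `3m`,
#' `6m`, `12m`; unknown labels are rejected, not coerced.
#'
#' @param path CSV file path.
#' @return Data frame with the five columns, `code` integer (`NA` = missing).
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "timepoint", "instrument", "item_id", "code")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df <- df[, need]
  code_chr <- trimws(df$code)
  code <- suppressWarnings(as.integer(code_chr))
  bad <- which(nzchar(code_chr) & is.na(code))
  if (length(bad))
    stop_("%s: non-integer response code on line(s) %s", path,
          paste(bad + 1L, collapse = ", "))   # +1 for the header line
  df$code <- code
  check_timepoints(df$timepoint)
  bad_instr <- setdiff(unique(df$instrument), c("mHHS", "HOOS"))
  if (length(bad_instr))
    stop_("%s: unknown instrument(s): %s", path,
          paste(bad_instr, collapse = ", "))
  df
}

#' Score every patient-visit in a long-format response table
#'
#' Applies the instrument scoring engines to each patient x visit x
#' instrument group and returns one row per group, wide over subscales.
#' HOOS-12 rows are derived from the HOOS responses when
#' `derive_hoos12 = TRUE`; for HOOS-12 the `activity` column carries its
#' function scale.
#'
#' @param responses Data frame as returned by [read_responses()].
#' @param derive_hoos12 Also emit HOOS-12 scores extracted from HOOS rows?
#' @return Data frame with columns `patient_id`, `timepoint`, `instrument`,
#'   `total`, `pain`, `gait`, `symptoms`, `activity`, `sport`, `qol`,
#'   `n_missing_items` (subscales an instrument lacks are `NA`).
#' @export
score_responses <- function(responses, derive_hoos12 = TRUE) {
  check_timepoints(responses$timepoint)
  cols <- c("pain", "gait", "symptoms", "activity", "sport", "qol")
  key <- interaction(responses$patient_id, responses$timepoint,
                     responses$instrument, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(responses, key), function(g) {
    pid <- g$patient_id[1]; tp <- g$timepoint[1]; instr <- g$instrument[1]
    resp <- g[, c("item_id", "code")]
    recs <- if (instr == "mHHS") {
      list(score_mhhs(resp, pid, tp))
    } else if (derive_hoos12) {
      list(score_hoos_total(resp, pid, tp), extract_hoos12(resp, pid, tp))
    } else {
      list(score_hoos_total(resp, pid, tp))
    }
    do.call(rbind, lapply(recs, function(r) {
      ss <- stats::setNames(rep(NA_real_, length(cols)), cols)
      nm <- names(r$subscale_scores)
      nm[nm == "function"] <- "activity"   # HOOS-12 function scale
      ss[nm] <- r$subscale_scores
      data.frame(patient_id = r$patient_id, timepoint = r$timepoint,
                 instrument = r$instrument, total = r$total, t(ss),
                 n_missing_items = r$n_missing_items,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$patient_id, match(out$timepoint, TIMEPOINTS),
            out$instrument), , drop = FALSE]
}

#' Write / read a scores table
#'
#' @param scores Data frame from [score_responses()].
#' @param path CSV file path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$patient_id <- as.character(df$patient_id)
  check_timepoints(df$timepoint)
  df
}

#' Matched patient-derived score pairs
#'
#' Pairs two instruments' PD totals at common patient-visits — the training
#' set for a crosswalk.  `matched_pairs()` joins a scores table;
#' `matched_pair_set()` builds a set directly from score vectors (mainly for
#' tests and small worked examples).
#'
#' @param scores Data frame from [score_responses()].
#' @param instrument_x,instrument_y Instrument names; `x` is the side scores
#'   are converted *from* in the default direction.
#' @return An object of class `matched_pair_set`: a data frame with columns
#'   `patient_id`, `timepoint`, `score_x`, `score_y` and attributes
#'   `instrument_x`, `instrument_y`, `range_x`, `range_y`.
#' @export
matched_pairs <- function(scores, instrument_x = "mHHS",
                          instrument_y = "HOOS") {
  pick <- function(instr) {
    s <- scores[scores$instrument == instr & !is.na(scores$total),
                c("patient_id", "timepoint", "total")]
    if (anyDuplicated(s[, c("patient_id", "timepoint")]))
      stop_("duplicate %s score for some patient-visit", instr)
    s
  }
  m <- merge(pick(instrument_x), pick(instrument_y),
             by = c("patient_id", "timepoint"), suffixes = c("_x", "_y"))
  matched_pair_set(m$total_x, m$total_y,
                   patient_id = m$patient_id, timepoint = m$timepoint,
                   instrument_x = instrument_x, instrument_y = instrument_y)
}

#' @rdname matched_pairs
#' @param score_x,score_y Paired PD scores (no missing values).
#' @param patient_id,timepoint Pair identifiers (recycled if scalar).
#' @param range_x,range_y Score ranges; default from the instrument
#'   definitions.
#' @export
matched_pair_set <- function(score_x, score_y,
                             patient_id = as.character(seq_along(score_x)),
                             timepoint = "preop",
                             instrument_x = "mHHS", instrument_y = "HOOS",
                             range_x = NULL, range_y = NULL) {
  if (length(score_x) != length(score_y))
    stop_("score_x and score_y must have equal length")
  if (anyNA(score_x) || anyNA(score_y))
    stop_("matched pairs must have both scores non-missing")
  if (is.null(range_x)) range_x <- instrument_range(instrument_x)
  if (is.null(range_y)) range_y <- instrument_range(instrument_y)
  if (any(score_x < range_x[1] | score_x > range_x[2]))
    stop_("score_x outside the %s range [%g, %g]",
          instrument_x, range_x[1], range_x[2])
  if (any(score_y < range_y[1] | score_y > range_y[2]))
    stop_("score_y outside the %s range [%g, %g]",
          instrument_y, range_y[1], range_y[2])
  df <- data.frame(patient_id = rep_len(as.character(patient_id),
                                        length(score_x)),
                   timepoint = rep_len(as.character(timepoint),
                                       length(score_x)),
                   score_x = as.numeric(score_x),
                   score_y = as.numeric(score_y),
                   stringsAsFactors = FALSE)
  check_timepoints(df$timepoint)
  if (anyDuplicated(df[, c("patient_id", "timepoint")]))
    stop_("duplicate (patient_id, timepoint) in matched pairs")
  structure(df, class = c("matched_pair_set", "data.frame"),
            instrument_x = instrument_x, instrument_y = instrument_y,
            range_x = range_x, range_y = range_y)
}

#' @export
print.matched_pair_set <- function(x, ...) {
  cat(sprintf("<matched_pair_set> %s ~ %s, %d pairs\n",
              attr(x, "instrument_x"), attr(x, "instrument_y"), nrow(x)))
  print.data.frame(utils::head(x, 5))
  if (nrow(x) > 5) cat(sprintf("... %d more pairs\n", nrow(x) - 5L))
  invisible(x)
}

# Reverse pair orientation (x <-> y).
swap_pairs <- function(pairs) {
  matched_pair_set(pairs$score_y, pairs$score_x,
                   patient_id = pairs$patient_id, timepoint = pairs$timepoint,
                   instrument_x = attr(pairs, "instrument_y"),
                   instrument_y = attr(pairs, "instrument_x"),
                   range_x = attr(pairs, "range_y"),
                   range_y = attr(pairs, "range_x"))
}
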