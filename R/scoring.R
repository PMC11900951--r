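# Scoring engines: raw item responses -> patient-derived (PD) scores.

#' @rdname score_mhhs
#' @export
score_record <- function(patient_id, timepoint, instrument, total,
                         subscale_scores, n_missing_items) {
  structure(list(patient_id = patient_id, timepoint = timepoint,
                 instrument = instrument, total = total,
                 subscale_scores = subscale_scores,
                 n_missing_items = n_missing_items),
            class = "score_record")
}

#' @export
print.score_record <- function(x, ...) {
  cat(sprintf("<score_record> %s %s/%s: total %s (%d missing item%s)\n",
              x$instrument, x$patient_id, x$timepoint,
              ifelse(is.na(x$total), "NA", format(x$total)),
              x$n_missing_items, if (x$n_missing_items == 1) "" else "s"))
  ss <- x$subscale_scores
  cat("  ", paste(sprintf("%s=%s", names(ss),
                          ifelse(is.na(ss), "NA", format(ss))),
                  collapse = "  "), "\n")
  invisible(x)
}

# Accepts a named vector (item_id -> code) or a data frame with columns
# item_id and code; returns a clean data frame, rejecting duplicates.
normalise_responses <- function(responses) {
  if (is.data.frame(responses)) {
    if (!all(c("item_id", "code") %in% names(responses)))
      stop_("responses need columns 'item_id' and 'code'")
    out <- data.frame(item_id = as.character(responses$item_id),
                      code = responses$code, stringsAsFactors = FALSE)
  } else {
    if (is.null(names(responses)))
      stop_("responses must be a named vector or a data frame")
    out <- data.frame(item_id = names(responses),
                      code = unname(responses), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$item_id))
    stop_("duplicate response(s) for item(s): %s",
          paste(unique(out$item_id[duplicated(out$item_id)]), collapse = ", "))
  out$code <- suppressWarnings(as.integer(out$code))
  out
}

# Map each of an instrument's items to the answered code's points; NA where
# unanswered.  Rejects unknown items and undefined codes by name.
lookup_points <- function(def, responses) {
  r <- normalise_responses(responses)
  unknown <- setdiff(r$item_id, def$items$item_id)
  if (length(unknown))
    stop_("unknown %s item(s): %s", def$name, paste(unknown, collapse = ", "))
  codes <- r$code[match(def$items$item_id, r$item_id)]
  points <- rep(NA_real_, nrow(def$items))
  for (i in seq_along(codes)) {
    if (is.na(codes[i])) next
    id <- def$items$item_id[i]
    opt <- def$options[def$options$item_id == id, ]
    j <- match(codes[i], opt$code)
    if (is.na(j))
      stop_("code %d is not a defined option for %s item '%s'",
            codes[i], def$name, id)
    points[i] <- opt$points[j]
  }
  data.frame(item_id = def$items$item_id, domain = def$items$domain,
             retained = def$items$retained, code = codes, points = points,
             stringsAsFactors = FALSE)
}

#' Score one mHHS visit
#'
#' Computes the patient-derived (PD) modified Harris Hip Score from one
#' visit's item responses.  The total is the sum of the selected options'
#' point weights over the retained items; the public-transport item never
#' contributes.  Because item weights are unequal, a visit with any missing
#' retained item gets a missing total (no imputation).
#'
#' @param responses Named vector (`item_id` -> response code) or data frame
#'   with columns `item_id` and `code` for one patient-visit.
#' @param patient_id,timepoint Optional identifiers carried into the record.
#' @return A `score_record` with `total` in \[0, 90\] (or `NA`),
#'   `subscale_scores` containing `pain` (out of 44), `gait` (out of 33) and
#'   `activity` (stairs + shoes/socks + sitting, out of 13), and
#'   `n_missing_items` over retained items.
#' @examples
#' best <- c(pain = 0, limp = 0, support = 0, walk_distance = 0,
#'           stairs = 0, shoes_socks = 0, sitting = 0)
#' score_mhhs(best)$total  # 90
#' @export
score_mhhs <- function(responses, patient_id = NA_character_,
                       timepoint = NA_character_) {
  def <- instrument_definition("mHHS")
  tab <- lookup_points(def, responses)
  ret <- tab[tab$retained, ]
  if (all(is.na(ret$points)))
    stop_("no retained mHHS item answered for this visit")
  n_missing <- sum(is.na(ret$points))
  sub <- vapply(def$subscales, function(ids) {
    p <- tab$points[match(ids, tab$item_id)]
    if (anyNA(p)) NA_real_ else sum(p)
  }, numeric(1))
  total <- if (n_missing > 0) NA_real_ else sum(ret$points)
  score_record(patient_id, timepoint, "mHHS", total, sub, n_missing)
}

#' Score one HOOS subscale
#'
#' Transforms a subscale's 0 (best) to 4 (worst) item codes onto the 0–100
#' scale (100 = best): `100 - mean(answered codes) / 4 * 100`.  The subscale
#' is computed when at least half of its items are answered (mean of the
#' answered items), otherwise it is flagged missing rather than zero.
#'
#' @param responses Item responses of one visit (named vector or data frame).
#' @param subscale One of `"pain"`, `"symptoms"`, `"activity"`, `"sport"`,
#'   `"qol"`.
#' @return A number in \[0, 100\], or `NA` if too few items are answered.
#' @export
score_hoos_subscale <- function(responses,
                                subscale = c("pain", "symptoms", "activity",
                                             "sport", "qol")) {
  subscale <- match.arg(subscale)
  def <- instrument_definition("HOOS")
  tab <- lookup_points(def, responses)
  rescaled_subscale(tab, def$subscales[[subscale]])
}

# shared 0-100 transform with the half-answered rule
rescaled_subscale <- function(tab, ids) {
  codes <- tab$code[match(ids, tab$item_id)]
  answered <- codes[!is.na(codes)]
  if (length(answered) * 2 < length(ids)) return(NA_real_)
  100 - mean(answered) / 4 * 100
}

#' Score one HOOS visit
#'
#' Computes the five subscale scores (each 0–100, 100 = best) and the
#' overall PD HOOS as the unweighted mean of the five subscale scores.  The
#' total is missing whenever any subscale is missing under the
#' half-answered rule (see [score_hoos_subscale()]).
#'
#' @inheritParams score_mhhs
#' @return A `score_record` with subscales `pain`, `symptoms`, `activity`,
#'   `sport`, `qol`.
#' @export
score_hoos_total <- function(responses, patient_id = NA_character_,
                             timepoint = NA_character_) {
  def <- instrument_definition("HOOS")
  tab <- lookup_points(def, responses)
  if (all(is.na(tab$code)))
    stop_("no HOOS item answered for this visit")
  sub <- vapply(def$subscales, function(ids) rescaled_subscale(tab, ids),
                numeric(1))
  total <- if (anyNA(sub)) NA_real_ else mean(sub)
  score_record(patient_id, timepoint, "HOOS", total, sub,
               sum(is.na(tab$code)))
}

#' Extract and score the HOOS-12 from HOOS responses
#'
#' The 12-item short form is scored from a completed HOOS questionnaire
#' using only the 12 designated items (see [hoos12_item_map()]): three
#' 4-item scales (pain, function, quality of life) each on 0–100, with
#' their unweighted mean as the total.
#'
#' @param responses HOOS item responses of one visit (the full 40 items or
#'   any subset containing the designated 12).
#' @inheritParams score_mhhs
#' @return A `score_record` for instrument `"HOOS-12"`.
#' @export
extract_hoos12 <- function(responses, patient_id = NA_character_,
                           timepoint = NA_character_) {
  hoos <- instrument_definition("HOOS")
  def12 <- instrument_definition("HOOS-12")
  tab <- lookup_points(hoos, responses)   # accepts any HOOS item
  sub <- vapply(def12$subscales, function(ids) rescaled_subscale(tab, ids),
                numeric(1))
  total <- if (anyNA(sub)) NA_real_ else mean(sub)
  n_missing <- sum(is.na(tab$code[match(def12$items$item_id, tab$item_id)]))
  score_record(patient_id, timepoint, "HOOS-12", total, sub, n_missing)
}

#' Pain and activity subcategory scores
#'
#' The crosswalk subcategory analysis compares pain and activity across
#' instruments on the scales their published error tables use: HOOS and
#' HOOS-12 pain/activity rescaled to 0–100 (100 = best), mHHS pain raw out
#' of 44 and mHHS activity (stairs + shoes/socks + sitting) raw out of 13.
#' For HOOS-12 the activity subcategory is its 4-item function scale.
#'
#' @param responses Item responses of one visit for `instrument`.
#' @param instrument `"mHHS"`, `"HOOS"` or `"HOOS-12"`.
#' @return Named numeric `c(pain = , activity = )`; a subcategory with
#'   missing constituent items is `NA`.
#' @examples
#' subcategory_scores(c(stairs = 0, shoes_socks = 0, sitting = 0,
#'                      pain = 0), "mHHS")["activity"]  # 13
#' @export
subcategory_scores <- function(responses,
                               instrument = c("mHHS", "HOOS", "HOOS-12")) {
  instrument <- match.arg(instrument)
  if (instrument == "mHHS") {
    def <- instrument_definition("mHHS")
    tab <- lookup_points(def, responses)
    raw_sum <- function(ids) {
      p <- tab$points[match(ids, tab$item_id)]
      if (anyNA(p)) NA_real_ else sum(p)
    }
    return(c(pain = raw_sum(def$subscales$pain),
             activity = raw_sum(def$subscales$activity)))
  }
  hoos <- instrument_definition("HOOS")
  tab <- lookup_points(hoos, responses)
  if (instrument == "HOOS") {
    ids_pain <- hoos$subscales$pain
    ids_act <- hoos$subscales$activity
  } else {
    def12 <- instrument_definition("HOOS-12")
    ids_pain <- def12$subscales$pain
    ids_act <- def12$subscales[["function"]]
  }
  c(pain = rescaled_subscale(tab, ids_pain),
    activity = rescaled_subscale(tab, ids_act))
}

#' Subcategory score ranges
#'
#' Scale limits used by the subcategory crosswalks and their error tables:
#' mHHS pain 0–44 and activity 0–13 (raw points), HOOS/HOOS-12 pain and
#' activity 0–100.
#'
#' @inheritParams subcategory_scores
#' @param subcategory `"pain"` or `"activity"`.
#' @return Numeric `c(min, max)`.
#' @export
subcategory_range <- function(instrument, subcategory = c("pain", "activity")) {
  subcategory <- match.arg(subcategory)
  if (instrument == "mHHS") {
    if (subcategory == "pain") c(0, 44) else c(0, 13)
  } else c(0, 100)
}
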