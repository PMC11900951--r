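#' Instrument definitions
#'
#' The package ships definitions of the three hip patient-reported outcome
#' instruments it links:
#'
#' * **mHHS** — the modified Harris Hip Score: the patient-reported part of
#'   the Harris Hip Score without the clinician-scored range-of-motion and
#'   deformity domains, and with the public-transport item excluded from the
#'   total.  Items carry unequal point weights (pain up to 44, gait 33,
#'   stairs/shoes/sitting 13); the retained maximum is 90, higher = better.
#' * **HOOS** — the Hip disability and Osteoarthritis Outcome Score: 40 items
#'   in five subscales (pain 10, symptoms 5, activities of daily living 17,
#'   sport/recreation 4, quality of life 4), each item coded 0 (best) to 4
#'   (worst), each subscale linearly transformed to 0–100 (100 = best).
#' * **HOOS-12** — the 12-item short form extracted from a completed HOOS
#'   (pain, function and quality-of-life scales of 4 items each).
#'
#' Rubrics are read from editable CSV files under `inst/extdata/` so the
#' point weights and the HOOS-12 item mapping can be adjusted without
#' touching code; the mHHS rubric is checked at load time against the
#' instrument's published domain totals (pain 44, gait 33, activities of
#' daily living 14; retained total 90, 91 with the public-transport item).
#'
#' @param name Instrument name: `"mHHS"`, `"HOOS"` or `"HOOS-12"`.
#' @return An object of class `instrument_definition`: a list with elements
#'   `name`, `items` (data frame: `item_id`, `domain`, `retained`),
#'   `options` (data frame: `item_id`, `code`, `points`), `score_min`,
#'   `score_max` and `subscales` (named list of item-id vectors).
#' @examples
#' def <- instrument_definition("mHHS")
#' def$score_max      # 90
#' names(def$subscales)
#' @export
instrument_definition <- function(name = c("mHHS", "HOOS", "HOOS-12")) {
  name <- match.arg(name)
  key <- gsub("-", "_", name)
  cached <- .instrument_cache[[key]]
  if (!is.null(cached)) return(cached)
  def <- switch(name,
    "mHHS"    = build_mhhs_definition(),
    "HOOS"    = build_hoos_definition(),
    "HOOS-12" = build_hoos12_definition())
  assign(key, def, envir = .instrument_cache)
  def
}

.instrument_cache <- new.env(parent = emptyenv())

#' @export
print.instrument_definition <- function(x, ...) {
  cat(sprintf("<instrument_definition> %s: %d items, score range [%g, %g]\n",
              x$name, nrow(x$items), x$score_min, x$score_max))
  cat("subscales:",
      paste(sprintf("%s (%d)", names(x$subscales), lengths(x$subscales)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Score range of an instrument
#'
#' @param name Instrument name.
#' @return Numeric vector `c(min, max)`.
#' @export
instrument_range <- function(name) {
  def <- instrument_definition(name)
  c(def$score_min, def$score_max)
}

new_instrument_definition <- function(name, items, options, score_min,
                                      score_max, subscales) {
  stopifnot(!anyDuplicated(items$item_id))
  # options strictly ordered by code, no duplicates, within each item
  for (id in items$item_id) {
    codes <- options$code[options$item_id == id]
    if (anyDuplicated(codes) || is.unsorted(codes, strictly = TRUE))
      stop_("options for item '%s' are not strictly ordered by code", id)
  }
  structure(list(name = name, items = items, options = options,
                 score_min = score_min, score_max = score_max,
                 subscales = subscales),
            class = "instrument_definition")
}

item_max_points <- function(options, ids) {
  vapply(ids, function(id) max(options$points[options$item_id == id]),
         numeric(1))
}

build_mhhs_definition <- function() {
  rub <- utils::read.csv(extdata("mhhs_rubric.csv"), stringsAsFactors = FALSE)
  items <- unique(rub[, c("item_id", "domain", "retained")])
  rownames(items) <- NULL
  options <- rub[, c("item_id", "code", "points")]
  # per-item weak monotonicity: points never increase with severity code
  for (id in items$item_id) {
    p <- options$points[options$item_id == id]
    if (is.unsorted(rev(p))) stop_("mHHS item '%s' weights not decreasing", id)
  }
  retained <- items$item_id[items$retained]
  maxima <- item_max_points(options, retained)
  subscales <- list(
    pain     = "pain",
    gait     = c("limp", "support", "walk_distance"),
    activity = c("stairs", "shoes_socks", "sitting"))
  # pin the editable rubric to the published domain totals
  stopifnot(
    sum(maxima) == 90,
    sum(item_max_points(options, items$item_id)) == 91,
    sum(item_max_points(options, subscales$pain)) == 44,
    sum(item_max_points(options, subscales$gait)) == 33,
    sum(item_max_points(options, subscales$activity)) == 13)
  new_instrument_definition("mHHS", items, options, 0, 90, subscales)
}

build_hoos_definition <- function() {
  tab <- utils::read.csv(extdata("hoos_items.csv"), stringsAsFactors = FALSE)
  items <- data.frame(item_id = tab$item_id, domain = tab$subscale,
                      retained = TRUE, stringsAsFactors = FALSE)
  options <- data.frame(
    item_id = rep(tab$item_id, each = 5),
    code = rep(0:4, nrow(tab)),
    points = rep(0:4, nrow(tab)))   # raw points equal severity codes
  subscales <- split(tab$item_id, tab$subscale)
  subscales <- subscales[c("pain", "symptoms", "activities", "sport", "qol")]
  names(subscales)[names(subscales) == "activities"] <- "activity"
  stopifnot(nrow(items) == 40,
            identical(unname(lengths(subscales)), c(10L, 5L, 17L, 4L, 4L)))
  new_instrument_definition("HOOS", items, options, 0, 100, subscales)
}

build_hoos12_definition <- function() {
  hoos <- instrument_definition("HOOS")
  map <- utils::read.csv(extdata("hoos12_items.csv"), stringsAsFactors = FALSE)
  missing <- setdiff(map$hoos_item_id, hoos$items$item_id)
  if (length(missing))
    stop_("HOOS-12 mapping refers to unknown HOOS item(s): %s",
          paste(missing, collapse = ", "))
  keep <- hoos$items$item_id %in% map$hoos_item_id
  items <- hoos$items[keep, ]
  rownames(items) <- NULL
  options <- hoos$options[hoos$options$item_id %in% map$hoos_item_id, ]
  rownames(options) <- NULL
  subscales <- split(map$hoos_item_id, map$scale)[c("pain", "function", "qol")]
  stopifnot(nrow(items) == 12,
            identical(unname(lengths(subscales)), c(4L, 4L, 4L)))
  new_instrument_definition("HOOS-12", items, options, 0, 100, subscales)
}

#' HOOS items forming the bundled HOOS-12 short form
#'
#' Returns the editable item mapping shipped in `inst/extdata/hoos12_items.csv`:
#' which HOOS items enter the 12-item short form and which of its three
#' scales (pain, function, quality of life) each belongs to.
#'
#' @return Data frame with columns `hoos_item_id` and `scale`.
#' @export
hoos12_item_map <- function() {
  utils::read.csv(extdata("hoos12_items.csv"), stringsAsFactors = FALSE)
}
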