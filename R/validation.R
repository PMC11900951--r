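# Crosswalk validity: Spearman gate, MAE (overall / per time point /
# per subcategory), correlation power analysis.

#' Spearman correlation gate
#'
#' A crosswalk is only built when the two instruments' PD scores show a
#' Spearman rank correlation of at least `threshold` (0.3 by default, the
#' customary minimum for observed-score linking).  Ties are handled by
#' average ranks.  If the correlation falls below the threshold a condition
#' of class `hipcw_gate_failure` is raised carrying the computed rho, so
#' callers can refuse to write a crosswalk.
#'
#' @param pairs A [matched_pair_set()] (at least 3 pairs).
#' @param threshold Minimum admissible Spearman rho.
#' @return The Spearman rho (invisibly a plain number), when the gate passes.
#' @export
spearman_gate <- function(pairs, threshold = 0.3) {
  x <- pairs$score_x; y <- pairs$score_y
  if (length(x) < 3) stop_("Spearman gate needs at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_("degenerate constant score series: Spearman rho undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (rho < threshold) {
    cond <- structure(
      class = c("hipcw_gate_failure", "error", "condition"),
      list(message = sprintf(
             "Spearman gate failed: rho = %.4f < threshold %.3f; crosswalk not built",
             rho, threshold),
           call = NULL, rho = rho, threshold = threshold))
    stop(cond)
  }
  rho
}

#' Mean absolute error of a crosswalk
#'
#' Validates a crosswalk by converting each pair's source PD score and
#' comparing the crosswalk-derived (CWD) score against the paired target PD
#' score: `MAE = mean(|CWD - PD|)`, on unrounded CWD values.  Errors are
#' reported overall, per follow-up time point (a time point with no pairs
#' is flagged absent, not zero), and as the largest absolute difference
#' together with the source score at which it occurs.
#'
#' @param pairs A [matched_pair_set()] oriented source -> target (use
#'   `direction` to flip).
#' @param table A `crosswalk_table` whose source instrument matches the
#'   pair orientation.
#' @param direction Orientation of `pairs` relative to the table.
#' @return Object of class `crosswalk_mae`: list with `mae_overall`,
#'   `mae_by_timepoint` (named over `preop`, `3m`, `6m`, `12m`; `NA` where
#'   empty), `n_overall`, `n_by_timepoint`, `max_abs_difference`,
#'   `max_abs_at_source_score`.
#' @export
crosswalk_mae <- function(pairs, table, direction = c("x_to_y", "y_to_x")) {
  p <- orient_pairs(pairs, direction)
  if (!identical(attr(p, "instrument_x"), table$source_instrument) ||
      !identical(attr(p, "instrument_y"), table$target_instrument))
    stop_("table direction (%s -> %s) does not match pair orientation (%s -> %s)",
          table$source_instrument, table$target_instrument,
          attr(p, "instrument_x"), attr(p, "instrument_y"))
  cwd <- apply_crosswalk(table, p$score_x)
  err <- abs(cwd - p$score_y)
  by_tp <- vapply(TIMEPOINTS, function(tp) {
    e <- err[p$timepoint == tp]
    if (!length(e)) NA_real_ else mean(e)
  }, numeric(1))
  n_tp <- vapply(TIMEPOINTS, function(tp) sum(p$timepoint == tp), integer(1))
  imax <- which.max(err)
  structure(list(mae_overall = mean(err),
                 mae_by_timepoint = by_tp,
                 n_overall = nrow(p), n_by_timepoint = n_tp,
                 max_abs_difference = err[imax],
                 max_abs_at_source_score = p$score_x[imax]),
            class = "crosswalk_mae")
}

#' @export
print.crosswalk_mae <- function(x, ...) {
  cat(sprintf("<crosswalk_mae> overall %.2f over %d pairs; largest |CWD - PD| %.2f at source %g\n",
              x$mae_overall, x$n_overall, x$max_abs_difference,
              x$max_abs_at_source_score))
  tp <- x$mae_by_timepoint
  cat("  ", paste(sprintf("%s=%s", names(tp),
                          ifelse(is.na(tp), "-", sprintf("%.2f", tp))),
                  collapse = "  "), "\n")
  invisible(x)
}

parse_direction <- function(direction) {
  parts <- strsplit(direction, "_to_", fixed = TRUE)[[1]]
  ok <- c("mHHS", "HOOS", "HOOS-12")
  if (length(parts) != 2 || !all(parts %in% ok))
    stop_("unknown direction '%s' (expected e.g. 'mHHS_to_HOOS')", direction)
  list(source = parts[1], target = parts[2])
}

#' Subcategory mean absolute error (equipercentile)
#'
#' Pain and activity are linked separately with the equipercentile method
#' (the subcategory scores are coarse-grained, so a parametric line is not
#' used) to locate which domain contributes most error.  The HOOS /
#' HOOS-12 side is rescaled to 0–100; the mHHS side stays raw, out of 44
#' (pain) and 13 (activity), and each subcategory's MAE is reported on the
#' target side's scale.
#'
#' @param responses Long-format item responses (both instruments) as read
#'   by [read_responses()].
#' @param direction One of `"mHHS_to_HOOS"`, `"HOOS_to_mHHS"`,
#'   `"mHHS_to_HOOS-12"`, `"HOOS-12_to_mHHS"`.
#' @return Named numeric `c(pain = , activity = )` with attributes `n`
#'   (pairs used per subcategory).
#' @export
subcategory_mae <- function(responses, direction = "mHHS_to_HOOS") {
  d <- parse_direction(direction)
  sub <- subcategory_series(responses)
  other <- setdiff(c(d$source, d$target), "mHHS")
  out <- c(pain = NA_real_, activity = NA_real_)
  n <- c(pain = 0L, activity = 0L)
  for (sc in c("pain", "activity")) {
    m <- merge(sub[sub$instrument == "mHHS", c("patient_id", "timepoint", sc)],
               sub[sub$instrument == other, c("patient_id", "timepoint", sc)],
               by = c("patient_id", "timepoint"), suffixes = c("_m", "_o"))
    m <- m[stats::complete.cases(m), ]
    sx <- if (d$source == "mHHS") m[[paste0(sc, "_m")]] else m[[paste0(sc, "_o")]]
    sy <- if (d$source == "mHHS") m[[paste0(sc, "_o")]] else m[[paste0(sc, "_m")]]
    pairs <- matched_pair_set(sx, sy,
                              patient_id = m$patient_id,
                              timepoint = m$timepoint,
                              instrument_x = d$source, instrument_y = d$target,
                              range_x = subcategory_range(d$source, sc),
                              range_y = subcategory_range(d$target, sc))
    tab <- equipercentile_crosswalk(pairs)
    out[sc] <- crosswalk_mae(pairs, tab)$mae_overall
    n[sc] <- nrow(pairs)
  }
  attr(out, "n") <- n
  out
}

# one row per visit x instrument with pain / activity subcategory scores
subcategory_series <- function(responses) {
  key <- interaction(responses$patient_id, responses$timepoint,
                     responses$instrument, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(responses, key), function(g) {
    instr <- g$instrument[1]
    resp <- g[, c("item_id", "code")]
    mk <- function(instrument, s)
      data.frame(patient_id = g$patient_id[1], timepoint = g$timepoint[1],
                 instrument = instrument, pain = s[["pain"]],
                 activity = s[["activity"]], stringsAsFactors = FALSE)
    if (instr == "mHHS") {
      mk("mHHS", subcategory_scores(resp, "mHHS"))
    } else {
      rbind(mk("HOOS", subcategory_scores(resp, "HOOS")),
            mk("HOOS-12", subcategory_scores(resp, "HOOS-12")))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample size for detecting a correlation
#'
#' Smallest number of matched score pairs at which the test of rho = 0
#' against rho = `r_min` reaches the target power, using the bias-corrected
#' Fisher-z normal approximation: `z_r = atanh(r) + r / (2 (n - 1))`
#' compared against the t-based critical correlation at level `alpha`
#' (`alpha / 2` when two-sided).  With the conventional linking threshold
#' `r_min = 0.3`, `alpha = 0.05` and power 0.8 the one-sided answer is 67
#' matched pairs (the two-sided reading needs 85).
#'
#' @param r_min Minimum correlation to detect, in (0, 1).
#' @param alpha Significance level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param sided `"one"` (default) or `"two"`.
#' @return Integer sample size (at least 4).
#' @examples
#' required_sample_size(0.3, 0.05, 0.8)  # 67
#' @export
required_sample_size <- function(r_min = 0.3, alpha = 0.05, power = 0.8,
                                 sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!is.finite(r_min) || r_min <= 0 || r_min >= 1)
    stop_("r_min must lie strictly between 0 and 1")
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie strictly between 0 and 1")
  if (power <= 0 || power >= 1) stop_("power must lie strictly between 0 and 1")
  pw <- function(n) correlation_power(n, r_min, alpha, sided)
  n <- 4L
  if (pw(n) >= power) return(n)
  hi <- 8L
  while (pw(hi) < power) {
    hi <- hi * 2L
    if (hi > 1e8) stop_("required sample size exceeds 1e8; check inputs")
  }
  lo <- hi %/% 2L
  while (hi - lo > 1L) {      # power is monotone increasing in n
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

# Power of the correlation test at sample size n against rho = r.
correlation_power <- function(n, r, alpha, sided = "one") {
  a <- if (sided == "two") alpha / 2 else alpha
  tcrit <- stats::qt(a, df = n - 2, lower.tail = FALSE)
  rc <- sqrt(tcrit^2 / (tcrit^2 + n - 2))      # critical sample correlation
  zr <- atanh(r) + r / (2 * (n - 1))           # bias-corrected Fisher z
  stats::pnorm((zr - atanh(rc)) * sqrt(n - 3))
}
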