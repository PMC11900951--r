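# Observed-score equating: equipercentile and linear-regression crosswalks.

#' Mid-percentile rank with linear continuization
#'
#' The percentile rank of `x` in `sample` is
#' `100 * (count(sample < x) + 0.5 * count(sample == x)) / n`.  Because the
#' instruments are discrete, the rank function is continuized: for `x`
#' strictly between two observed distinct scores the rank is interpolated
#' linearly between their mid-ranks.  Values below (above) every
#' observation return 0 (100).
#'
#' @param sample Numeric vector of observed scores (non-empty; `NA` dropped).
#' @param x Score(s) at which to evaluate the rank.
#' @return Percentile rank(s) in \[0, 100\].
#' @examples
#' percentile_rank(c(10, 20, 20, 30), 20)  # 50
#' percentile_rank(c(10, 20, 20, 30), 10)  # 12.5
#' @export
percentile_rank <- function(sample, x) {
  sample <- sample[!is.na(sample)]
  if (!length(sample)) stop_("percentile rank needs a non-empty sample")
  pr <- rank_function(sample)
  pr(x)
}

# Closure evaluating the continuized mid-percentile-rank function.
rank_function <- function(sample) {
  v <- sort(unique(sample))
  n <- length(sample)
  cnt <- tabulate(match(sample, v), nbins = length(v))
  mid <- 100 * (cumsum(cnt) - cnt / 2) / n
  function(x) {
    vapply(as.numeric(x), function(s) {
      if (s < v[1]) return(0)
      if (s > v[length(v)]) return(100)
      i <- findInterval(s, v)
      if (v[i] == s) return(mid[i])
      mid[i] + (mid[i + 1] - mid[i]) * (s - v[i]) / (v[i + 1] - v[i])
    }, numeric(1))
  }
}

# Inverse of the continuized rank function: piecewise-linear through
# (mid-rank, score), clamped to the observed score extremes.
inverse_rank_function <- function(sample) {
  v <- sort(unique(sample))
  n <- length(sample)
  cnt <- tabulate(match(sample, v), nbins = length(v))
  mid <- 100 * (cumsum(cnt) - cnt / 2) / n
  function(p) {
    vapply(as.numeric(p), function(q) {
      if (q <= mid[1]) return(v[1])
      if (q >= mid[length(mid)]) return(v[length(v)])
      i <- findInterval(q, mid)
      if (mid[i] == q) return(v[i])
      v[i] + (v[i + 1] - v[i]) * (q - mid[i]) / (mid[i + 1] - mid[i])
    }, numeric(1))
  }
}

new_crosswalk_table <- function(source_score, target_score, method,
                                source_instrument, target_instrument,
                                source_range, target_range, n_pairs,
                                slope = NULL, intercept = NULL) {
  target_score <- clamp(target_score, target_range[1], target_range[2])
  entries <- data.frame(source_score = as.integer(source_score),
                        target_score = as.numeric(target_score))
  stopifnot(identical(entries$source_score,
                      as.integer(seq(source_range[1], source_range[2], by = 1))),
            !is.unsorted(entries$target_score))
  structure(list(method = method,
                 source_instrument = source_instrument,
                 target_instrument = target_instrument,
                 source_range = source_range, target_range = target_range,
                 n_pairs = n_pairs,
                 fit_meta = if (is.null(slope)) NULL else
                   list(slope = slope, intercept = intercept),
                 entries = entries),
            class = "crosswalk_table")
}

#' @export
print.crosswalk_table <- function(x, ...) {
  cat(sprintf("<crosswalk_table> %s: %s -> %s (n_pairs = %s)\n",
              x$method, x$source_instrument, x$target_instrument,
              ifelse(is.na(x$n_pairs), "?", x$n_pairs)))
  if (!is.null(x$fit_meta))
    cat(sprintf("  fit: target = %.6g * source + %.6g\n",
                x$fit_meta$slope, x$fit_meta$intercept))
  cat(sprintf("  grid: %d..%d -> [%g, %g]\n",
              x$source_range[1], x$source_range[2],
              x$target_range[1], x$target_range[2]))
  invisible(x)
}

orient_pairs <- function(pairs, direction = c("x_to_y", "y_to_x")) {
  direction <- match.arg(direction)
  if (direction == "y_to_x") swap_pairs(pairs) else pairs
}

#' Equipercentile crosswalk
#'
#' Non-parametric observed-score linking: scores with the same percentile
#' rank in their respective distributions are considered equivalent.  For
#' every integer source score the continuized mid-percentile rank in the
#' source distribution is pushed through the inverse of the target
#' distribution's rank function, interpolating linearly between observed
#' target scores.  Source grid points below (above) every observed source
#' score are mapped linearly from the outermost observed conversion down
#' (up) to the target range endpoint, so a bounded instrument is never
#' extrapolated past its range.
#'
#' @param pairs A [matched_pair_set()].
#' @param direction `"x_to_y"` (default) converts `instrument_x` scores to
#'   `instrument_y`; `"y_to_x"` the reverse.
#' @return A `crosswalk_table` covering every integer source score, with a
#'   non-decreasing target column inside the target range.
#' @export
equipercentile_crosswalk <- function(pairs, direction = c("x_to_y", "y_to_x")) {
  p <- orient_pairs(pairs, direction)
  x <- p$score_x; y <- p$score_y
  if (length(unique(x)) < 2)
    stop_("all source scores identical: the source distribution cannot be inverted")
  if (length(unique(y)) < 2)
    stop_("all target scores identical: the target distribution cannot be inverted")
  src_range <- attr(p, "range_x"); tgt_range <- attr(p, "range_y")
  grid <- seq(src_range[1], src_range[2], by = 1L)
  pr_x <- rank_function(x)
  inv_y <- inverse_rank_function(y)
  x_lo <- min(x); x_hi <- max(x)
  y_lo <- inv_y(pr_x(x_lo)); y_hi <- inv_y(pr_x(x_hi))
  target <- vapply(grid, function(s) {
    if (s < x_lo) {
      # linear ramp from the target minimum up to the lowest conversion
      tgt_range[1] + (y_lo - tgt_range[1]) * (s - src_range[1]) / (x_lo - src_range[1])
    } else if (s > x_hi) {
      y_hi + (tgt_range[2] - y_hi) * (s - x_hi) / (src_range[2] - x_hi)
    } else {
      inv_y(pr_x(s))
    }
  }, numeric(1))
  new_crosswalk_table(grid, cummax(target), "EQ",
                      attr(p, "instrument_x"), attr(p, "instrument_y"),
                      src_range, tgt_range, nrow(p))
}

#' Linear-regression crosswalk
#'
#' Assumes a linear relationship between the two instruments' PD scores and
#' tabulates the ordinary least-squares line `target = slope * source +
#' intercept` on the integer source grid, clamped to the target range.  The
#' fitted coefficients are kept in `fit_meta` at full precision.
#'
#' @inheritParams equipercentile_crosswalk
#' @return A `crosswalk_table` with `fit_meta$slope` / `fit_meta$intercept`.
#' @export
linear_regression_crosswalk <- function(pairs,
                                        direction = c("x_to_y", "y_to_x")) {
  p <- orient_pairs(pairs, direction)
  if (stats::var(p$score_x) == 0)
    stop_("zero variance in source scores: no line can be fitted")
  fit <- stats::lm(score_y ~ score_x, data = p)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  src_range <- attr(p, "range_x"); tgt_range <- attr(p, "range_y")
  grid <- seq(src_range[1], src_range[2], by = 1L)
  raw <- slope * grid + intercept
  if (any(raw < tgt_range[1] | raw > tgt_range[2]))
    warning(sprintf("%s->%s line leaves the target range [%g, %g]; values clamped",
                    attr(p, "instrument_x"), attr(p, "instrument_y"),
                    tgt_range[1], tgt_range[2]), call. = FALSE)
  tab <- new_crosswalk_table(grid, raw, "LR",
                             attr(p, "instrument_x"), attr(p, "instrument_y"),
                             src_range, tgt_range, nrow(p),
                             slope = slope, intercept = intercept)
  tab
}

# Crosswalk table straight from published line coefficients.
lr_table_from_coef <- function(slope, intercept, source_instrument,
                               target_instrument, n_pairs = NA_integer_) {
  src_range <- instrument_range(source_instrument)
  tgt_range <- instrument_range(target_instrument)
  grid <- seq(src_range[1], src_range[2], by = 1L)
  new_crosswalk_table(grid, slope * grid + intercept, "LR",
                      source_instrument, target_instrument,
                      src_range, tgt_range, n_pairs,
                      slope = slope, intercept = intercept)
}

#' Convert scores through a crosswalk
#'
#' Integer scores are table lookups; non-integer scores interpolate
#' linearly between the adjacent grid entries.  Scores outside the source
#' instrument's range are rejected.
#'
#' @param table A `crosswalk_table`.
#' @param score Numeric score(s) on the source instrument.
#' @return Crosswalk-derived (CWD) score(s) on the target instrument,
#'   always inside the target range.
#' @export
apply_crosswalk <- function(table, score) {
  stopifnot(inherits(table, "crosswalk_table"))
  rng <- table$source_range
  if (anyNA(score) || any(score < rng[1] | score > rng[2]))
    stop_("score outside the %s source range [%g, %g]",
          table$source_instrument, rng[1], rng[2])
  stats::approx(table$entries$source_score, table$entries$target_score,
                xout = score, rule = 2)$y
}

#' Write / read a crosswalk table CSV
#'
#' One row per integer source grid point, columns
#' `source_score,target_score_exact,target_score_rounded` (rounding half
#' away from zero), preceded by `#` comment lines carrying the method,
#' direction, pair count and — for linear crosswalks — slope and intercept
#' at full precision.
#'
#' @param table A `crosswalk_table`.
#' @param path CSV file path.
#' @export
write_crosswalk <- function(table, path) {
  meta <- c(sprintf("# method: %s", table$method),
            sprintf("# source: %s", table$source_instrument),
            sprintf("# target: %s", table$target_instrument),
            sprintf("# n_pairs: %s", table$n_pairs))
  if (!is.null(table$fit_meta))
    meta <- c(meta,
              sprintf("# slope: %.17g", table$fit_meta$slope),
              sprintf("# intercept: %.17g", table$fit_meta$intercept))
  body <- data.frame(source_score = table$entries$source_score,
                     target_score_exact = table$entries$target_score,
                     target_score_rounded =
                       as.integer(round_half_away(table$entries$target_score)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(body, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  new_crosswalk_table(
    body$source_score, body$target_score_exact,
    method = meta$method,
    source_instrument = meta$source, target_instrument = meta$target,
    source_range = range(body$source_score),
    target_range = instrument_range(meta$target),
    n_pairs = as.integer(meta$n_pairs),
    slope = if (!is.null(meta$slope)) as.numeric(meta$slope),
    intercept = if (!is.null(meta$intercept)) as.numeric(meta$intercept))
}
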