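# Response-vector builders and independent oracles used across tests.

mhhs_items <- function() instrument_definition("mHHS")$items$item_id
hoos_items <- function() instrument_definition("HOOS")$items$item_id

# Response vector selecting one extreme on every item of an instrument.
best_mhhs <- function(include_transport = FALSE) {
  ids <- mhhs_items()
  if (!include_transport) ids <- setdiff(ids, "public_transport")
  stats::setNames(rep(0L, length(ids)), ids)
}
worst_mhhs <- function() {
  def <- instrument_definition("mHHS")
  codes <- vapply(def$items$item_id, function(id)
    max(def$options$code[def$options$item_id == id]), integer(1))
  stats::setNames(codes, def$items$item_id)
}
hoos_uniform <- function(code) stats::setNames(rep(code, 40L), hoos_items())

# random valid single-visit responses for property tests
random_mhhs <- function() {
  def <- instrument_definition("mHHS")
  vapply(stats::setNames(def$items$item_id, def$items$item_id), function(id) {
    codes <- def$options$code[def$options$item_id == id]
    sample(codes, 1)
  }, integer(1))
}
random_hoos <- function() stats::setNames(sample(0:4, 40, replace = TRUE),
                                          hoos_items())

# Brute-force equipercentile oracle: direct counting for the rank, linear
# scan + approx() for the inverse.  Independent of the package's
# findInterval-based implementation.
oracle_eq_table <- function(x, y, src_range, tgt_range) {
  pr <- function(sample, s) {
    v <- sort(unique(sample))
    if (s %in% v || s <= min(v) || s >= max(v)) {
      100 * (sum(sample < s) + 0.5 * sum(sample == s)) / length(sample)
    } else {
      lo <- max(v[v < s]); hi <- min(v[v > s])
      p_lo <- 100 * (sum(sample < lo) + 0.5 * sum(sample == lo)) / length(sample)
      p_hi <- 100 * (sum(sample < hi) + 0.5 * sum(sample == hi)) / length(sample)
      p_lo + (p_hi - p_lo) * (s - lo) / (hi - lo)
    }
  }
  inv <- function(sample, p) {
    v <- sort(unique(sample))
    mids <- vapply(v, function(s) pr(sample, s), numeric(1))
    if (p <= mids[1]) return(v[1])
    if (p >= mids[length(mids)]) return(v[length(v)])
    stats::approx(mids, v, xout = p)$y
  }
  grid <- seq(src_range[1], src_range[2])
  x_lo <- min(x); x_hi <- max(x)
  vapply(grid, function(s) {
    if (s < x_lo) {
      y_lo <- inv(y, pr(x, x_lo))
      tgt_range[1] + (y_lo - tgt_range[1]) * (s - src_range[1]) / (x_lo - src_range[1])
    } else if (s > x_hi) {
      y_hi <- inv(y, pr(x, x_hi))
      y_hi + (tgt_range[2] - y_hi) * (s - x_hi) / (src_range[2] - x_hi)
    } else inv(y, pr(x, s))
  }, numeric(1))
}

# Brute-force Spearman: Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  rk <- function(v) vapply(v, function(s)
    sum(v < s) + (sum(v == s) + 1) / 2, numeric(1))
  stats::cor(rk(x), rk(y))
}

# Small matched cohort on reduced integer supports, used by equating tests.
small_pairs <- function(n, seed, range_x = c(0, 90), range_y = c(0, 100)) {
  set.seed(seed)
  x <- sample(seq(range_x[1] + 5, range_x[2] - 5), n, replace = TRUE)
  y <- round(clamp(range_y[2] * (x - range_x[1]) / diff(range_x) +
                     rnorm(n, 0, 8), range_y[1], range_y[2]))
  matched_pair_set(x, y,
                   timepoint = sample(c("preop", "3m", "6m", "12m"), n,
                                      replace = TRUE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
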