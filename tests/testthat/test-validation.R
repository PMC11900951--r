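# Spearman gate, MAE reporting, subcategory analysis, power analysis.

test_that("spearman gate passes concordant and fails discordant series", {
  x <- c(10, 20, 30, 40, 50, 60, 70, 80, 85, 90)
  expect_equal(spearman_gate(matched_pair_set(x, x + 5)), 1)
  disc <- matched_pair_set(x, rev(x))
  err <- tryCatch(spearman_gate(disc), error = identity)
  expect_s3_class(err, "hipcw_gate_failure")
  expect_equal(err$rho, -1)
})

test_that("spearman gate agrees with a brute-force rank correlation", {
  set.seed(8)
  x <- sample(0:90, 10)
  y <- clamp(100 - x + sample(-30:30, 10, replace = TRUE), 0, 100)
  rho <- oracle_spearman(x, y)
  expect_lt(rho, 0.3)    # fixture chosen below the linking threshold
  err <- tryCatch(spearman_gate(matched_pair_set(x, y)), error = identity)
  expect_s3_class(err, "hipcw_gate_failure")
  expect_equal(err$rho, rho, tolerance = 1e-12)
  # and on a passing sample the returned rho matches the oracle
  pairs <- small_pairs(25, 4)
  expect_equal(spearman_gate(pairs),
               oracle_spearman(pairs$score_x, pairs$score_y),
               tolerance = 1e-12)
})

test_that("spearman gate is invariant under strictly monotone transforms", {
  pairs <- small_pairs(30, 6)
  rho <- spearman_gate(pairs)
  warped <- matched_pair_set(pairs$score_x^2 / 90, sqrt(pairs$score_y) * 10,
                             timepoint = pairs$timepoint)
  expect_equal(spearman_gate(warped), rho, tolerance = 1e-12)
  expect_error(spearman_gate(matched_pair_set(c(1, 2), c(3, 4))),
               "at least 3")
  expect_error(spearman_gate(matched_pair_set(rep(5, 5), 1:5)), "degenerate")
})

test_that("MAE matches hand computation and the stratum-weighting identity", {
  # identity crosswalk, CWD == PD everywhere -> MAE 0
  x <- c(10, 25, 40, 55, 70, 85)
  ident <- equipercentile_crosswalk(matched_pair_set(x, x))
  pairs0 <- matched_pair_set(x, apply_crosswalk(ident, x))
  expect_equal(crosswalk_mae(pairs0, ident)$mae_overall, 0)

  # two pairs with absolute errors 10 and 5 -> MAE 7.5
  tab <- hipcrosswalk:::lr_table_from_coef(1, 0, "mHHS", "HOOS")
  pairs2 <- matched_pair_set(c(40, 60), c(50, 65),
                             timepoint = c("preop", "3m"))
  m <- crosswalk_mae(pairs2, tab)
  expect_equal(m$mae_overall, 7.5)
  expect_equal(m$max_abs_difference, 10)
  expect_equal(m$max_abs_at_source_score, 40)
  expect_equal(unname(m$mae_by_timepoint[c("preop", "3m")]), c(10, 5))
  # empty strata flagged absent, not zero
  expect_true(all(is.na(m$mae_by_timepoint[c("6m", "12m")])))
  expect_equal(unname(m$n_by_timepoint), c(1L, 1L, 0L, 0L))

  # overall MAE is the count-weighted mean of the per-time-point MAEs
  pairs <- small_pairs(80, 9)
  mm <- crosswalk_mae(pairs, suppressWarnings(
    linear_regression_crosswalk(pairs)))
  keep <- !is.na(mm$mae_by_timepoint)
  expect_equal(mm$mae_overall,
               sum(mm$mae_by_timepoint[keep] * mm$n_by_timepoint[keep]) /
                 sum(mm$n_by_timepoint[keep]),
               tolerance = 1e-9)

  # orientation mismatch is rejected
  expect_error(crosswalk_mae(pairs2, tab, "y_to_x"), "does not match")
})

test_that("EQ crosswalk beats a constant predictor on its training pairs", {
  for (seed in c(12, 13, 14)) {
    pairs <- small_pairs(50, seed)
    tab <- equipercentile_crosswalk(pairs)
    mae <- crosswalk_mae(pairs, tab)$mae_overall
    const_mae <- mean(abs(mean(pairs$score_y) - pairs$score_y))
    expect_lte(mae, const_mae)
  }
})

test_that("subcategory MAE is zero for perfectly concordant responses and matches a brute-force recomputation", {
  # cohort where each visit answers every item of both questionnaires at
  # one shared severity level
  level_cohort <- function(lvls) {
    do.call(rbind, lapply(seq_along(lvls), function(i) {
      lv <- lvls[i]
      mh <- worst_mhhs()
      mh[] <- pmin(mh, lv)
      rbind(data.frame(patient_id = sprintf("P%02d", i), timepoint = "preop",
                       instrument = "mHHS", item_id = names(mh),
                       code = unname(mh)),
            data.frame(patient_id = sprintf("P%02d", i), timepoint = "preop",
                       instrument = "HOOS", item_id = hoos_items(),
                       code = lv))
    }))
  }
  resp <- level_cohort(c(0, 1, 2, 3, 4, 2))
  for (dir in c("mHHS_to_HOOS", "HOOS_to_mHHS")) {
    s <- subcategory_mae(resp, dir)
    # brute-force: score, equate, apply, average - via the test oracle
    sub <- hipcrosswalk:::subcategory_series(resp)
    for (sc in c("pain", "activity")) {
      m <- merge(sub[sub$instrument == "mHHS", c("patient_id", sc)],
                 sub[sub$instrument == "HOOS", c("patient_id", sc)],
                 by = "patient_id", suffixes = c("_m", "_h"))
      src <- if (dir == "mHHS_to_HOOS") m[[paste0(sc, "_m")]] else m[[paste0(sc, "_h")]]
      tgt <- if (dir == "mHHS_to_HOOS") m[[paste0(sc, "_h")]] else m[[paste0(sc, "_m")]]
      rx <- if (dir == "mHHS_to_HOOS") subcategory_range("mHHS", sc) else c(0, 100)
      ry <- if (dir == "mHHS_to_HOOS") c(0, 100) else subcategory_range("mHHS", sc)
      oracle <- oracle_eq_table(src, tgt, rx, ry)
      cwd <- approx(seq(rx[1], rx[2]), oracle, xout = src)$y
      expect_equal(unname(s[sc]), mean(abs(cwd - tgt)), tolerance = 1e-9)
    }
  }
  # identical rank and tie structure on both sides -> subcategory MAE 0:
  # equal percentile ranks force each observed source score onto exactly
  # its paired target score
  resp0 <- level_cohort(c(0, 1, 2, 0, 1, 2))
  for (dir in c("mHHS_to_HOOS", "HOOS_to_mHHS")) {
    s0 <- subcategory_mae(resp0, dir)
    expect_equal(as.numeric(s0), c(0, 0), tolerance = 1e-9)
  }
})

test_that("EQ and LR err similarly on a realistic synthetic cohort", {
  co <- generate_cohort(cohort_config(seed = 1, exact_counts = TRUE))
  pairs <- matched_pairs(score_responses(co$responses), "mHHS", "HOOS")
  expect_equal(nrow(pairs), 121)
  eq <- crosswalk_mae(pairs, equipercentile_crosswalk(pairs))$mae_overall
  lr <- crosswalk_mae(pairs, suppressWarnings(
    linear_regression_crosswalk(pairs)))$mae_overall
  # the two methods agree to within 25% relative difference
  expect_lt(abs(eq - lr) / max(eq, lr), 0.25)
})

test_that("correlation power analysis reproduces the published sample size", {
  expect_equal(required_sample_size(0.3, 0.05, 0.8, "one"), 67)
  expect_equal(required_sample_size(0.3, 0.05, 0.8, "two"), 85)
  # at the printed n the one-sided power just crosses 0.8
  expect_gte(hipcrosswalk:::correlation_power(67, 0.3, 0.05), 0.8)
  expect_lt(hipcrosswalk:::correlation_power(66, 0.3, 0.05), 0.8)
})

test_that("required sample size is monotone in its inputs", {
  for (sided in c("one", "two")) {
    n_by_r <- sapply(c(0.2, 0.3, 0.4, 0.6), function(r)
      required_sample_size(r, 0.05, 0.8, sided))
    expect_false(is.unsorted(rev(n_by_r)))          # non-increasing in r_min
    n_by_a <- sapply(c(0.01, 0.05, 0.1), function(a)
      required_sample_size(0.3, a, 0.8, sided))
    expect_false(is.unsorted(rev(n_by_a)))          # non-increasing in alpha
    n_by_p <- sapply(c(0.5, 0.8, 0.9, 0.95), function(p)
      required_sample_size(0.3, 0.05, p, sided))
    expect_false(is.unsorted(n_by_p))               # non-decreasing in power
  }
  # as target power collapses toward alpha, n collapses to the minimum
  expect_equal(required_sample_size(0.3, 0.05, 0.06), 4)
  expect_error(required_sample_size(1.2), "between 0 and 1")
  expect_error(required_sample_size(0), "between 0 and 1")
})
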