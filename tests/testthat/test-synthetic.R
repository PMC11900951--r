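# Synthetic THA-recovery cohort generator.

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_patients = 20, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cohort_config(n_patients = 20, seed = 42))
  expect_identical(a$responses, b$responses)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_config(n_patients = 20, seed = 43))
  expect_false(identical(a$responses, c2$responses))
})

test_that("exact-counts mode reproduces the 121 matched visits", {
  co <- generate_cohort(cohort_config(seed = 5, exact_counts = TRUE))
  counts <- table(co$truth$timepoint)[c("preop", "3m", "6m", "12m")]
  expect_equal(unname(c(counts)), c(35, 32, 30, 24))
  expect_equal(nrow(co$truth), 121)
  scores <- score_responses(co$responses)
  pairs <- matched_pairs(scores, "mHHS", "HOOS")
  expect_equal(nrow(pairs), 121)
  # matched visits carry both instruments or neither
  tab <- table(co$responses$patient_id, co$responses$timepoint,
               co$responses$instrument)
  expect_true(all((tab[, , "mHHS"] > 0) == (tab[, , "HOOS"] > 0)))
})

test_that("every emitted code is a defined option for its item", {
  co <- generate_cohort(cohort_config(n_patients = 15, seed = 3))
  for (instr in c("mHHS", "HOOS")) {
    def <- instrument_definition(instr)
    r <- co$responses[co$responses$instrument == instr, ]
    ok <- mapply(function(id, code)
      code %in% def$options$code[def$options$item_id == id],
      r$item_id, r$code)
    expect_true(all(ok))
  }
})

test_that("a noiseless cohort yields perfectly concordant totals", {
  cfg <- cohort_config(n_patients = 60, discordance_sd = 0,
                       item_noise_sd = 0, seed = 2)
  scores <- score_responses(generate_cohort(cfg)$responses)
  pairs <- matched_pairs(scores, "mHHS", "HOOS")
  # both totals are (weakly) monotone functions of one shared latent
  # trait: no pair of visits may be strictly discordant, and rank
  # correlation is perfect up to discretisation ties
  disc <- outer(pairs$score_x, pairs$score_x, "-") *
    outer(pairs$score_y, pairs$score_y, "-")
  expect_true(all(disc >= 0))
  expect_gt(cor(pairs$score_x, pairs$score_y, method = "spearman"), 0.95)
})

test_that("default cohort at 500 visits hits the configured correlation", {
  cfg <- cohort_config(n_patients = 125,
                       completion = c(preop = 1, `3m` = 1, `6m` = 1,
                                      `12m` = 1),
                       seed = 7)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth), 500)
  scores <- score_responses(co$responses)
  pairs <- matched_pairs(scores, "mHHS", "HOOS")
  rho <- cor(pairs$score_x, pairs$score_y, method = "spearman")
  expect_lt(abs(rho - cfg$target_spearman), 0.05)
  # recovery structure: 3-month scores more variable than pre-op, both
  # for the latent trait and the observed totals
  v_theta <- tapply(co$truth$theta, co$truth$timepoint, var)
  expect_gt(v_theta[["3m"]], v_theta[["preop"]])
  v_tot <- tapply(pairs$score_x, pairs$timepoint, var)
  expect_gt(v_tot[["3m"]], v_tot[["preop"]])
  # pre-op scores sit lowest on average (patients awaiting surgery)
  m_tot <- tapply(pairs$score_x, pairs$timepoint, mean)
  expect_true(all(m_tot[["preop"]] < m_tot[c("3m", "6m", "12m")]))
})

test_that("raising the latent trait never lowers either instrument's total", {
  set.seed(21)
  for (instr in c("mHHS", "HOOS")) {
    lay <- hipcrosswalk:::item_layout(instr)
    for (rep in 1:10) {
      eta <- runif(1, 0, 1)
      noise <- rnorm(length(lay), 0, 0.08)
      codes_at <- function(e) {
        v <- mapply(function(item_codes, nz)
          hipcrosswalk:::severity_to_code((1 - e) + nz, item_codes),
          lay, noise)
        stats::setNames(as.integer(v), names(lay))
      }
      lo <- codes_at(eta)
      hi <- codes_at(min(eta + 0.1, 1))
      total <- function(codes) {
        if (instr == "mHHS") score_mhhs(codes)$total
        else score_hoos_total(codes)$total
      }
      expect_gte(total(hi), total(lo))
    }
  }
})

test_that("large low-noise cohorts recover the latent linear slope", {
  cfg <- cohort_config(n_patients = 300,
                       completion = c(preop = 1, `3m` = 1, `6m` = 1,
                                      `12m` = 1),
                       discordance_sd = 0, item_noise_sd = 0.02, seed = 9)
  co <- generate_cohort(cfg)
  scores <- score_responses(co$responses)
  pairs <- matched_pairs(scores, "mHHS", "HOOS")
  expect_gte(nrow(pairs), 1000)
  tab <- linear_regression_crosswalk(pairs)
  # implied slope: regress the noise-free score maps evaluated on the
  # cohort's own latent traits
  lay <- list(mHHS = hipcrosswalk:::item_layout("mHHS"),
              HOOS = hipcrosswalk:::item_layout("HOOS"))
  noiseless_total <- function(instr, eta) {
    vapply(eta, function(e) {
      codes <- vapply(lay[[instr]], function(item_codes)
        as.integer(hipcrosswalk:::severity_to_code(1 - e, item_codes)),
        integer(1))
      if (instr == "mHHS") score_mhhs(codes)$total
      else score_hoos_total(codes)$total
    }, numeric(1))
  }
  x0 <- noiseless_total("mHHS", co$truth$theta)
  y0 <- noiseless_total("HOOS", co$truth$theta)
  implied <- unname(coef(lm(y0 ~ x0))[2])
  expect_lt(abs(tab$fit_meta$slope - implied) / implied, 0.05)
})

test_that("impossible and invalid configurations are rejected", {
  expect_error(cohort_config(target_spearman = 1),
               "impossible with positive discordance")
  expect_silent(cohort_config(target_spearman = 1, discordance_sd = 0,
                              item_noise_sd = 0))
  expect_error(cohort_config(n_patients = 1), "at least 2")
  expect_error(cohort_config(completion = c(preop = 1.2, `3m` = 1,
                                            `6m` = 1, `12m` = 1)),
               "\\[0, 1\\]")
  expect_error(cohort_config(discordance_sd = -0.1), "non-negative")
  expect_error(cohort_config(exact_counts = TRUE, n_patients = 10),
               "cannot exceed")
})

test_that("cohorts round-trip through CSV, truth kept out of the responses", {
  co <- generate_cohort(cohort_config(n_patients = 8, seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  truth_path <- withr::local_tempfile(fileext = ".csv")
  cohort_to_csv(co, path, truth_path)
  back <- read_responses(path)
  expect_equal(back, co$responses)
  expect_false("theta" %in% names(back))
  expect_true("theta" %in% names(read.csv(truth_path)))
  # empty cohort -> header-only file
  empty <- generate_cohort(cohort_config(
    n_patients = 2, seed = 1,
    completion = c(preop = 0, `3m` = 0, `6m` = 0, `12m` = 0)))
  path2 <- withr::local_tempfile(fileext = ".csv")
  cohort_to_csv(empty, path2)
  expect_equal(length(readLines(path2)), 1L)
  expect_equal(nrow(read_responses(path2)), 0L)
})
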