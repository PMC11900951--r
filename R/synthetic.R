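# Synthetic THA-recovery cohort: matched mHHS/HOOS item responses with the
# statistical structure the crosswalk analysis assumes.

#' Configure a synthetic recovery cohort
#'
#' The generator emulates a primary total-hip-arthroplasty cohort completing
#' both the mHHS and the HOOS pre-operatively and at 3, 6 and 12 months.
#' Each patient-visit carries a latent health trait on a 0–1 scale (0 worst):
#' `theta = trait_mean + shift[t] + patient effect + visit noise`, with the
#' pre-op mean low (patients in pain) and per-time-point spread largest at 3
#' months, when some patients have recovered and others have not.  Each
#' instrument observes the trait through its own lens — a shared trait plus
#' an instrument-specific discordance deviation — and every item discretises
#' `1 - trait` through equal-width thresholds jittered by per-item noise.
#' Defaults emulate 49 patients with completion rates giving 35/32/30/24
#' matched visits (121 pairs) and a total-score Spearman correlation near
#' the configured 0.9 target.
#'
#' @param n_patients Number of patients (>= 2).
#' @param completion Named per-timepoint completion probabilities.
#' @param trait_mean Pre-op mean of the latent trait (0–1 scale).
#' @param patient_sd Between-patient sd of the persistent trait component.
#' @param recovery_shift Named per-timepoint additive recovery of the trait.
#' @param timepoint_sd Named per-timepoint sd of the visit-level trait noise.
#' @param discordance_sd Sd of the instrument-specific latent deviation
#'   (drives disagreement between the two questionnaires on the same day).
#' @param item_noise_sd Sd of the per-item jitter on the discretisation.
#' @param target_spearman Correlation between instrument totals the defaults
#'   are calibrated to; used to validate the configuration (a target of 1
#'   is impossible with any positive discordance or item noise).
#' @param seed Integer seed; identical configuration + seed reproduce the
#'   cohort byte-for-byte.
#' @param exact_counts If `TRUE`, ignore `completion` probabilities and draw
#'   exactly `timepoint_counts` completed visits per time point.
#' @param timepoint_counts Named per-timepoint visit counts for
#'   `exact_counts` mode (defaults 35/32/30/24).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 49L,
                          completion = c(preop = 35, `3m` = 32,
                                         `6m` = 30, `12m` = 24) / 49,
                          trait_mean = 0.35,
                          patient_sd = 0.06,
                          recovery_shift = c(preop = 0, `3m` = 0.20,
                                             `6m` = 0.33, `12m` = 0.40),
                          timepoint_sd = c(preop = 0.10, `3m` = 0.17,
                                           `6m` = 0.14, `12m` = 0.13),
                          discordance_sd = 0.06,
                          item_noise_sd = 0.08,
                          target_spearman = 0.9,
                          seed = 1L,
                          exact_counts = FALSE,
                          timepoint_counts = c(preop = 35, `3m` = 32,
                                               `6m` = 30, `12m` = 24)) {
  if (n_patients < 2) stop_("n_patients must be at least 2")
  for (nm in c("completion", "recovery_shift", "timepoint_sd",
               "timepoint_counts")) {
    v <- get(nm)
    if (!all(TIMEPOINTS %in% names(v)))
      stop_("%s must be named over %s", nm, paste(TIMEPOINTS, collapse = ", "))
  }
  if (any(completion < 0 | completion > 1))
    stop_("completion probabilities must lie in [0, 1]")
  if (any(c(patient_sd, timepoint_sd, discordance_sd, item_noise_sd) < 0))
    stop_("standard deviations must be non-negative")
  if (target_spearman <= 0 || target_spearman > 1)
    stop_("target_spearman must lie in (0, 1]")
  if (target_spearman == 1 && (discordance_sd > 0 || item_noise_sd > 0))
    stop_("target_spearman = 1 is impossible with positive discordance or item noise: the two instruments would have to agree exactly")
  if (exact_counts && any(timepoint_counts > n_patients))
    stop_("timepoint_counts cannot exceed n_patients")
  structure(list(n_patients = as.integer(n_patients),
                 completion = completion[TIMEPOINTS],
                 trait_mean = trait_mean, patient_sd = patient_sd,
                 recovery_shift = recovery_shift[TIMEPOINTS],
                 timepoint_sd = timepoint_sd[TIMEPOINTS],
                 discordance_sd = discordance_sd,
                 item_noise_sd = item_noise_sd,
                 target_spearman = target_spearman,
                 seed = as.integer(seed),
                 exact_counts = isTRUE(exact_counts),
                 timepoint_counts = timepoint_counts[TIMEPOINTS]),
            class = "cohort_config")
}

# Per-instrument item layout: ids and each item's option codes ordered
# best -> worst.  mHHS points are goodness weights (order by decreasing
# points); HOOS points are severity codes (order by ascending code).
# Only retained items are generated.
item_layout <- function(instrument) {
  def <- instrument_definition(instrument)
  ids <- def$items$item_id[def$items$retained]
  lapply(stats::setNames(ids, ids), function(id) {
    opt <- def$options[def$options$item_id == id, ]
    if (instrument == "mHHS") opt$code[order(-opt$points, opt$code)]
    else opt$code[order(opt$code)]
  })
}

# Deterministic discretisation: severity (1 - latent trait, plus jitter)
# through equal-width thresholds onto an item's options, best -> worst.
severity_to_code <- function(severity, codes_best_to_worst) {
  k <- length(codes_best_to_worst)
  codes_best_to_worst[clamp(floor(severity * k), 0, k - 1) + 1]
}

#' Generate a synthetic matched-PROM cohort
#'
#' Draws the latent recovery trajectories and emits long-format item
#' responses for both instruments at every completed visit (a visit has
#' both questionnaires or neither).  The generating latent traits are kept
#' as a ground-truth sidecar for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `responses`
#'   (long-format data frame `patient_id,timepoint,instrument,item_id,code`),
#'   `truth` (per visit: latent trait and each instrument's latent view)
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))
  b <- stats::rnorm(n, 0, config$patient_sd)
  layouts <- list(mHHS = item_layout("mHHS"), HOOS = item_layout("HOOS"))
  resp <- list(); truth <- list()
  for (tp in TIMEPOINTS) {
    done <- if (config$exact_counts) {
      seq_len(n) %in% sample(n, config$timepoint_counts[[tp]])
    } else {
      stats::runif(n) < config$completion[[tp]]
    }
    idx <- which(done)
    if (!length(idx)) next
    theta <- config$trait_mean + config$recovery_shift[[tp]] + b[idx] +
      stats::rnorm(length(idx), 0, config$timepoint_sd[[tp]])
    eta <- list()
    for (instr in names(layouts)) {
      eta[[instr]] <- theta + stats::rnorm(length(idx), 0,
                                           config$discordance_sd)
      lay <- layouts[[instr]]
      for (item in names(lay)) {
        sev <- (1 - eta[[instr]]) +
          stats::rnorm(length(idx), 0, config$item_noise_sd)
        code <- severity_to_code(sev, lay[[item]])
        resp[[length(resp) + 1L]] <- data.frame(
          patient_id = pid[idx], timepoint = tp, instrument = instr,
          item_id = item, code = code, stringsAsFactors = FALSE)
      }
    }
    truth[[length(truth) + 1L]] <- data.frame(
      patient_id = pid[idx], timepoint = tp, theta = theta,
      eta_mhhs = eta$mHHS, eta_hoos = eta$HOOS, stringsAsFactors = FALSE)
  }
  responses <- if (length(resp)) do.call(rbind, resp) else
    data.frame(patient_id = character(), timepoint = character(),
               instrument = character(), item_id = character(),
               code = integer(), stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient_id = character(), timepoint = character(),
               theta = numeric(), eta_mhhs = numeric(),
               eta_hoos = numeric(), stringsAsFactors = FALSE)
  ord <- order(responses$patient_id, match(responses$timepoint, TIMEPOINTS),
               responses$instrument, responses$item_id)
  responses <- responses[ord, , drop = FALSE]
  rownames(responses) <- NULL
  truth <- truth[order(truth$patient_id,
                       match(truth$timepoint, TIMEPOINTS)), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(responses = responses, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d completed visits, %d response rows (seed %d)\n",
              x$config$n_patients, nrow(x$truth), nrow(x$responses),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to CSV
#'
#' The response table round-trips losslessly through [read_responses()];
#' the latent ground truth, if requested, goes to a separate sidecar file
#' and never into the main response CSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Response CSV path.
#' @param truth_path Optional ground-truth sidecar CSV path.
#' @export
cohort_to_csv <- function(cohort, path, truth_path = NULL) {
  utils::write.csv(cohort$responses, path, row.names = FALSE, na = "")
  if (!is.null(truth_path))
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(path)
}
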