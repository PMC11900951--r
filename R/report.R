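# Full validation report: the error-table layout (rows Overall / Pre-OP /
# 3 / 6 / 12 Months, columns the four crosswalk directions) for each
# equating method, plus the pain/activity subcategory section.

DIRECTIONS <- c("mHHS_to_HOOS", "HOOS_to_mHHS",
                "mHHS_to_HOOS-12", "HOOS-12_to_mHHS")

#' Build the full crosswalk validation report
#'
#' Scores a long-format response table, gates each instrument pairing on
#' the Spearman threshold, builds every requested crosswalk
#' (method x direction), and evaluates the MAE of CWD against PD scores
#' overall and per time point, plus the EQ-only pain/activity subcategory
#' errors.
#'
#' @param responses Long-format item responses (both instruments), as read
#'   by [read_responses()].
#' @param methods Equating methods to validate (`"EQ"`, `"LR"`).
#' @param threshold Spearman gate threshold.
#' @return Object of class `validation_report`: list with
#'   * `totals` — data frame `method`, `direction`, `stratum`, `n`, `mae`;
#'   * `subcategories` — data frame `direction`, `subcategory`, `n`, `mae`;
#'   * `spearman` — named rho per instrument pairing;
#'   * `largest` — data frame of each crosswalk's largest |CWD - PD| and
#'     the source score where it occurs.
#' @export
validation_report <- function(responses, methods = c("EQ", "LR"),
                              threshold = 0.3) {
  methods <- match.arg(methods, several.ok = TRUE)
  scores <- score_responses(responses)
  spearman <- c()
  totals <- list(); largest <- list()
  for (other in c("HOOS", "HOOS-12")) {
    pairs <- matched_pairs(scores, "mHHS", other)
    rho <- spearman_gate(pairs, threshold)
    spearman[paste0("mHHS~", other)] <- rho
    for (direction in c("x_to_y", "y_to_x")) {
      lab <- if (direction == "x_to_y") paste0("mHHS_to_", other)
             else paste0(other, "_to_mHHS")
      for (method in methods) {
        tab <- if (method == "EQ") equipercentile_crosswalk(pairs, direction)
               else linear_regression_crosswalk(pairs, direction)
        m <- crosswalk_mae(pairs, tab, direction)
        totals[[paste(method, lab)]] <- data.frame(
          method = method, direction = lab,
          stratum = c("Overall", unname(TIMEPOINT_LABELS)),
          n = c(m$n_overall, unname(m$n_by_timepoint)),
          mae = c(m$mae_overall, unname(m$mae_by_timepoint)),
          stringsAsFactors = FALSE)
        largest[[paste(method, lab)]] <- data.frame(
          method = method, direction = lab,
          max_abs_difference = m$max_abs_difference,
          at_source_score = m$max_abs_at_source_score,
          stringsAsFactors = FALSE)
      }
    }
  }
  subcat <- do.call(rbind, lapply(DIRECTIONS, function(d) {
    s <- subcategory_mae(responses, d)
    data.frame(direction = d, subcategory = names(s),
               n = unname(attr(s, "n")), mae = unname(s),
               stringsAsFactors = FALSE)
  }))
  structure(list(totals = do.call(rbind, c(totals, make.row.names = FALSE)),
                 subcategories = subcat,
                 spearman = spearman,
                 largest = do.call(rbind, c(largest, make.row.names = FALSE))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("Spearman rho:",
      paste(sprintf("%s = %.3f", names(x$spearman), x$spearman),
            collapse = ", "), "\n")
  for (method in unique(x$totals$method)) {
    cat(sprintf("\nMAE (%s method):\n", method))
    print(report_wide(x$totals[x$totals$method == method, ],
                      "stratum", "direction", "mae"))
  }
  cat("\nSubcategory MAE (EQ method):\n")
  print(report_wide(x$subcategories, "subcategory", "direction", "mae"))
  invisible(x)
}

# long -> wide with one row per `row_var`, one column per direction
report_wide <- function(df, row_var, col_var, val_var) {
  rows <- unique(df[[row_var]]); cols <- unique(df[[col_var]])
  out <- data.frame(row = rows, stringsAsFactors = FALSE)
  names(out) <- row_var
  for (cc in cols)
    out[[cc]] <- round(df[[val_var]][match(
      paste(rows, cc), paste(df[[row_var]], df[[col_var]]))], 1)
  out
}

#' Write a validation report
#'
#' `path` receives a CSV mirroring the published error-table layout (one
#' block per method, rows Overall / Pre-OP / 3 / 6 / 12 Months, columns the
#' four directions, `NA` for an absent stratum; then the subcategory
#' block).  `log_path`, if given, receives a structured plain-text log with
#' Spearman coefficients, pair counts and largest differences.
#'
#' @param report A `validation_report`.
#' @param path Output CSV path.
#' @param log_path Optional plain-text log path.
#' @export
write_validation_report <- function(report, path, log_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# crosswalk validation report", con)
  for (method in unique(report$totals$method)) {
    writeLines(sprintf("# MAE, %s method", method), con)
    wide <- report_wide(report$totals[report$totals$method == method, ],
                        "stratum", "direction", "mae")
    utils::write.table(wide, con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  writeLines("# subcategory MAE, EQ method", con)
  wide <- report_wide(report$subcategories, "subcategory", "direction", "mae")
  utils::write.table(wide, con, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(log_path)) {
    lines <- c("crosswalk validation log",
               sprintf("spearman %s = %.4f", names(report$spearman),
                       report$spearman),
               sprintf("largest |CWD - PD| %s %s: %.2f at source score %g",
                       report$largest$method, report$largest$direction,
                       report$largest$max_abs_difference,
                       report$largest$at_source_score))
    writeLines(lines, log_path)
  }
  invisible(path)
}
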