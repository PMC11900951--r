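# Shared helpers.

TIMEPOINTS <- c("preop", "3m", "6m", "12m")
TIMEPOINT_LABELS <- c(preop = "Pre-OP", `3m` = "3 Months",
                      `6m` = "6 Months", `12m` = "12 Months")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round half away from zero (presentation / table export only; internal
# arithmetic stays on exact values)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_timepoints <- function(tp) {
  bad <- setdiff(unique(as.character(tp)), TIMEPOINTS)
  if (length(bad))
    stop_("unknown timepoint label(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(TIMEPOINTS, collapse = ", "))
  invisible(TRUE)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "hipcrosswalk")
  if (!nzchar(path)) stop_("bundled data file not found: %s", file)
  path
}
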