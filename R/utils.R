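# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup left_join n
#' @importFrom stats qt sd setNames coef vcov
NULL

# Abort with a condition class so the plate pipeline can catch per-well
# failures without string matching.
stop_mbr <- function(message, class, ...) {
  abort(message, class = c(class, "mbrfit_error"), ...)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Validate a raw well table: strictly increasing time, numeric backscatter,
# equal lengths, at least 4 cycles.
check_raw_well <- function(data, arg = "data") {
  if (!is.data.frame(data)) {
    stop_mbr(sprintf("`%s` must be a data frame of raw well readings.", arg),
             "mbrfit_bad_input")
  }
  for (col in c("time_h", "backscatter")) {
    if (!col %in% names(data)) {
      stop_mbr(sprintf("`%s` must have a `%s` column.", arg, col),
               "mbrfit_bad_input")
    }
  }
  t <- data$time_h
  if (anyNA(t) || anyNA(data$backscatter)) {
    stop_mbr("raw well readings contain missing values", "mbrfit_bad_input")
  }
  if (nrow(data) < 4L) {
    stop_mbr("a raw well needs at least 4 measurement cycles", "mbrfit_bad_input")
  }
  if (any(diff(t) <= 0)) {
    stop_mbr("`time_h` must be strictly increasing", "mbrfit_bad_input")
  }
  invisible(data)
}

# Validate a blanked curve table (time_h, value, error).
check_blanked_curve <- function(data, arg = "data") {
  if (!is.data.frame(data) ||
      !all(c("time_h", "value", "error") %in% names(data))) {
    stop_mbr(sprintf(
      "`%s` must be a blanked curve with columns time_h, value, error (see apply_blank()).",
      arg), "mbrfit_bad_input")
  }
  invisible(data)
}
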