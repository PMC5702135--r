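#' Read a multi-well plate table
#'
#' Supported dialects:
#' \describe{
#'   \item{`wide_csv`}{header row; first column `time_h` (configurable),
#'     remaining columns one per well id; decimal point `"."`.}
#'   \item{`biolector_xlsx`}{spreadsheet export with one sheet per channel,
#'     rows = measurement cycles, columns = wells, plus a time column.
#'     Configure with `config = list(sheet=, time_column=, wells=, time_unit=)`.}
#'   \item{`biolector_csv`}{the same sheet layout saved as CSV.}
#' }
#' Time is normalised to hours on ingestion (`config$time_unit`: `"h"`
#' default, `"min"`, or `"s"`), since growth rates are reported in 1/h.
#' Unparseable readings truncate the affected well at the first bad row,
#' with a warning; wells are stored independently, no interpolation.
#'
#' @param path Path to the plate file.
#' @param dialect One of `"wide_csv"`, `"biolector_xlsx"`, `"biolector_csv"`.
#' @param config Named list of dialect options: `time_column` (default
#'   `"time_h"` for wide CSV, `"time"` otherwise), `time_unit`, `sheet`
#'   (xlsx only), `wells` (optional character vector restricting the well
#'   columns).
#' @return A long tibble of class `mbr_plate` with columns `well_id`,
#'   `time_h`, `backscatter`.
#' @export
read_plate_table <- function(path,
                             dialect = c("wide_csv", "biolector_xlsx",
                                         "biolector_csv"),
                             config = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_mbr(sprintf("plate file not found: %s", path), "mbrfit_io")
  }
  time_col <- config$time_column %||%
    if (dialect == "wide_csv") "time_h" else "time"
  raw <- switch(dialect,
    wide_csv = ,
    biolector_csv = readr::read_csv(path, show_col_types = FALSE,
                                    progress = FALSE),
    biolector_xlsx = readxl::read_excel(path, sheet = config$sheet %||% 1L))
  if (!time_col %in% names(raw)) {
    stop_mbr(sprintf("missing time column `%s` in %s", time_col, path),
             "mbrfit_io")
  }
  wells <- setdiff(names(raw), time_col)
  if (!is.null(config$wells)) wells <- intersect(wells, config$wells)
  if (length(wells) == 0L) {
    stop_mbr("no well columns found", "mbrfit_io")
  }
  if (anyDuplicated(wells)) {
    stop_mbr("duplicate well ids in header", "mbrfit_io")
  }
  if (nrow(raw) < 4L) {
    stop_mbr("plate table has fewer than 4 measurement cycles", "mbrfit_io")
  }
  unit <- config$time_unit %||% "h"
  div <- switch(unit, h = 1, min = 60, s = 3600,
                stop_mbr("time_unit must be h, min or s", "mbrfit_bad_input"))
  time_h <- suppressWarnings(as.numeric(raw[[time_col]])) / div
  if (anyNA(time_h)) {
    stop_mbr("unparseable values in the time column", "mbrfit_io")
  }
  long <- purrr::map(wells, function(wid) {
    v <- suppressWarnings(as.numeric(raw[[wid]]))
    bad <- which(!is.finite(v))
    keep <- length(v)
    if (length(bad) > 0L) {
      keep <- bad[1L] - 1L
      warn(sprintf("well %s: unparseable value at row %d; well truncated to %d cycles",
                   wid, bad[1L], keep))
    }
    tibble(well_id = wid, time_h = time_h[seq_len(keep)],
           backscatter = v[seq_len(keep)])
  })
  plate <- bind_rows(long)
  class(plate) <- c("mbr_plate", class(plate))
  plate
}

#' Write a plate as a wide CSV
#'
#' Writes the same wide-CSV dialect that [read_plate_table()] consumes
#' (column `time_h` plus one column per well), so simulated plates round-trip
#' through the reader.
#'
#' @param plate An `mbr_plate` long tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  wide <- tidyr::pivot_wider(plate, id_cols = "time_h",
                             names_from = "well_id",
                             values_from = "backscatter")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a well-to-strain mapping
#'
#' @param path CSV with columns `well_id`, `strain` (and optionally
#'   `replicate`).
#' @return A tibble with those columns.
#' @export
read_groups <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("well_id", "strain") %in% names(g))) {
    stop_mbr("groups file needs columns well_id, strain", "mbrfit_io")
  }
  g
}

#' Process every well of a plate
#'
#' Runs blank estimation, blanking, LOQ detection and exponential-phase
#' detection independently for each well. Failures are isolated per well:
#' a well whose signal never exceeds the LOQ is reported with status
#' `no_growth`, a well where no window satisfies the stopping criteria with
#' `no_exponential_phase`; the remaining wells are unaffected. Results are
#' identical regardless of well processing order (the output is sorted by
#' `well_id` and nothing in the computation is order- or state-dependent).
#'
#' @param plate An `mbr_plate` (see [read_plate_table()] /
#'   [simulate_plate()]).
#' @param loq Limit of quantification, a.u. If `NULL`, defaults per well to
#'   `10 * sigma` (ten times the estimated measurement error) and a note is
#'   emitted — the LOQ is meant to be a deliberate user choice.
#' @param r2_min Adjusted R-squared acceptance threshold (default 0.99).
#' @param blank_policy,blank_cycles Passed to [estimate_blank()].
#' @param groups Optional tibble (`well_id`, `strain`) attaching strain
#'   labels; defaults to the plate's `groups` attribute if present.
#' @param nlr Also run the non-linear cross-check per converged well.
#' @return A tibble with one row per well: `well_id`, `strain`, `status`
#'   (`ok` / `no_growth` / `no_exponential_phase`), `mu`, `ci_low`,
#'   `ci_high`, `adj_r2`, `n_points`, `window_start_h`, `window_end_h`,
#'   `iterations`, `blank`, `sigma`, `propagated_error`, `loq` (and
#'   `mu_nlr`, `ci_low_nlr`, `ci_high_nlr` when `nlr = TRUE`).
#' @export
process_plate <- function(plate, loq = NULL, r2_min = 0.99,
                          blank_policy = c("fixed", "adaptive"),
                          blank_cycles = 5L, groups = NULL, nlr = FALSE) {
  blank_policy <- match.arg(blank_policy)
  if (!is.data.frame(plate) ||
      !all(c("well_id", "time_h", "backscatter") %in% names(plate))) {
    stop_mbr("`plate` must have columns well_id, time_h, backscatter",
             "mbrfit_bad_input")
  }
  groups <- groups %||% attr(plate, "groups", exact = TRUE)
  if (is.null(loq)) {
    inform("no LOQ supplied: defaulting to 10 * sigma per well")
  }
  ids <- sort(unique(plate$well_id))
  rows <- purrr::map(ids, function(wid) {
    raw <- plate[plate$well_id == wid, c("time_h", "backscatter")]
    process_well(raw, wid, loq = loq, r2_min = r2_min,
                 blank_policy = blank_policy, blank_cycles = blank_cycles,
                 nlr = nlr)
  })
  res <- bind_rows(rows)
  if (!is.null(groups)) {
    res <- left_join(res, groups[, c("well_id", "strain")], by = "well_id")
  } else {
    res$strain <- NA_character_
  }
  nlr_cols <- intersect(c("mu_nlr", "ci_low_nlr", "ci_high_nlr"), names(res))
  res[, c("well_id", "strain", "status", "mu", "ci_low", "ci_high", "adj_r2",
          "n_points", "window_start_h", "window_end_h", "iterations",
          "blank", "sigma", "propagated_error", "loq", nlr_cols)]
}

process_well <- function(raw, wid, loq, r2_min, blank_policy, blank_cycles,
                         nlr = FALSE) {
  bs <- estimate_blank(raw, policy = blank_policy, n_blank = blank_cycles)
  curve <- apply_blank(raw, bs)
  well_loq <- loq %||% (10 * bs$sigma)
  base <- tibble(well_id = wid, status = NA_character_,
                 mu = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 adj_r2 = NA_real_, n_points = NA_integer_,
                 window_start_h = NA_real_, window_end_h = NA_real_,
                 iterations = NA_integer_,
                 blank = bs$blank, sigma = bs$sigma,
                 propagated_error = curve$error[1L], loq = well_loq)
  det <- tryCatch(
    detect_growth(curve, loq = well_loq, r2_min = r2_min, nlr = nlr),
    mbrfit_no_growth = function(cnd) NULL)
  if (is.null(det)) {
    base$status <- "no_growth"
    return(base)
  }
  g <- glance(det)
  base$status <- if (det$converged) "ok" else "no_exponential_phase"
  base$mu <- g$mu; base$ci_low <- g$ci_low; base$ci_high <- g$ci_high
  base$adj_r2 <- g$adj_r2; base$n_points <- g$n_points
  base$window_start_h <- g$window_start_h; base$window_end_h <- g$window_end_h
  base$iterations <- g$iterations
  if (nlr) {
    if (!is.null(det$fit_nlr)) {
      base$mu_nlr <- det$fit_nlr$mu
      base$ci_low_nlr <- det$fit_nlr$ci95[1]
      base$ci_high_nlr <- det$fit_nlr$ci95[2]
    } else {
      base$mu_nlr <- NA_real_
      base$ci_low_nlr <- NA_real_
      base$ci_high_nlr <- NA_real_
    }
  }
  base
}

#' Aggregate replicate growth rates per strain
#'
#' The replicate growth rates of each strain are combined by their
#' arithmetic mean; per-replicate confidence intervals are kept in the
#' per-well results, not pooled. Rounding to two decimals happens only in
#' the presentation column `mu_mean_2dp`.
#'
#' @param results Per-well results from [process_plate()].
#' @param reference Optional tibble (`strain`, `mu_lit`) of reference growth
#'   rates; when given, the percent deviation
#'   `|1 - mu_mean / mu_lit| * 100` is added (see [deviation_percent()]).
#' @return A tibble with one row per strain: `strain`, `n_replicates`,
#'   `mu_mean`, `mu_sd`, `mu_mean_2dp`, `status` (`ok` or
#'   `no_ok_replicates`), and `dev_pct` when a reference is supplied.
#' @export
aggregate_replicates <- function(results, reference = NULL) {
  if (!all(c("strain", "status", "mu") %in% names(results))) {
    stop_mbr("`results` must come from process_plate()", "mbrfit_bad_input")
  }
  out <- results |>
    group_by(.data$strain) |>
    summarise(
      n_replicates = sum(.data$status == "ok"),
      mu_mean = if (any(.data$status == "ok"))
        mean(.data$mu[.data$status == "ok"]) else NA_real_,
      mu_sd = if (sum(.data$status == "ok") > 1L)
        sd(.data$mu[.data$status == "ok"]) else NA_real_,
      .groups = "drop") |>
    mutate(mu_mean_2dp = round(.data$mu_mean, 2),
           status = ifelse(.data$n_replicates > 0L, "ok", "no_ok_replicates"))
  if (!is.null(reference)) {
    if (!all(c("strain", "mu_lit") %in% names(reference))) {
      stop_mbr("`reference` needs columns strain, mu_lit", "mbrfit_bad_input")
    }
    out <- left_join(out, reference[, c("strain", "mu_lit")], by = "strain")
    out$dev_pct <- ifelse(is.na(out$mu_lit), NA_real_,
                          deviation_percent(out$mu_mean, out$mu_lit))
  }
  arrange(out, .data$strain)
}

#' Percent deviation of an automated growth rate from a reference value
#'
#' \deqn{Dev[\%] = |1 - \mu_{auto} / \mu_{ref}| \cdot 100}
#'
#' @param mu_auto Automatically determined growth rate(s), 1/h.
#' @param mu_ref Reference (e.g. literature) growth rate(s), 1/h; must be
#'   positive.
#' @return Percent deviation, same length as the inputs.
#' @examples
#' deviation_percent(0.30, 0.32)  # 6.25
#' @export
deviation_percent <- function(mu_auto, mu_ref) {
  if (any(!is.finite(mu_ref)) || any(mu_ref <= 0)) {
    stop_mbr("`mu_ref` must be positive", "mbrfit_bad_input")
  }
  abs(1 - mu_auto / mu_ref) * 100
}

#' Write per-well results and per-strain summaries to CSV
#'
#' Fixed column order, numeric columns at 6 significant digits. The results
#' file always includes non-converged wells (their status documents why no
#' rate is reported); the summary file keeps its header even when empty.
#'
#' @param results Per-well results from [process_plate()].
#' @param summaries Per-strain summaries from [aggregate_replicates()], or
#'   `NULL` to skip.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`results.csv`, `summary.csv`).
#' @export
write_results <- function(results, summaries = NULL, dir = ".") {
  if (nrow(results) == 0L) {
    stop_mbr("`results` is empty", "mbrfit_bad_input")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    df |> mutate(dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  }
  paths <- file.path(dir, c("results.csv", "summary.csv"))
  readr::write_csv(fmt(results), paths[1], progress = FALSE, na = "")
  if (is.null(summaries)) {
    summaries <- tibble(strain = character(), n_replicates = integer(),
                        mu_mean = double(), mu_sd = double(),
                        mu_mean_2dp = double(), status = character())
  }
  readr::write_csv(fmt(summaries), paths[2], progress = FALSE, na = "")
  invisible(paths)
}
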