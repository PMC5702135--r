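#' Estimate the blank value and additive measurement error of a well
#'
#' Backscatter readings recorded before any detectable growth scatter around a
#' constant offset (the blank). The blank is the mean of these pre-growth
#' readings and the per-reading measurement error is their sample standard
#' deviation; the error is treated as additive and constant for all readings
#' of the well.
#'
#' Two policies select the pre-growth readings:
#' \describe{
#'   \item{`"fixed"`}{the first `n_blank` cycles (default 5). Reproducible and
#'     appropriate for the usual pre-growth plateau at 9-min cycle times.}
#'   \item{`"adaptive"`}{seeds blank and sigma from the first `n_blank`
#'     cycles, then extends the prefix while the next reading stays within
#'     `blank +/- 3 * sigma` of that seed estimate (i.e. below the limit of
#'     detection), so all pre-growth cycles contribute; blank and sigma are
#'     recomputed from the full accepted prefix.}
#' }
#'
#' @param data A raw well table with columns `time_h` and `backscatter`.
#' @param policy `"fixed"` or `"adaptive"` (see Details).
#' @param n_blank Number of leading cycles used (fixed policy) or used to seed
#'   the running estimate (adaptive policy). Must be at least 2.
#' @return A one-row tibble with columns `blank` (a.u.), `sigma` (per-reading
#'   additive error, a.u.), `n_pre` (cycles used) and `lod`
#'   (`blank + 3 * sigma`, the limit of detection, reported for diagnostics).
#' @examples
#' raw <- tibble::tibble(time_h = 0:9 / 4,
#'                       backscatter = c(9, 11, 10, 10, 10, 12, 16, 24, 40, 70))
#' estimate_blank(raw)
#' @export
estimate_blank <- function(data, policy = c("fixed", "adaptive"), n_blank = 5L) {
  check_raw_well(data)
  policy <- match.arg(policy)
  bs <- data$backscatter
  n_blank <- as.integer(n_blank)
  if (!is_number(n_blank) || n_blank < 2L) {
    stop_mbr("`n_blank` must be an integer >= 2", "mbrfit_bad_input")
  }
  if (length(bs) < n_blank) {
    stop_mbr("insufficient blank window: fewer pre-growth cycles than `n_blank`",
             "mbrfit_blank_window")
  }
  k <- n_blank
  if (policy == "adaptive") {
    # Fixed detection band from the seed prefix: extending against a running
    # band would let the blank estimate chase a slowly rising signal.
    m0 <- mean(bs[seq_len(k)])
    s0 <- sd(bs[seq_len(k)])
    in_band <- function(x) if (s0 == 0) x == m0 else abs(x - m0) <= 3 * s0
    while (k < length(bs)) {
      nxt <- bs[k + 1L]
      if (!in_band(nxt)) {
        # growth is persistent, noise spikes are not: stop only when the
        # next reading is also outside the detection band
        if (k + 2L > length(bs) || !in_band(bs[k + 2L])) break
      }
      k <- k + 1L
    }
  }
  pre <- bs[seq_len(k)]
  blank <- mean(pre)
  sigma <- sd(pre)
  tibble(blank = blank, sigma = sigma, n_pre = k, lod = blank + 3 * sigma)
}

#' Blank a raw backscatter curve and propagate the measurement error
#'
#' Subtracts the blank from every reading and attaches the propagated
#' per-point error
#' \deqn{\delta = \sqrt{\sigma^2 + \sigma^2 / n_{pre}},}
#' i.e. the per-reading error plus the uncertainty of the subtracted blank
#' mean. Under the additive-error model the propagated error is a single
#' constant replicated for every point. Negative blanked values are permitted;
#' points below the limit of quantification are excluded later.
#'
#' @param data A raw well table with columns `time_h` and `backscatter`.
#' @param blank_stats A one-row data frame with columns `blank`, `sigma` and
#'   `n_pre`, as returned by [estimate_blank()]; if `NULL`, the blank is
#'   estimated from `data` with the given policy.
#' @inheritParams estimate_blank
#' @return A tibble with columns `time_h`, `value` (blanked backscatter,
#'   a.u.) and `error` (propagated per-point error, a.u.).
#' @seealso [estimate_blank()], [find_loq_crossing()]
#' @export
apply_blank <- function(data, blank_stats = NULL,
                        policy = c("fixed", "adaptive"), n_blank = 5L) {
  check_raw_well(data)
  if (is.null(blank_stats)) {
    blank_stats <- estimate_blank(data, policy = policy, n_blank = n_blank)
  }
  if (!all(c("blank", "sigma", "n_pre") %in% names(blank_stats))) {
    stop_mbr("`blank_stats` needs columns blank, sigma, n_pre", "mbrfit_bad_input")
  }
  sigma <- blank_stats$sigma[1L]
  n_pre <- blank_stats$n_pre[1L]
  delta <- sqrt(sigma^2 + sigma^2 / n_pre)
  tibble(time_h = data$time_h,
         value = data$backscatter - blank_stats$blank[1L],
         error = rep(delta, nrow(data)))
}

#' Locate the first cycle exceeding the limit of quantification
#'
#' Returns the index of the first blanked reading strictly greater than the
#' user-defined limit of quantification (LOQ). All phase detection operates on
#' cycles at or after this index.
#'
#' @param data A blanked curve (columns `time_h`, `value`, `error`), as
#'   returned by [apply_blank()].
#' @param loq Limit of quantification, a.u.; must be positive.
#' @return The integer cycle index of the crossing.
#'   If no reading ever exceeds `loq`, an error of class
#'   `mbrfit_no_growth` is signalled ("no quantifiable growth"); the plate
#'   pipeline catches it and reports the well as a non-grower.
#' @export
find_loq_crossing <- function(data, loq) {
  check_blanked_curve(data)
  if (!is_number(loq) || loq <= 0) {
    stop_mbr("`loq` must be a positive number", "mbrfit_bad_input")
  }
  idx <- which(data$value > loq)
  if (length(idx) == 0L) {
    stop_mbr("no quantifiable growth: backscatter never exceeds the LOQ",
             "mbrfit_no_growth")
  }
  idx[1L]
}

#' Log-transform a blanked curve window for weighted regression
#'
#' Natural-log transforms the blanked biomass signal and propagates the
#' additive error through the transformation: for a value \eqn{c} with error
#' \eqn{\delta}, the transformed error is \eqn{\bar\delta = \delta / c} and
#' the regression weight is \eqn{w = \bar\delta^{-2} = (c/\delta)^2}. Larger
#' (later-exponential) readings therefore carry quadratically more weight.
#'
#' When the propagated error is exactly zero (noise-free data) all weights
#' are set to 1; the weighted fit then reduces to ordinary least squares.
#'
#' @inheritParams find_loq_crossing
#' @param window Optional integer index range (e.g. `5:40`) selecting the
#'   cycles to transform; defaults to the whole curve. Every selected value
#'   must be strictly positive — a non-positive value inside the window
#'   signals a windowing bug upstream, not a user error.
#' @return A tibble with columns `time_h`, `y` (`log(value)`), and `w`
#'   (regression weight).
#' @export
log_transform <- function(data, window = NULL) {
  check_blanked_curve(data)
  if (is.null(window)) window <- seq_len(nrow(data))
  v <- data$value[window]
  e <- data$error[window]
  if (any(v <= 0)) {
    stop_mbr("log of non-positive biomass inside the fitting window",
             "mbrfit_window_bug")
  }
  w <- if (all(e == 0)) rep(1, length(v)) else (v / e)^2
  tibble(time_h = data$time_h[window], y = log(v), w = w)
}
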