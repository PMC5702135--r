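#' Evaluate the three stopping criteria for exponential-phase acceptance
#'
#' For the current window of blanked (linear-scale) backscatter values `v`
#' with last-cycle increase `d_last = v[end] - v[end-1]` and previous
#' increase `d_prev = v[end-1] - v[end-2]`:
#' \describe{
#'   \item{c1}{the adjusted R-squared of the weighted log-linear fit exceeds
#'     `r2_min` (strictly greater).}
#'   \item{c2}{the last biomass increase is strictly higher than the previous
#'     one (`d_last > d_prev`) — on exponential data increases accelerate, on
#'     stationary data they do not, so a high R-squared alone is not enough
#'     at high temporal resolution.}
#'   \item{c3}{both increases are non-negative — negative dips are a known
#'     measurement artifact at the transition into stationary phase.}
#' }
#' The window is accepted when all three hold. Increases are computed on the
#' blanked linear-scale signal, not on the log scale.
#'
#' @param values Blanked backscatter values of the current window (>= 4).
#' @param fit The `mbr_fit` of the current window (for its adjusted R-squared).
#' @param r2_min Adjusted R-squared threshold, in (0, 1); 0.99 by default.
#' @return A named logical vector `c(c1, c2, c3)`.
#' @export
stopping_criteria <- function(values, fit, r2_min = 0.99) {
  m <- length(values)
  if (m < 4L) {
    stop_mbr("criteria need a window of at least 4 points", "mbrfit_short_window")
  }
  d_last <- values[m] - values[m - 1L]
  d_prev <- values[m - 1L] - values[m - 2L]
  c(c1 = fit$adj_r2 > r2_min,
    c2 = d_last > d_prev,
    c3 = d_last >= 0 && d_prev >= 0)
}

#' Detect the exponential growth phase and estimate the growth rate
#'
#' Implements the iterative trailing-point removal procedure. The first
#' evaluated window runs from the first cycle whose blanked backscatter
#' exceeds the limit of quantification (LOQ) to the final measurement
#' (typically in stationary phase). Each iteration log-transforms the window,
#' fits a weighted linear regression and evaluates the three
#' [stopping criteria][stopping_criteria]; if any fails, the last measurement
#' is dropped and the next iteration evaluates the shortened window. The
#' procedure stops at the first window satisfying all criteria, or gives up
#' when fewer than `min_points` cycles remain.
#'
#' @param data A blanked curve (columns `time_h`, `value`, `error`), see
#'   [apply_blank()].
#' @param loq Limit of quantification, a.u. (> 0).
#' @param r2_min Adjusted R-squared acceptance threshold (default 0.99).
#' @param min_points Smallest admissible window (default 4: the regression
#'   needs 3 points and the two trailing increases must lie inside the
#'   window).
#' @param nlr Also run the non-linear exponential cross-check on the accepted
#'   window, seeded by the linear fit (default `FALSE`).
#' @return An object of class `mbr_detection`: list with `fit` (`mbr_fit`,
#'   WLR), `fit_nlr` (if requested and converged), `start_index`,
#'   `end_index`, `iterations`, `converged`, and `trace` — a tibble with one
#'   row per iteration recording the window end, adjusted R-squared, the two
#'   trailing increases and the three criteria. If no window satisfies the
#'   criteria, `converged` is `FALSE` and `fit` holds the last evaluated fit;
#'   the condition is reported, not fatal, so plate runs continue. A curve
#'   that never exceeds the LOQ signals `mbrfit_no_growth` (see
#'   [find_loq_crossing()]).
#' @examples
#' curve <- simulate_curve(curve_spec(noise_sd = 0, seed = 1))
#' blanked <- apply_blank(curve)
#' det <- detect_growth(blanked, loq = 1)
#' glance(det)
#' @export
detect_growth <- function(data, loq, r2_min = 0.99, min_points = 4L,
                          nlr = FALSE) {
  check_blanked_curve(data)
  if (!is_number(r2_min) || r2_min <= 0 || r2_min >= 1) {
    stop_mbr("`r2_min` must lie in (0, 1)", "mbrfit_bad_input")
  }
  start <- find_loq_crossing(data, loq)
  n <- nrow(data)
  e <- n
  trace <- vector("list", max(0L, e - start + 1L))
  it <- 0L
  fit <- NULL
  converged <- FALSE
  while (e - start + 1L >= min_points) {
    window <- start:e
    lt <- log_transform(data, window)
    # a constant-signal window has an undefined R^2: count it as a criteria
    # failure (it is certainly not exponential growth), don't abort the well
    this_fit <- tryCatch(fit_wlr(lt), mbrfit_degenerate = function(cnd) NULL)
    v <- data$value[window]
    m <- length(v)
    it <- it + 1L
    if (is.null(this_fit)) {
      crit <- c(c1 = FALSE, c2 = FALSE, c3 = FALSE)
      r2 <- NA_real_
    } else {
      fit <- this_fit
      crit <- stopping_criteria(v, fit, r2_min)
      r2 <- fit$adj_r2
    }
    trace[[it]] <- tibble(
      iteration = it, end_index = e, n_points = m, adj_r2 = r2,
      d_last = v[m] - v[m - 1L], d_prev = v[m - 1L] - v[m - 2L],
      c1 = crit[["c1"]], c2 = crit[["c2"]], c3 = crit[["c3"]])
    if (all(crit)) { converged <- TRUE; break }
    e <- e - 1L
  }
  if (!converged) {
    # e was decremented past the evaluated range; report the last window tried
    e <- if (it > 0L) trace[[it]]$end_index else NA_integer_
  }
  out <- structure(
    list(fit = fit, fit_nlr = NULL, start_index = start, end_index = e,
         iterations = if (is.na(e)) 0L else n - e,  # trailing removals
         converged = converged,
         trace = bind_rows(trace[seq_len(it)]),
         loq = loq, r2_min = r2_min, data = as_tibble(data)),
    class = "mbr_detection")
  if (nlr && converged) {
    out$fit_nlr <- tryCatch(
      fit_nlr(data[start:e, , drop = FALSE], init = fit),
      mbrfit_nlr_failure = function(cnd) {
        warn(conditionMessage(cnd))
        NULL
      })
  }
  out
}

#' @export
print.mbr_detection <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<mbr_detection> converged after %d trailing-point removals\n", x$iterations))
    cat(sprintf("  window: cycles %d-%d (%.2f-%.2f h), %d points\n",
                x$start_index, x$end_index,
                x$data$time_h[x$start_index], x$data$time_h[x$end_index],
                x$end_index - x$start_index + 1L))
    print(x$fit)
    if (!is.null(x$fit_nlr)) print(x$fit_nlr)
  } else {
    cat("<mbr_detection> no exponential phase found (not converged)\n")
  }
  invisible(x)
}

#' Tidy the iteration trace of an exponential-phase detection
#'
#' @param x An `mbr_detection`.
#' @param ... Unused.
#' @return The per-iteration criteria trace as a tibble (columns `iteration`,
#'   `end_index`, `n_points`, `adj_r2`, `d_last`, `d_prev`, `c1`, `c2`, `c3`).
#' @export
tidy.mbr_detection <- function(x, ...) x$trace

#' One-row summary of an exponential-phase detection
#'
#' @inheritParams tidy.mbr_detection
#' @return A one-row tibble: `mu`, `ci_low`, `ci_high`, `adj_r2`, `n_points`,
#'   `window_start_h`, `window_end_h`, `iterations`, `converged`.
#' @export
glance.mbr_detection <- function(x, ...) {
  tibble(
    mu = if (is.null(x$fit)) NA_real_ else x$fit$mu,
    ci_low = if (is.null(x$fit)) NA_real_ else x$fit$ci95[1],
    ci_high = if (is.null(x$fit)) NA_real_ else x$fit$ci95[2],
    adj_r2 = if (is.null(x$fit)) NA_real_ else x$fit$adj_r2,
    n_points = if (is.na(x$end_index)) NA_integer_
               else x$end_index - x$start_index + 1L,
    window_start_h = x$data$time_h[x$start_index],
    window_end_h = if (is.na(x$end_index)) NA_real_ else x$data$time_h[x$end_index],
    iterations = x$iterations,
    converged = x$converged)
}
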