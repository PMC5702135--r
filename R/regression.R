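#' Weighted linear regression of log-biomass on time
#'
#' Fits `y = a + mu * t` by weighted least squares using the closed-form
#' weighted normal equations. With `y = log(blanked backscatter)` and weights
#' from [log_transform()], the slope is the specific growth rate
#' \eqn{\mu = \Delta \log(c_X) / \Delta t} in 1/h.
#'
#' The slope standard error comes from the weighted residual variance with
#' `n - 2` degrees of freedom and the 95% confidence interval uses the
#' Student-t quantile on that standard error. The reported coefficient of
#' determination is the weighted, adjusted R-squared (see [adjusted_r2()]).
#'
#' @param data A data frame with the fitting window; columns `time_h`, `y`
#'   and `w` as produced by [log_transform()].
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return An object of class `mbr_fit`: a list with elements `mu`,
#'   `intercept`, `mu_se`, `ci95` (length-2 numeric), `adj_r2`, `n`,
#'   `method = "WLR"` and `fitted`. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] for tabular views.
#' @examples
#' d <- tibble::tibble(time_h = 0:5, y = 0.2 + 0.46 * (0:5), w = 1)
#' glance(fit_wlr(d))
#' @export
fit_wlr <- function(data, conf_level = 0.95) {
  t <- data$time_h; y <- data$y; w <- data$w
  n <- length(t)
  if (n < 3L || length(y) != n || length(w) != n) {
    stop_mbr("window too short: weighted regression needs >= 3 points",
             "mbrfit_short_window")
  }
  if (any(w <= 0) || anyNA(w)) {
    stop_mbr("all regression weights must be positive", "mbrfit_bad_input")
  }
  sw  <- sum(w)
  tbar <- sum(w * t) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (t - tbar)^2)
  if (sxx == 0) {
    stop_mbr("degenerate time vector: all time stamps equal",
             "mbrfit_degenerate")
  }
  mu <- sum(w * (t - tbar) * (y - ybar)) / sxx
  a  <- ybar - mu * tbar
  fitted <- a + mu * t
  # weighted residual variance on n - 2 dof; weights treated as relative
  s2 <- sum(w * (y - fitted)^2) / (n - 2L)
  mu_se <- sqrt(s2 / sxx)
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 2L)
  structure(
    list(mu = mu, intercept = a, mu_se = mu_se,
         ci95 = c(mu - tq * mu_se, mu + tq * mu_se),
         adj_r2 = adjusted_r2(y, fitted, w),
         n = n, method = "WLR", df = n - 2L, conf_level = conf_level,
         fitted = fitted, data = tibble(time_h = t, y = y, w = w)),
    class = "mbr_fit")
}

#' Weighted adjusted coefficient of determination
#'
#' \eqn{R^2_w = 1 - SSE_w / SST_w} with weighted sums of squares about the
#' weighted mean, adjusted for model size:
#' \eqn{R^2_{adj} = 1 - (1 - R^2_w)(n - 1)/(n - p)}. At equal weights this
#' reduces to the ordinary adjusted R-squared.
#'
#' @param y Observed values.
#' @param yhat Fitted values.
#' @param w Positive weights (default all 1).
#' @param p Number of fitted coefficients (2 for slope + intercept).
#' @return The adjusted weighted R-squared (scalar, at most 1).
#' @export
adjusted_r2 <- function(y, yhat, w = rep(1, length(y)), p = 2L) {
  n <- length(y)
  if (length(yhat) != n || length(w) != n || n < 3L) {
    stop_mbr("`y`, `yhat`, `w` must share a length of at least 3",
             "mbrfit_bad_input")
  }
  ybar <- sum(w * y) / sum(w)
  sst <- sum(w * (y - ybar)^2)
  if (sst == 0) {
    stop_mbr("undefined R-squared: response is constant", "mbrfit_degenerate")
  }
  r2 <- 1 - sum(w * (y - yhat)^2) / sst
  1 - (1 - r2) * (n - 1L) / (n - p)
}

#' Non-linear exponential regression of blanked biomass on time
#'
#' Fits the untransformed exponential growth model
#' \eqn{c(t) = c_0 e^{\mu t}} by iteratively (weighted) minimising
#' \eqn{\sum (c_i - c_0 e^{\mu t_i})^2 / \delta_i^2}. Non-linear regression
#' needs a starting point; the natural one is the weighted linear fit of the
#' log-transformed data, passed as `init`. Convergence requires the relative
#' change in the objective/parameters to drop below 1e-12 within 500
#' iterations (Levenberg-Marquardt, via \pkg{minpack.lm}).
#'
#' @param data A blanked curve window: columns `time_h`, `value`, `error`.
#' @param init An `mbr_fit` from [fit_wlr()] supplying the initial guess
#'   (`mu`, and `c0 = exp(intercept)`).
#' @param weighted Weight residuals by `1/error^2` (default `TRUE`,
#'   consistent with the additive-error model); ignored when all errors are
#'   zero.
#' @inheritParams fit_wlr
#' @return An `mbr_fit` with `method = "NLR"` and the fitted initial biomass
#'   `c0`; confidence interval from the local curvature with `n - 2` degrees
#'   of freedom. On non-convergence an error of class `mbrfit_nlr_failure`
#'   carries the initial WLR fit in its `init` field.
#' @export
fit_nlr <- function(data, init, weighted = TRUE, conf_level = 0.95) {
  check_blanked_curve(data)
  if (!inherits(init, "mbr_fit")) {
    stop_mbr("`init` must be an `mbr_fit` from fit_wlr()", "mbrfit_bad_input")
  }
  t <- data$time_h; v <- data$value; e <- data$error
  n <- length(t)
  if (any(v <= 0)) {
    stop_mbr("non-positive blanked biomass in NLR window", "mbrfit_window_bug")
  }
  w <- if (!weighted || all(e == 0)) rep(1, n) else 1 / e^2
  start <- list(c0 = exp(init$intercept), mu = init$mu)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ c0 * exp(mu * t),
      start = start, weights = w,
      control = minpack.lm::nls.lm.control(
        maxiter = 500L, ftol = 1e-12, ptol = 1e-12)),
    error = function(cnd) {
      stop_mbr(paste0("NLR failed to converge: ", conditionMessage(cnd)),
               "mbrfit_nlr_failure", init = init)
    })
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 2L)
  fitted <- est[["c0"]] * exp(est[["mu"]] * t)
  structure(
    list(mu = est[["mu"]], intercept = log(est[["c0"]]), c0 = est[["c0"]],
         mu_se = se[["mu"]],
         ci95 = c(est[["mu"]] - tq * se[["mu"]], est[["mu"]] + tq * se[["mu"]]),
         adj_r2 = adjusted_r2(v, fitted, w),
         n = n, method = "NLR", df = n - 2L, conf_level = conf_level,
         fitted = fitted, data = tibble(time_h = t, value = v, error = e)),
    class = "mbr_fit")
}

#' @export
print.mbr_fit <- function(x, ...) {
  cat(sprintf("<mbr_fit %s>  mu = %.4f 1/h  (95%% CI %.4f-%.4f)  adj R2 = %.4f  n = %d\n",
              x$method, x$mu, x$ci95[1], x$ci95[2], x$adj_r2, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a growth-rate fit
#'
#' @param x An `mbr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.mbr_fit <- function(x, ...) {
  out <- tibble(
    term = c("mu", "intercept"),
    estimate = c(x$mu, x$intercept),
    std.error = c(x$mu_se, NA_real_),
    conf.low = c(x$ci95[1], NA_real_),
    conf.high = c(x$ci95[2], NA_real_))
  if (identical(x$method, "NLR")) {
    out <- bind_rows(out, tibble(term = "c0", estimate = x$c0,
                                 std.error = NA_real_,
                                 conf.low = NA_real_, conf.high = NA_real_))
  }
  out
}

#' Glance at a growth-rate fit
#'
#' @inheritParams tidy.mbr_fit
#' @return A one-row tibble: `mu`, `mu_se`, `ci_low`, `ci_high`, `adj_r2`,
#'   `n`, `method`.
#' @export
glance.mbr_fit <- function(x, ...) {
  tibble(mu = x$mu, mu_se = x$mu_se, ci_low = x$ci95[1], ci_high = x$ci95[2],
         adj_r2 = x$adj_r2, n = x$n, method = x$method)
}
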