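#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_rect
#'   labs theme_bw scale_y_log10 annotate facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot an exponential-phase detection
#'
#' Blanked backscatter versus time with the accepted exponential window
#' shaded and the fitted exponential overlaid. With `log = TRUE` the y axis
#' is logarithmic, so the accepted phase appears as a straight line.
#'
#' @param object An `mbr_detection` from [detect_growth()].
#' @param log Use a log10 y axis (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbr_detection <- function(object, log = FALSE, ...) {
  d <- object$data
  p <- ggplot(d, aes(x = .data$time_h, y = .data$value)) +
    geom_point(size = 0.6, colour = "grey40") +
    labs(x = "time [h]", y = "blanked backscatter [a.u.]",
         title = if (object$converged)
           sprintf("mu = %.3f 1/h (95%% CI %.3f-%.3f)",
                   object$fit$mu, object$fit$ci95[1], object$fit$ci95[2])
         else "no exponential phase found") +
    theme_bw()
  if (object$converged) {
    win <- d[object$start_index:object$end_index, ]
    fit_line <- tibble(
      time_h = win$time_h,
      value = exp(object$fit$intercept + object$fit$mu * win$time_h))
    p <- p +
      annotate("rect", xmin = min(win$time_h), xmax = max(win$time_h),
               ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
      geom_line(data = fit_line, colour = "firebrick")
  }
  if (log) p <- p + scale_y_log10()
  p
}

#' Plot all wells of a plate
#'
#' Raw backscatter time series, one facet per well.
#'
#' @param object An `mbr_plate`.
#' @param ncol Facet columns (default 8, one microtiter-plate row per line).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbr_plate <- function(object, ncol = 8, ...) {
  ggplot(object, aes(x = .data$time_h, y = .data$backscatter)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~well_id, ncol = ncol) +
    labs(x = "time [h]", y = "backscatter [a.u.]") +
    theme_bw()
}

#' Write per-well diagnostic plots
#'
#' One PNG per converged well: the detection plot of [autoplot.mbr_detection].
#'
#' @param plate An `mbr_plate`.
#' @param results Per-well results from [process_plate()].
#' @param dir Output directory for the PNG files.
#' @param loq,r2_min,blank_cycles Parameters matching the processing run.
#' @return Invisibly, the written file paths.
#' @export
write_diagnostic_plots <- function(plate, results, dir,
                                   loq = NULL, r2_min = 0.99,
                                   blank_cycles = 5L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- results$well_id[results$status == "ok"]
  paths <- purrr::map_chr(ok, function(wid) {
    raw <- plate[plate$well_id == wid, c("time_h", "backscatter")]
    curve <- apply_blank(raw, n_blank = blank_cycles)
    det <- detect_growth(curve,
                         loq = loq %||% results$loq[results$well_id == wid][1],
                         r2_min = r2_min)
    f <- file.path(dir, paste0(wid, ".png"))
    ggplot2::ggsave(f, autoplot(det), width = 5, height = 3.5, dpi = 120)
    f
  })
  invisible(paths)
}
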