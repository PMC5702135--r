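#' Specify a synthetic microbioreactor growth curve
#'
#' Describes the latent (noise-free) backscatter trajectory of one well and
#' its additive Gaussian measurement noise. The latent signal above blank is
#' \deqn{x(t) = 0 \textrm{ for } t < t_{lag};\quad
#'       c_0 e^{\mu_1 (t - t_{lag})} \textrm{ for } t_{lag} \le t \le t_{end,1},}
#' capped at `plateau`. Before `t_lag` the culture is below the limit of
#' detection, so its backscatter contribution is part of the operational
#' blank and the signal above blank is zero; observable growth starts at
#' amplitude `c0` (about the noise scale, so the onset is seamless). When `mu2` is given, a second retarded (diauxic)
#' phase continues exponentially from the phase-1 endpoint at rate `mu2`,
#' again capped at `plateau`; otherwise the signal stays at the phase-1
#' endpoint (stationary). Observed backscatter is
#' `blank_level + x(t) + N(0, noise_sd^2)`, sampled every `cycle_min`
#' minutes.
#'
#' Defaults emulate a C. glutamicum batch cultivation in a 48-well
#' microbioreactor: 9-min measurement cycle over 30 h (201 cycles), blank
#' around 40 a.u., additive noise of 0.4 a.u., growth at 0.46 1/h between a
#' 15 h lag and substrate depletion at 24 h. Use
#' `curve_spec_ecoli()` for a diauxic E. coli-like preset (0.61 1/h first
#' phase to 7 h, retarded second phase to 15 h).
#'
#' @param blank_level Blank (offset) signal, a.u.
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise, a.u. (>= 0).
#' @param c0 Initial biomass signal above blank, a.u. (> 0).
#' @param mu1 First-phase specific growth rate, 1/h (> 0).
#' @param t_lag Lag-phase end, h.
#' @param t_phase1_end End of the first exponential phase, h.
#' @param mu2 Optional second-phase (diauxic) growth rate, 1/h; must be
#'   smaller than `mu1`. `NULL` for single-phase growth.
#' @param t_phase2_end End of the second phase, h (only used with `mu2`).
#' @param plateau Maximum blanked signal, a.u.
#' @param cycle_min Measurement cycle time, minutes.
#' @param t_total Total cultivation time, h.
#' @param stationary `"hard"` (signal holds its endpoint value exactly) or
#'   `"smooth"` (exponential approach to the plateau, as real curves round
#'   off at the transition).
#' @param seed Integer seed making the curve reproducible.
#' @return A `curve_spec` object (validated list).
#' @export
curve_spec <- function(blank_level = 40, noise_sd = 0.4, c0 = 0.5,
                       mu1 = 0.46, t_lag = 15, t_phase1_end = 24,
                       mu2 = NULL, t_phase2_end = NULL, plateau = 40,
                       cycle_min = 9, t_total = 30,
                       stationary = c("hard", "smooth"), seed = 1L) {
  spec <- list(blank_level = blank_level, noise_sd = noise_sd, c0 = c0,
               mu1 = mu1, t_lag = t_lag, t_phase1_end = t_phase1_end,
               mu2 = mu2, t_phase2_end = t_phase2_end, plateau = plateau,
               cycle_min = cycle_min, t_total = t_total,
               stationary = match.arg(stationary), seed = as.integer(seed))
  validate_curve_spec(spec)
  structure(spec, class = "curve_spec")
}

#' @rdname curve_spec
#' @param ... Overrides passed on to [curve_spec()].
#' @export
curve_spec_ecoli <- function(...) {
  defaults <- list(blank_level = 40, noise_sd = 0.32, c0 = 0.8, mu1 = 0.61,
                   t_lag = 1, t_phase1_end = 7, mu2 = 0.1, t_phase2_end = 15,
                   plateau = 70, cycle_min = 9, t_total = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(curve_spec, args)
}

validate_curve_spec <- function(spec) {
  ok <- is_number(spec$mu1) && spec$mu1 > 0 &&
    is_number(spec$noise_sd) && spec$noise_sd >= 0 &&
    is_number(spec$c0) && spec$c0 > 0 &&
    is_number(spec$t_lag) && is_number(spec$t_phase1_end) &&
    is_number(spec$t_total) &&
    spec$t_lag < spec$t_phase1_end && spec$t_phase1_end < spec$t_total &&
    is_number(spec$plateau) && spec$plateau > 0 &&
    is_number(spec$cycle_min) && spec$cycle_min > 0
  if (ok && !is.null(spec$mu2)) {
    ok <- is_number(spec$mu2) && spec$mu2 < spec$mu1 &&
      is_number(spec$t_phase2_end %||% NA) &&
      spec$t_phase2_end > spec$t_phase1_end
  }
  if (!ok) {
    stop_mbr("invalid curve specification (check rates, times and noise)",
             "mbrfit_bad_spec")
  }
  invisible(spec)
}

latent_signal <- function(spec, t) {
  # Before t_lag the culture is below the limit of detection: its (tiny)
  # backscatter contribution is part of the operational blank, so the latent
  # signal above blank is 0. Observable growth starts at amplitude c0.
  x <- rep(0, length(t))
  grow <- t >= spec$t_lag & t <= spec$t_phase1_end
  x[grow] <- spec$c0 * exp(spec$mu1 * (t[grow] - spec$t_lag))
  x1_end <- min(spec$c0 * exp(spec$mu1 * (spec$t_phase1_end - spec$t_lag)),
                spec$plateau)
  after1 <- t > spec$t_phase1_end
  if (!is.null(spec$mu2)) {
    ph2 <- after1 & t <= spec$t_phase2_end
    x[ph2] <- x1_end * exp(spec$mu2 * (t[ph2] - spec$t_phase1_end))
    x2_end <- min(x1_end * exp(spec$mu2 * (spec$t_phase2_end - spec$t_phase1_end)),
                  spec$plateau)
    tail <- t > spec$t_phase2_end
    x[tail] <- x2_end
    t_station <- spec$t_phase2_end
    x_station <- x2_end
  } else {
    x[after1] <- x1_end
    t_station <- spec$t_phase1_end
    x_station <- x1_end
  }
  x <- pmin(x, spec$plateau)
  if (spec$stationary == "smooth") {
    # round the hard stop off: exponential approach towards the plateau
    tail <- t > t_station
    x[tail] <- x_station +
      (spec$plateau - x_station) * (1 - exp(-spec$mu1 * (t[tail] - t_station)))
  }
  x
}

#' Simulate one well's backscatter time series with known ground truth
#'
#' @param spec A [curve_spec()].
#' @param well_id Well label attached to the curve.
#' @return A tibble (class `mbr_curve`) with columns `time_h` and
#'   `backscatter`, carrying attributes `spec` (the generating spec) and
#'   `truth` — a tibble of the per-cycle latent noise-free signal and phase
#'   label (`lag`, `exponential`, `second_phase`, `stationary`). Retrieve it
#'   with [curve_truth()]. Identical specs (same seed) give identical
#'   curves.
#' @examples
#' curve <- simulate_curve(curve_spec(seed = 42))
#' head(curve_truth(curve))
#' @export
simulate_curve <- function(spec, well_id = "A01") {
  validate_curve_spec(spec)
  t <- seq(0, spec$t_total, by = spec$cycle_min / 60)
  x <- latent_signal(spec, t)
  eps <- local_rng(spec$seed, stats::rnorm(length(t), 0, spec$noise_sd))
  phase <- rep("stationary", length(t))
  phase[t < spec$t_lag] <- "lag"
  phase[t >= spec$t_lag & t <= spec$t_phase1_end] <- "exponential"
  if (!is.null(spec$mu2)) {
    phase[t > spec$t_phase1_end & t <= spec$t_phase2_end] <- "second_phase"
  }
  out <- tibble(time_h = t, backscatter = spec$blank_level + x + eps)
  attr(out, "spec") <- spec
  attr(out, "truth") <- tibble(time_h = t, latent = x, phase = phase)
  attr(out, "well_id") <- well_id
  class(out) <- c("mbr_curve", class(out))
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ground truth of a simulated curve
#'
#' @param curve An `mbr_curve` from [simulate_curve()].
#' @return The per-cycle latent-signal tibble attached at simulation time.
#' @export
curve_truth <- function(curve) {
  truth <- attr(curve, "truth", exact = TRUE)
  if (is.null(truth)) {
    stop_mbr("`curve` carries no ground truth (not a simulated curve?)",
             "mbrfit_bad_input")
  }
  truth
}

#' Simulate a whole multi-well plate with known ground truth
#'
#' Generates `n_wells` independent wells. Wells are assigned to replicate
#' groups round-robin over `specs`; per-well seeds are derived
#' deterministically from `seed`, so the same call always produces the same
#' plate. Optionally appends non-grower wells (blank medium: noise around
#' the blank level, no growth).
#'
#' @param n_wells Number of growing wells (>= 1).
#' @param specs A single [curve_spec()] or a named list of specs, one per
#'   replicate group (names become strain labels).
#' @param seed Master seed for the plate.
#' @param n_blank_wells Number of additional blank-medium (non-growing)
#'   wells, strain label `"blank"`.
#' @return A list with elements `plate` — a long tibble (class `mbr_plate`)
#'   with columns `well_id`, `time_h`, `backscatter` and a `groups`
#'   attribute mapping `well_id` to `strain` — and `truth`, a tibble with
#'   one row per well (`well_id`, `strain`, `mu_true`, `t_lag`,
#'   `t_phase1_end`, `seed`) joining 1:1 with plate results on `well_id`.
#' @examples
#' sim <- simulate_plate(6, curve_spec(), seed = 7)
#' dplyr::count(sim$plate, well_id)
#' @export
simulate_plate <- function(n_wells = 48L, specs = curve_spec(), seed = 1L,
                           n_blank_wells = 0L) {
  if (!is_number(n_wells) || n_wells < 1L) {
    stop_mbr("`n_wells` must be >= 1", "mbrfit_bad_input")
  }
  if (inherits(specs, "curve_spec")) specs <- list(strain_A = specs)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- paste0("strain_", LETTERS[seq_along(specs)])
  }
  total <- n_wells + n_blank_wells
  ids <- well_ids(total)
  rows <- vector("list", total)
  truth <- vector("list", total)
  for (i in seq_len(total)) {
    wseed <- derive_seed(seed, i)
    if (i <= n_wells) {
      g <- ((i - 1L) %% length(specs)) + 1L
      spec <- specs[[g]]
      spec$seed <- wseed
      cur <- simulate_curve(spec, well_id = ids[i])
      strain <- names(specs)[g]
      mu_true <- spec$mu1
      t_lag <- spec$t_lag; t1 <- spec$t_phase1_end
    } else {
      ref <- specs[[1L]]
      t <- seq(0, ref$t_total, by = ref$cycle_min / 60)
      eps <- local_rng(wseed, stats::rnorm(length(t), 0, ref$noise_sd))
      cur <- tibble(time_h = t, backscatter = ref$blank_level + eps)
      strain <- "blank"
      mu_true <- NA_real_
      t_lag <- NA_real_; t1 <- NA_real_
    }
    rows[[i]] <- tibble(well_id = ids[i], time_h = cur$time_h,
                        backscatter = cur$backscatter)
    truth[[i]] <- tibble(well_id = ids[i], strain = strain, mu_true = mu_true,
                         t_lag = t_lag, t_phase1_end = t1, seed = wseed)
  }
  truth <- bind_rows(truth)
  plate <- bind_rows(rows)
  attr(plate, "groups") <- truth[, c("well_id", "strain")]
  class(plate) <- c("mbr_plate", class(plate))
  list(plate = plate, truth = truth)
}

# Deterministic per-well seed below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483587L)
}

# "A01" ... "F08" style ids for up to 48 wells, beyond that zero-padded.
well_ids <- function(n) {
  if (n <= 48L) {
    grid <- expand.grid(col = 1:8, row = LETTERS[1:6])
    sprintf("%s%02d", grid$row, grid$col)[seq_len(n)]
  } else {
    sprintf("W%03d", seq_len(n))
  }
}
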