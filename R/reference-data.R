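#' Published growth rates of a genome-reduced C. glutamicum strain panel
#'
#' Reference dataset for benchmarking automated growth-rate determination:
#' 23 genome-reduced *Corynebacterium glutamicum* strains (derived from the
#' wildtype ATCC13032 or the lysine producer DM1933) with the manually
#' evaluated growth rate from the original strain characterisations
#' (`mu_lit`, mean and standard deviation) next to the rate obtained by the
#' automated exponential-phase detection on the same microbioreactor raw
#' data (`mu_auto`, with its 95% confidence interval). The wildtype was
#' cultivated in duplicate with both runs yielding 0.46 1/h; it appears
#' once.
#'
#' Comparing the two columns with [deviation_percent()] shows that for 13 of
#' the 23 strains the automated rate deviates from the manual reference by
#' at most 10%.
#'
#' @return A tibble with columns `strain`, `mu_lit`, `mu_lit_sd`, `mu_auto`,
#'   `ci_low`, `ci_high` (all rates in 1/h, values as printed, two
#'   decimals).
#' @examples
#' panel <- cglutamicum_panel()
#' sum(deviation_percent(panel$mu_auto, panel$mu_lit) <= 10)
#' @export
cglutamicum_panel <- function() {
  tibble::tribble(
    ~strain,          ~mu_lit, ~mu_lit_sd, ~mu_auto, ~ci_low, ~ci_high,
    "DM1933",            0.32,       0.01,     0.30,    0.29,     0.30,
    "DM1933 dCGP1",      0.30,       0.03,     0.30,    0.29,     0.31,
    "DM1933 dCGP2",      0.31,       0.03,     0.32,    0.31,     0.32,
    "DM1933 dCGP3",      0.31,       0.02,     0.32,    0.31,     0.32,
    "DM1933 dCGP123",    0.33,       0.03,     0.33,    0.32,     0.34,
    "GRLP16",            0.31,       0.02,     0.35,    0.34,     0.35,
    "GRLP23",            0.33,       0.02,     0.31,    0.30,     0.32,
    "GRLP41",            0.31,       0.01,     0.29,    0.28,     0.30,
    "GRLP42",            0.36,       0.06,     0.30,    0.29,     0.31,
    "GRLP46",            0.30,       0.04,     0.32,    0.32,     0.33,
    "GRS37",             0.45,       0.03,     0.51,    0.51,     0.52,
    "GRS40",             0.44,       0.03,     0.50,    0.49,     0.51,
    "GRS41",             0.41,       0.04,     0.47,    0.46,     0.47,
    "GRS42",             0.39,       0.01,     0.47,    0.46,     0.48,
    "GRS46",             0.43,       0.03,     0.50,    0.49,     0.50,
    "GRS45",             0.31,       0.02,     0.34,    0.34,     0.34,
    "GRS47",             0.41,       0.03,     0.48,    0.47,     0.49,
    "GRS48",             0.45,       0.01,     0.49,    0.49,     0.50,
    "GRS53",             0.44,       0.03,     0.47,    0.47,     0.48,
    "MB001",             0.43,       0.04,     0.48,    0.47,     0.48,
    "GRS16",             0.44,       0.03,     0.49,    0.48,     0.50,
    "GRS23",             0.46,       0.02,     0.47,    0.47,     0.48,
    "WT",                0.43,       0.04,     0.46,    0.45,     0.46)
}
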