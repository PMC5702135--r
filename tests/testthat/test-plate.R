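test_that("wide CSV round-trips through writer and reader", {
  sim <- simulate_plate(3, curve_spec(t_total = 14.85, t_lag = 5,
                                      t_phase1_end = 12), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(sim$plate, path)
  plate <- read_plate_table(path, "wide_csv")
  expect_identical(length(unique(plate$well_id)), 3L)
  expect_identical(nrow(plate), nrow(sim$plate))
  expect_equal(plate$backscatter, sim$plate$backscatter, tolerance = 1e-9)
})

test_that("time units are normalised to hours on ingestion", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time = c(0, 9, 18, 27, 36),
                                  A01 = c(1, 1, 2, 4, 8)), path)
  plate <- read_plate_table(path, "biolector_csv",
                            config = list(time_unit = "min"))
  expect_equal(plate$time_h, c(0, 9, 18, 27, 36) / 60)
})

test_that("structural file defects are hard errors naming the defect", {
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(t = 1:5, A01 = 1:5), p)
  expect_error(read_plate_table(p, "wide_csv"), "time column")
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time_h = 1:3, A01 = 1:3), p2)
  expect_error(read_plate_table(p2, "wide_csv"), "fewer than 4")
  expect_error(read_plate_table(file.path(tempdir(), "nope.csv"), "wide_csv"),
               class = "mbrfit_io")
})

test_that("an unparseable reading truncates only the affected well, with a warning", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,A01,A02",
               "0,10,10", "0.15,11,10", "0.3,oops,10", "0.45,13,10",
               "0.6,14,10"), p)
  expect_warning(plate <- read_plate_table(p, "wide_csv"), "A01")
  expect_identical(nrow(plate[plate$well_id == "A01", ]), 2L)
  expect_identical(nrow(plate[plate$well_id == "A02", ]), 5L)
})

test_that("plate processing isolates non-growing wells and keeps the rest", {
  sim <- simulate_plate(5, curve_spec(), seed = 6, n_blank_wells = 1)
  res <- suppressMessages(
    process_plate(sim$plate, loq = 4, blank_policy = "adaptive"))
  expect_identical(nrow(res), 6L)
  expect_identical(sum(res$status == "no_growth"), 1L)
  expect_identical(sum(res$status == "ok"), 5L)
  blank_row <- res[res$status == "no_growth", ]
  expect_true(is.na(blank_row$mu))
  expect_identical(blank_row$strain, "blank")
})

test_that("48-well plate recovers the true rate within the CI for most wells", {
  sim <- simulate_plate(48, curve_spec(), seed = 13)
  res <- suppressMessages(
    process_plate(sim$plate, loq = 4, blank_policy = "adaptive"))
  expect_identical(nrow(res), 48L)
  expect_identical(sum(res$status == "ok"), 48L)
  covered <- sum(res$ci_low <= 0.46 & 0.46 <= res$ci_high)
  expect_gte(covered, 43L)
})

test_that("well processing order does not change the written results", {
  sim <- simulate_plate(8, curve_spec(), seed = 14)
  ord <- order(match(sim$plate$well_id, rev(unique(sim$plate$well_id))),
               sim$plate$time_h)
  plate_shuffled <- sim$plate[ord, ]
  attr(plate_shuffled, "groups") <- attr(sim$plate, "groups")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- suppressMessages(process_plate(sim$plate, loq = 4))
  r2 <- suppressMessages(process_plate(plate_shuffled, loq = 4))
  write_results(r1, aggregate_replicates(r1), d1)
  write_results(r2, aggregate_replicates(r2), d2)
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
})

test_that("replicate aggregation takes plain means, rounded only for presentation", {
  res <- tibble::tibble(
    well_id = c("A01", "A02", "A03", "B01", "B02"),
    strain = c("ecoli", "ecoli", "ecoli", "cglut", "cglut"),
    status = c("ok", "ok", "ok", "ok", "no_exponential_phase"),
    mu = c(0.601, 0.615, 0.617, 0.455, NA))
  s <- aggregate_replicates(res)
  eco <- s[s$strain == "ecoli", ]
  expect_equal(eco$mu_mean, mean(c(0.601, 0.615, 0.617)))
  expect_equal(eco$mu_mean, 0.611)
  expect_equal(eco$mu_mean_2dp, 0.61)
  cg <- s[s$strain == "cglut", ]
  expect_identical(cg$n_replicates, 1L)
  expect_equal(cg$mu_mean, 0.455)
  # duplicate rates averaging to 0.4555 present as 0.46
  res2 <- tibble::tibble(well_id = c("C1", "C2"), strain = "wt",
                         status = "ok", mu = c(0.455, 0.456))
  expect_equal(aggregate_replicates(res2)$mu_mean_2dp, 0.46)
})

test_that("a group with no converged replicate is flagged, not averaged", {
  res <- tibble::tibble(well_id = c("A01", "A02"),
                        strain = c("x", "y"),
                        status = c("ok", "no_growth"),
                        mu = c(0.3, NA))
  s <- aggregate_replicates(res)
  expect_identical(s$status[s$strain == "y"], "no_ok_replicates")
  expect_true(is.na(s$mu_mean[s$strain == "y"]))
})

test_that("percent deviation follows |1 - mu_auto/mu_ref| * 100", {
  expect_equal(deviation_percent(0.30, 0.30), 0)
  expect_equal(deviation_percent(0.30, 0.32), 6.25)
  # scale-free: 10% above reference is always 10
  for (x in c(0.1, 0.46, 2)) expect_equal(deviation_percent(1.1 * x, x), 10)
  expect_error(deviation_percent(0.3, 0), class = "mbrfit_bad_input")
})

test_that("result CSVs keep fixed columns, stored precision and empty summaries", {
  sim <- simulate_plate(3, curve_spec(), seed = 15)
  res <- suppressMessages(process_plate(sim$plate, loq = 4))
  dir <- withr::local_tempdir()
  paths <- write_results(res, NULL, dir)
  out <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_identical(names(out)[1:6],
                   c("well_id", "strain", "status", "mu", "ci_low", "ci_high"))
  # round-trip at stored precision (6 significant digits)
  expect_equal(out$mu, signif(res$mu, 6))
  smry <- readr::read_csv(paths[2], show_col_types = FALSE)
  expect_identical(nrow(smry), 0L)
  expect_true("mu_mean" %in% names(smry))
  expect_error(write_results(res[0, ], NULL, dir), class = "mbrfit_bad_input")
})

test_that("the reference strain panel reproduces its published deviation profile", {
  panel <- cglutamicum_panel()
  expect_identical(nrow(panel), 23L)
  expect_identical(anyDuplicated(panel$strain), 0L)
  dev <- deviation_percent(panel$mu_auto, panel$mu_lit)
  expect_identical(sum(dev <= 10), 13L)
  expect_true(all(panel$ci_low <= panel$mu_auto & panel$mu_auto <= panel$ci_high))
})
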