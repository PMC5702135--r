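test_that("weighted linear fit recovers an exact line", {
  d <- tibble::tibble(time_h = c(0, 1, 2, 3), y = c(1, 3, 5, 7), w = rep(2, 4))
  f <- fit_wlr(d)
  expect_equal(f$mu, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$adj_r2, 1, tolerance = 1e-12)
  expect_true(f$ci95[1] <= f$mu && f$mu <= f$ci95[2])
})

test_that("weighted fit equals the brute-force normal-equation oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    t <- sort(runif(n, 0, 20))
    y <- rnorm(n, 1 + 0.5 * t, 0.3)
    w <- runif(n, 0.01, 50)
    f <- fit_wlr(tibble::tibble(time_h = t, y = y, w = w))
    o <- wls_oracle(t, y, w)
    expect_equal(f$mu, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
  }
})

test_that("equal weights reproduce ordinary least squares exactly", {
  set.seed(202)
  t <- seq(0, 5, by = 0.25)
  y <- rnorm(length(t), 2 + 0.4 * t, 0.2)
  f <- fit_wlr(tibble::tibble(time_h = t, y = y, w = rep(3.7, length(t))))
  ols <- lm(y ~ t)
  expect_equal(f$mu, unname(coef(ols)[2]), tolerance = 1e-12)
  expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-12)
  expect_equal(f$mu_se, summary(ols)$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(f$adj_r2, summary(ols)$adj.r.squared, tolerance = 1e-10)
})

test_that("weighted fit agrees with lm(weights=) as an independent cross-check", {
  set.seed(303)
  t <- sort(runif(25, 0, 10))
  y <- rnorm(25, 1 + 0.6 * t, 0.5)
  w <- runif(25, 0.1, 10)
  f <- fit_wlr(tibble::tibble(time_h = t, y = y, w = w))
  wlm <- lm(y ~ t, weights = w)
  expect_equal(f$mu, unname(coef(wlm)[2]), tolerance = 1e-12)
  expect_equal(f$mu_se, summary(wlm)$coefficients[2, 2], tolerance = 1e-10)
})

test_that("log of a noiseless exponential gives the exact growth rate", {
  # c(t) = 0.5 * exp(0.46 t), 9-min sampling over 15-24 h
  t <- seq(15, 24, by = 0.15)
  cur <- tibble::tibble(time_h = t, value = 0.5 * exp(0.46 * t), error = 0)
  f <- fit_wlr(log_transform(cur))
  expect_equal(f$mu, 0.46, tolerance = 1e-11)
  # any positive weights: same exact slope on exact data
  lt <- log_transform(cur)
  lt$w <- runif(nrow(lt), 0.1, 5)
  expect_equal(fit_wlr(lt)$mu, 0.46, tolerance = 1e-11)
})

test_that("fit errors are classed for short, degenerate and bad inputs", {
  expect_error(fit_wlr(tibble::tibble(time_h = 1:2, y = 1:2, w = c(1, 1))),
               class = "mbrfit_short_window")
  expect_error(fit_wlr(tibble::tibble(time_h = rep(1, 4), y = 1:4, w = rep(1, 4))),
               class = "mbrfit_degenerate")
  expect_error(fit_wlr(tibble::tibble(time_h = 1:4, y = 1:4, w = c(1, 1, -1, 1))),
               class = "mbrfit_bad_input")
})

test_that("adjusted R2 matches its direct-sum oracle and edge identities", {
  expect_equal(adjusted_r2(c(1, 2, 3, 4), c(1, 2, 3, 4), rep(1, 4)), 1)
  # fitted values identically the weighted mean: R2_w = 0, adj = 1-(n-1)/(n-2)
  y <- c(1, 2, 3, 4, 10)
  w <- c(1, 2, 1, 2, 1)
  ybar <- sum(w * y) / sum(w)
  n <- length(y)
  expect_equal(adjusted_r2(y, rep(ybar, n), w), 1 - (n - 1) / (n - 2))
  # random data against the loop oracle
  set.seed(404)
  for (i in 1:20) {
    y <- rnorm(100); yhat <- rnorm(100); w <- runif(100, 0.1, 3)
    expect_equal(adjusted_r2(y, yhat, w), adj_r2_oracle(y, yhat, w),
                 tolerance = 1e-12)
  }
  # a *fitted* null model (weighted mean) marks the R2 = 0 baseline; fully
  # unrelated predictions fall below it
  set.seed(405)
  y2 <- rnorm(100)
  expect_lt(adjusted_r2(y2, rnorm(100), rep(1, 100)), 0)
  expect_error(adjusted_r2(rep(1, 5), rep(1, 5), rep(1, 5)),
               class = "mbrfit_degenerate")
})

test_that("nonlinear regression recovers exact exponential parameters", {
  t <- seq(1, 8, by = 0.15)
  cur <- tibble::tibble(time_h = t, value = 0.2 * exp(0.61 * t), error = 0.3)
  init <- fit_wlr(log_transform(cur))
  f <- fit_nlr(cur, init)
  expect_equal(f$mu, 0.61, tolerance = 1e-8)
  expect_equal(f$c0, 0.2, tolerance = 1e-8)
  expect_identical(f$method, "NLR")
  expect_gt(f$c0, 0)

  # basin robustness: an initial guess with mu doubled still reaches the
  # unique optimum on clean data
  init2 <- init
  init2$mu <- 2 * init$mu
  f2 <- fit_nlr(cur, init2)
  expect_equal(f2$mu, 0.61, tolerance = 1e-8)
})

test_that("confidence interval width shrinks roughly as 1/sqrt(n)", {
  widths <- sapply(c(10, 40, 160), function(n) {
    set.seed(500 + n)
    mean(replicate(40, {
      t <- seq(0, 5, length.out = n)
      v <- 5 * exp(0.4 * t) + rnorm(n, 0, 0.2)
      f <- fit_wlr(log_transform(tibble::tibble(time_h = t, value = v,
                                                error = 0.2)))
      diff(f$ci95)
    }))
  })
  # each 4x increase in n should shrink the width by about 2x
  expect_gt(widths[1] / widths[2], 1.5)
  expect_lt(widths[1] / widths[2], 2.9)
  expect_gt(widths[2] / widths[3], 1.5)
  expect_lt(widths[2] / widths[3], 2.9)
})

test_that("tidy and glance return broom-shaped summaries", {
  d <- tibble::tibble(time_h = 0:5, y = 1 + 0.3 * (0:5) + c(0, .01, -.01, 0, .02, 0),
                      w = rep(1, 6))
  f <- fit_wlr(d)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$term[1:2], c("mu", "intercept"))
  g <- glance(f)
  expect_identical(nrow(g), 1L)
  expect_identical(g$method, "WLR")
  expect_equal(g$mu, f$mu)
})
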