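test_that("Hegyi competition index: isolation, symmetry, monotonicity", {
  d <- design_table(data.frame(
    tree = c("a", "b", "far"), family = "f", provenance = "p", block = "b1",
    x = c(0, 1.2, 100), y = 0))
  sz <- c(a = 10, b = 10, far = 10)
  ci <- competition_index(d, sz)
  expect_equal(ci$ci[ci$tree == "far"], 0)                  # isolated
  expect_equal(ci$ci[ci$tree == "a"], 1 / 1.2, tolerance = 1e-12)
  expect_equal(ci$ci[ci$tree == "a"], ci$ci[ci$tree == "b"])

  sz2 <- c(a = 10, b = 20, far = 10)
  ci2 <- competition_index(d, sz2)
  expect_gt(ci2$ci[ci2$tree == "a"], ci$ci[ci$tree == "a"]) # bigger neighbour
})

test_that("trend removal: age-trend residuals are decorrelated from age", {
  set.seed(21)
  n_tree <- 100; ny <- 20
  x <- do.call(rbind, lapply(seq_len(n_tree), function(i) {
    age <- 1:ny
    data.frame(tree = i, year = 1989 + age, age = age,
               ba = cumsum(exp(2 - age / 8))^2,
               val = 3 * exp(-age / 6) + rnorm(ny, 0, 0.1))
  }))
  ft <- fit_trend(x, "val", covariates = c("age", "ba"))
  expect_lt(abs(cor(ft$data$residual, ft$data$age)), 0.05)
  # fitted surface tracks the true age curve to below the noise SD
  rmse <- sqrt(mean((ft$data$fitted - 3 * exp(-ft$data$age / 6))^2))
  expect_lt(rmse, 0.1)

  # constant trait -> zero residuals
  xc <- x; xc$val <- 5
  ftc <- fit_trend(xc, "val")
  expect_equal(ftc$data$residual, rep(0, nrow(xc)))
})

test_that("prewhitening removes AR(1) persistence", {
  set.seed(22)
  mk <- function(i, phi) {
    data.frame(tree = i, year = 1:100,
               residual = as.numeric(arima.sim(list(ar = phi), 100)))
  }
  x <- do.call(rbind, lapply(1:10, mk, phi = 0.6))
  pw <- prewhiten(x)
  lag1 <- vapply(split(pw, pw$tree), function(df) {
    w <- df$white[!is.na(df$white)]
    cor(w[-1], w[-length(w)])
  }, numeric(1))
  expect_true(all(abs(lag1) < 0.15))
  # variance rescaled to the input residual variance
  one <- pw[pw$tree == 1, ]
  expect_equal(sd(one$white, na.rm = TRUE), sd(one$input), tolerance = 1e-6)

  # white-noise input: order 0 selected in the majority of series
  xw <- do.call(rbind, lapply(11:30, function(i) {
    data.frame(tree = i, year = 1:80, residual = rnorm(80))
  }))
  pww <- prewhiten(xw)
  p_by_tree <- vapply(split(pww, pww$tree), function(df) df$p[1], integer(1))
  expect_gt(mean(p_by_tree == 0), 0.5)

  # constant series flagged, not fitted
  xc <- data.frame(tree = "c", year = 1:30, residual = 1)
  expect_equal(unique(prewhiten(xc)$flag), "constant")
})

test_that("prewhitened AR(1) input passes Ljung-Box in most seeds", {
  ok <- vapply(1:30, function(s) {
    set.seed(300 + s)
    x <- data.frame(tree = "t", year = 1:100,
                    residual = as.numeric(arima.sim(list(ar = 0.6), 100)))
    w <- prewhiten(x)$white
    Box.test(w[!is.na(w)], lag = 5, type = "Ljung-Box")$p.value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("standardize_rings chains the two steps and applies the year cut", {
  p <- tiny_params()
  tr <- simulate_trial(p)
  std <- standardize_rings(tr$rings, tr$design, cut_year = 1995)
  expect_true(all(std$year >= 1995))
  expect_true(all(is.finite(std$white)))
  # per-series prewhitened residuals are near mean zero
  mu <- vapply(split(std$white, std$tree), mean, numeric(1))
  expect_lt(max(abs(mu)), 0.5)
})
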