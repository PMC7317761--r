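test_that("BAI conversion matches hand calculation and telescopes", {
  rs <- ring_set(data.frame(tree = "t", year = 2000:2002, RW = c(1, 1, 1)))
  b <- rw_to_bai(rs)
  expect_equal(b$BAI, c(pi, 3 * pi, 5 * pi), tolerance = 1e-12)
  expect_equal(sum(b$BAI), pi * 3^2, tolerance = 1e-12)   # total basal area

  # single ring of width r -> pi r^2
  r1 <- rw_to_bai(ring_set(data.frame(tree = "s", year = 2000, RW = 2.5)))
  expect_equal(r1$BAI, pi * 2.5^2)

  # exact inversion given R_0 = 0
  set.seed(4)
  rw <- runif(20, 0.5, 4)
  b2 <- rw_to_bai(ring_set(data.frame(tree = "u", year = 1:20 + 1980, RW = rw)))
  radius <- sqrt(cumsum(b2$BAI) / pi)
  expect_equal(diff(c(0, radius)), rw, tolerance = 1e-10)
})

test_that("derived tracheid traits follow the wall/lumen formulas", {
  df <- ring_set(data.frame(tree = "t", year = 2000, RW = 1,
                            TDr = 30, TDt = 30, CWT = 2))
  d <- derive_tracheid(df)
  expect_equal(d$LDr, 28)
  expect_equal(d$LD, 28)
  expect_equal(d$CWRr, (4 / 28)^2, tolerance = 1e-12)
  expect_equal(d$CWR, (4 / 28)^2, tolerance = 1e-12)

  # CWT -> 0 drives CWR -> 0
  d0 <- derive_tracheid(ring_set(data.frame(tree = "t", year = 2000, RW = 1,
                                            TDr = 30, TDt = 30, CWT = 1e-6)))
  expect_lt(d0$CWR, 1e-12)

  # dimensionless: doubling all lengths leaves CWR unchanged
  d2 <- derive_tracheid(ring_set(data.frame(tree = "t", year = 2000, RW = 1,
                                            TDr = 60, TDt = 60, CWT = 4)))
  expect_equal(d2$CWR, d$CWR)

  # single-wall option
  d1 <- derive_tracheid(df, wall = "single")
  expect_equal(d1$CWRr, (2 / 28)^2)

  bad <- data.frame(tree = "t", year = 2000, RW = 1, TDr = 3, TDt = 30, CWT = 5)
  expect_error(derive_tracheid(bad), "CWT")
})

test_that("EPS closed form and monotonicity", {
  expect_equal(eps_signal(10, 0.3), 3 / 3.7, tolerance = 1e-12)
  expect_equal(eps_signal(5, 1), 1)
  n <- c(5, 10, 20, 40)
  expect_true(all(diff(eps_signal(n, 0.3)) > 0))
  expect_true(all(diff(eps_signal(10, c(0.1, 0.3, 0.6, 0.9))) > 0))
})

test_that("chronologies: means, depth, rbar and degenerate groups", {
  yrs <- 1990:2009
  base <- sin(yrs / 2)
  x <- rbind(
    data.frame(tree = "a", year = yrs, value = base),
    data.frame(tree = "b", year = yrs, value = base),       # identical
    data.frame(tree = "c", year = yrs, value = base + 0.5)) # shifted copy
  ch <- build_chronology(x, group = rep("g1", nrow(x)))
  expect_equal(ch$stats$rbar, 1)                            # identical shapes
  expect_equal(ch$stats$eps, 1)
  expect_equal(ch$chronology$depth, rep(3L, 20))
  expect_equal(ch$chronology$mean, base + 0.5 / 3, tolerance = 1e-12)

  # single-tree group flagged
  ch1 <- build_chronology(x[x$tree == "a", ], group = rep("solo", 20))
  expect_true(ch1$stats$flagged)
  expect_true(is.na(ch1$stats$eps))

  # independent white noise: low EPS in most seeds
  low <- vapply(1:40, function(s) {
    set.seed(s)
    w <- do.call(rbind, lapply(1:20, function(i) {
      data.frame(tree = paste0("t", i), year = 1:60, value = rnorm(60))
    }))
    build_chronology(w, rep("g", nrow(w)))$stats$eps
  }, numeric(1))
  expect_gte(mean(low < 0.5), 0.95)
})

test_that("cross-dating flags misdated and noise series", {
  set.seed(11)
  yrs <- 1960:2007
  sig <- as.numeric(arima.sim(list(ar = 0.3), length(yrs)))
  mk <- function(id, v) data.frame(tree = id, year = yrs, RW = 5 + v)
  good <- do.call(rbind, lapply(1:8, function(i) mk(paste0("g", i),
                                                   sig + rnorm(length(yrs), 0, 0.3))))
  rep <- crossdate_check(ring_set(good))
  expect_true(all(!rep$flag))
  expect_true(all(rep$best_lag == 0))

  # a copy of the mean signal dated one year late
  shifted <- data.frame(tree = "late", year = yrs + 1, RW = 5 + sig)
  rep2 <- crossdate_check(ring_set(rbind(good, shifted)))
  expect_equal(rep2$best_lag[rep2$tree == "late"], -1L)
  expect_true(rep2$flag[rep2$tree == "late"])

  # white noise against a strong master: flagged in most seeds
  flags <- vapply(1:30, function(s) {
    set.seed(100 + s)
    noise <- data.frame(tree = "nz", year = yrs, RW = 5 + rnorm(length(yrs), 0, 0.3))
    r <- crossdate_check(ring_set(rbind(good, noise)))
    r$flag[r$tree == "nz"]
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})
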