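test_that("monthly aggregation: means, sums and dry-day counts", {
  g <- expand.grid(day = 1:31, month = 1:12, year = 2000)
  dim_tab <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  g <- g[g$day <= dim_tab[g$month], ]
  daily <- data.frame(g, tmin = 5, tmean = 10, tmax = 15, prcp = 1,
                      rh = 70, vpd = 0.4)
  m <- aggregate_monthly(daily)
  expect_equal(nrow(m), 12)
  expect_equal(m$tmean, rep(10, 12))
  expect_equal(m$prcp, dim_tab)          # 1 mm/day
  expect_equal(sum(m$dry_days), 0)

  dry <- daily; dry$prcp <- 0
  expect_equal(sum(aggregate_monthly(dry)$dry_days), 365)  # ADD over a dry year

  expect_error(aggregate_monthly(daily[-1, ]), "incomplete",
               class = "dendroQG_missing_days")
})

test_that("soil moisture bucket: balance identity, monotonicity, bounds", {
  m <- flat_monthly(2000:2004)
  s <- compute_smi(m, w_max = 300, w_crit = 400)
  expect_true(all(s$W >= 0 & s$W <= 300))
  expect_true(all(s$SMI >= 0 & s$SMI <= 100))
  # mass balance closes to machine precision over the whole record
  dW <- sum(diff(c(attr(s, "w_init"), s$W)))
  expect_equal(dW, sum(s$gain) - sum(s$aet) - sum(s$overflow), tolerance = 1e-10)

  # no precipitation, positive PET: store non-increasing towards 0
  m0 <- flat_monthly(2000:2004, prcp = 0)
  s0 <- compute_smi(m0)
  expect_true(all(diff(s0$W) <= 1e-12))
  expect_lt(min(s0$W), 1)

  # P identically equal to AET keeps the store constant: set monthly
  # precipitation to the analytic AET at the target store
  w_star <- 150; w_crit <- 400
  g_star <- 2 * (w_star / w_crit) - (w_star / w_crit)^2
  m2 <- flat_monthly(2000:2001)
  m2$prcp <- pet_pm(12, 0.5) * m2$n_days * g_star
  s2 <- compute_smi(m2, w_max = 300, w_crit = w_crit, w_init = w_star)
  expect_equal(s2$W, rep(w_star, nrow(s2)), tolerance = 1e-9)
})

test_that("snowmelt banks sub-zero precipitation until the first thaw", {
  m <- flat_monthly(2000)
  m$tmean[1:3] <- -5; m$tmin[1:3] <- -9; m$tmax[1:3] <- -1
  s <- compute_smi(m, w_init = 100)
  expect_equal(s$gain[1:3], rep(0, 3))
  expect_equal(s$gain[4], sum(m$prcp[1:4]))  # three banked months + April
})

test_that("summer anomalies and drought detection", {
  m <- flat_monthly(1990:2007)
  m$SMI <- 60
  a <- summer_anomaly(m, "SMI")
  expect_equal(a$ratio, rep(1, 18))
  expect_length(detect_droughts(a), 0)      # flat climate -> nothing flagged

  # one imposed 2-year drought dated at its final year
  m$SMI[m$year %in% c(1995, 1996) & m$month %in% 6:8] <- 30
  a2 <- summer_anomaly(m, "SMI")
  # baseline includes the two depressed summers: 16 x 60 + 2 x 30 over 18
  expect_equal(a2$ratio[a2$year == 1990], 60 / ((16 * 60 + 2 * 30) / 18),
               tolerance = 1e-12)
  expect_equal(detect_droughts(a2, quantile = 0.1), 1996L)

  # half-baseline summer -> ratio 0.5 against an unperturbed baseline
  m3 <- flat_monthly(1990:2007); m3$SMI <- 60
  m3$SMI[m3$year == 2000 & m3$month %in% 6:8] <- 30
  a3 <- summer_anomaly(m3, "SMI", baseline = 1990:1999)
  expect_equal(a3$ratio[a3$year == 2000], 0.5)

  # three imposed droughts at realistic spacing -> exactly 3 events
  m4 <- flat_monthly(1989:2007); m4$SMI <- 60
  m4$SMI[m4$year %in% c(1997, 2001, 2002, 2005) & m4$month %in% 6:8] <- 25
  ev <- detect_droughts(summer_anomaly(m4, "SMI"))
  expect_equal(ev, c(1997L, 2002L, 2005L))

  # invariance to affine rescaling of the anomaly baseline
  m5 <- m4; m5$SMI <- m5$SMI * 1.3
  expect_equal(detect_droughts(summer_anomaly(m5, "SMI")), ev)
})

test_that("annual normals average the right quantities", {
  m <- flat_monthly(2000:2001, tmean = 8, prcp = 50)
  m$dry_days <- 10L
  s <- compute_smi(m)
  nm <- annual_normals(m, smi = s)
  expect_equal(nm$MAT, 8)
  expect_equal(nm$MAP, 600)
  expect_equal(nm$ADD, 120)
  expect_equal(nm$Summer_SMI, mean(s$SMI[s$month %in% 6:8]))
  expect_error(annual_normals(m, period = 1950), "empty")
})
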