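test_that("REML matches the closed-form ANOVA estimator on balanced one-way data", {
  d <- one_way(seed = 31)
  vc <- fit_lmm(d, "y", random = "grp")
  av <- anova(stats::lm(y ~ grp, d))
  msb <- av["grp", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
  expect_equal(vc$components$grp, (msb - msw) / 10, tolerance = 1e-4)
  expect_equal(vc$components$residual, msw, tolerance = 1e-4)
  expect_true(all(is.finite(unlist(vc$se))))

  # all-zero response: degenerate, all variances zero
  d0 <- data.frame(y = 0, grp = gl(5, 4))
  vc0 <- fit_lmm(d0, "y", random = "grp")
  expect_equal(unlist(vc0$components), c(grp = 0, residual = 0))
})

test_that("heritability and Q_ST reproduce published variance-component ratios", {
  r <- 0.2573
  # wood density row
  expect_equal(round(heritability(144.723, 1689.941, r)$estimate, 3), 0.333)
  expect_equal(round(qst(110.689, 144.723, r)$estimate, 3), 0.090)
  # mean lumen diameter row
  expect_equal(round(heritability(0.204, 2.95, r)$estimate, 3), 0.269)
  expect_equal(round(qst(0.123, 0.204, r)$estimate, 3), 0.072)
  # radial lumen diameter row
  expect_equal(round(qst(0.283e-3, 0.796e-3, r)$estimate, 3), 0.044)

  # trivial identities
  expect_equal(heritability(0, 10, 0.25)$estimate, 0)
  expect_equal(qst(0, 5, 0.25)$estimate, 0)
  expect_equal(qst(2 * 5 / 0.25, 5, 0.25)$estimate, 0.5)  # pop = 2 fam / r

  # both ratios are exactly scale invariant
  k <- 13.7
  expect_equal(heritability(144.723 * k, 1689.941 * k, r)$estimate,
               heritability(144.723, 1689.941, r)$estimate, tolerance = 1e-12)
  expect_equal(qst(110.689 * k, 144.723 * k, r)$estimate,
               qst(110.689, 144.723, r)$estimate, tolerance = 1e-12)
})

test_that("delta-method CIs are symmetric and shrink with design size", {
  fit_one <- function(n_grp, n_rep, seed) {
    d <- one_way(seed, n_grp = n_grp, n_rep = n_rep)
    vc <- fit_lmm(d, "y", random = "grp")
    h <- heritability(vc$components$grp,
                      vc$components$grp + vc$components$residual, r = 0.25,
                      vcov = matrix(c(vc$vcov["grp", "grp"],
                                      sum(vc$vcov["grp", ]),
                                      sum(vc$vcov["grp", ]),
                                      sum(vc$vcov)), 2, 2))
    h
  }
  small <- fit_one(15, 4, 41)
  big <- fit_one(120, 8, 41)
  expect_equal(unname(diff(small$ci)), unname(2 * 1.96 * small$se),
               tolerance = 1e-10)
  expect_lt(big$se, small$se)
})

test_that("likelihood-ratio test: null statistic and power", {
  set.seed(51)
  d <- one_way(seed = 52, n_grp = 30, n_rep = 8, s_b = 2)
  lr <- lrt_random(d, "y", random = c("grp"), term = "grp")
  expect_lt(lr$p_value, 0.001)

  # a second, pure-noise grouping is not significant
  d$g2 <- factor(sample(1:10, nrow(d), replace = TRUE))
  lr2 <- lrt_random(d, "y", random = c("grp", "g2"), term = "g2")
  expect_gt(lr2$p_value, 0.05)
  # a tied likelihood (boundary estimate) must give statistic 0, p = 1
  if (lr2$statistic == 0) expect_equal(lr2$p_value, 1)
})

test_that("type-I error of the boundary-mixture LRT is near nominal", {
  rej <- vapply(1:200, function(s) {
    d <- one_way(seed = 600 + s, n_grp = 20, n_rep = 5, s_b = 0)
    lrt_random(d, "y", random = "grp", term = "grp")$p_value < 0.05
  }, logical(1))
  # 7.5% allowed exceedance over nominal plus a 99% binomial MC allowance
  expect_lte(mean(rej), 0.075 + 2.33 * sqrt(0.075 * 0.925 / 200))
})

test_that("VanRaden G-matrix: centring, diagonal, within-family relatedness", {
  # every tree heterozygous: each row sits exactly at 2p, so W = 0 and all
  # relationships (including self) are 0
  M <- matrix(1L, nrow = 6, ncol = 120,
              dimnames = list(paste0("t", 1:6), NULL))
  G <- gmatrix(M, min_snps = 10)
  expect_true(all(G == 0))
  # Hardy-Weinberg simulation: mean diagonal near 1
  set.seed(61)
  p <- runif(2000, 0.1, 0.9)
  Mh <- sapply(p, function(pp) rbinom(80, 2, pp))
  rownames(Mh) <- paste0("t", 1:80)
  Gh <- gmatrix(Mh)
  expect_equal(mean(diag(Gh)), 1, tolerance = 0.05)
  expect_equal(mean(Gh[upper.tri(Gh)]), 0, tolerance = 0.02)

  expect_error(gmatrix(matrix(2L, 5, 200)), "monomorphic")
})

test_that("Weir-Cockerham theta: fixed demes, panmixia, Nei cross-check", {
  # two demes fixed for alternate alleles -> theta = 1
  M <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  f <- fst_wc(M, rep(c("A", "B"), each = 10))
  expect_equal(f$theta, 1)
  expect_equal(unique(round(f$per_snp$theta, 10)), 1)

  # panmictic simulation: theta within +/- 0.005 of 0
  set.seed(62)
  p <- runif(5000, 0.1, 0.9)
  Mp <- sapply(p, function(pp) rbinom(200, 2, pp))
  fp <- fst_wc(Mp, rep(paste0("d", 1:10), each = 20))
  expect_lt(abs(fp$theta), 0.005)
  # Nei-style G_ST carries a +1/(2n) finite-sample bias; loose cross-check only
  expect_lt(abs(fp$gst), 0.05)

  expect_error(fst_wc(M, rep("A", 20)), "2 demes")
})

test_that("repeated-measures components feed the ratio estimators coherently", {
  p <- tiny_params(seed = 17)
  tr <- simulate_trial(p)
  d <- as.data.frame(tr$rings)
  d <- merge(d, as.data.frame(tr$design), by = "tree")
  d$lrw <- log(d$RW)
  d$plot <- paste(d$family, d$block, sep = "/")
  d <- d[d$year %in% 1999:2001, ]
  vc <- fit_lmm(d, "lrw", fixed = "factor(year)",
                random = c("provenance", "family", "plot"),
                residual = "AR1", year = "year", tree = "tree")
  hq <- herit_qst(vc, r = 0.25)
  expect_gte(hq$qst$estimate, 0)
  expect_lte(hq$qst$estimate, 1)
  expect_gte(hq$h2$estimate, 0)
  expect_true(is.finite(hq$h2$estimate))
})
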