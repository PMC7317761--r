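test_that("simulated datasets are reproducible from (params, seed)", {
  p <- tiny_params(seed = 12)
  a <- simulate_trial(p)
  b <- simulate_trial(p)
  expect_identical(a$rings, b$rings)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$design, b$design)
  # a different seed changes the layout but not the design counts
  p2 <- tiny_params(seed = 13)
  c2 <- simulate_trial(p2)
  expect_false(identical(a$rings$RW, c2$rings$RW))
  expect_identical(table(a$design$provenance), table(c2$design$provenance))
})

test_that("weather generator honours its stationary precipitation moments", {
  w <- gen_weather(1801:2000, seed = 8)
  summer <- w[w$month %in% 6:8, ]
  totals <- tapply(summer$prcp, summer$year, sum)
  p_wet <- 0.35 / (1 + 0.35 - 0.55)          # stationary wet-day probability
  expected <- p_wet * 6.5 * 92               # mean amount * summer days
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
  expect_true(all(w$tmin <= w$tmean & w$tmean <= w$tmax))
  expect_true(all(w$vpd >= 0))
  expect_true(all(w$prcp >= 0))
})

test_that("drought years are severe relative to the local distribution", {
  hit <- vapply(1:100, function(s) {
    w <- gen_weather(1990:2005, seed = s, drought_years = 2000, severity = 0.3)
    su <- w[w$month %in% 6:8, ]
    tot <- tapply(su$prcp, su$year, sum)
    tot[["2000"]] < quantile(tot[names(tot) != "2000"], 0.10)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("an all-dry occurrence chain yields 365 dry days", {
  w <- gen_weather(2000:2001, seed = 1, p01 = 0, p11 = 0)
  m <- aggregate_monthly(w)
  expect_true(all(w$prcp < 0.2))
  expect_equal(sum(m$dry_days[m$year == 2000]), 365L)
})

test_that("design generator produces the expected plot structure", {
  p <- sim_params(n_prov = 43, n_fam = 197, n_blocks = 6, trees_per_plot = 5,
                  seed = 2)
  d <- gen_design(p)
  expect_equal(nrow(d), 197 * 6 * 5)          # 5910 tree slots
  expect_equal(length(unique(d$family)), 197)
  fam_per_prov <- table(unique(d[c("family", "provenance")])$provenance)
  expect_true(all(fam_per_prov >= 1 & fam_per_prov <= 5))
  # every family once per block
  tab <- table(d$family, d$block) / p$trees_per_plot
  expect_true(all(tab == 1))
  # origin gradient: Summer_SMI strictly monotone over the provenance index
  o <- attr(d, "origins")
  expect_true(all(diff(o$Summer_SMI) > 0))

  p1 <- sim_params(n_prov = 1, n_fam = 1, n_blocks = 1, trees_per_plot = 5)
  d1 <- gen_design(p1)
  expect_equal(nrow(d1), 5)
  expect_equal(length(unique(paste(d1$family, d1$block))), 1L)
})

test_that("genotype generator hits its differentiation and relatedness targets", {
  # unrelated trees (one per family): Weir-Cockerham consistency at fst = 0
  n_demes <- 12; n_per <- 20
  du <- design_table(data.frame(
    tree = sprintf("t%03d", 1:(n_demes * n_per)),
    family = sprintf("f%03d", 1:(n_demes * n_per)),
    provenance = rep(sprintf("p%02d", 1:n_demes), each = n_per),
    block = "b1", x = 1:(n_demes * n_per), y = 0))
  g0 <- gen_genotypes(du, n_snps = 3000, fst = 0, seed = 5)
  f0 <- fst_wc(g0, du$provenance)
  expect_lt(abs(f0$theta), 0.006)

  # half-sib families under panmixia: mean within-family genomic relatedness
  # near the pedigree 0.25 (deme differentiation would shift the G baseline)
  p <- sim_params(n_prov = 6, n_fam = 24, n_blocks = 2, trees_per_plot = 3)
  d <- gen_design(p, seed = 5)
  gf <- gen_genotypes(d, n_snps = 3000, fst = 0, seed = 6)
  G <- gmatrix(gf)
  r_hat <- avg_within_family(G, d)$r_hat
  expect_gte(r_hat, 0.2)
  expect_lte(r_hat, 0.3)
})

test_that("ring generator: degenerate flatness and drought construction", {
  p <- sim_params(n_prov = 2, n_fam = 4, n_blocks = 1, trees_per_plot = 2,
                  years = 1995:2004, drought_years = integer(0),
                  sigma2_pop = 0, sigma2_fam = 0, sigma2_plot = 0,
                  sigma2_e = 0, sigma2_pop_year = 0, sigma2_fam_year = 0,
                  rho = 0, seed = 9)
  d <- gen_design(p)
  m <- flat_monthly(1995:2004); s <- compute_smi(m)
  rg <- gen_rings(d, s, p)
  # no variance, flat climate, no drought: every tree has an identical series
  rw <- matrix(rg$rings$RW, nrow = length(p$years))
  expect_lt(max(apply(rw, 1, sd)), 1e-12)

  # with a drought imposed, the population-mean BAI dips below both neighbours
  p2 <- tiny_params(seed = 10)
  tr <- simulate_trial(p2)
  b <- rw_to_bai(tr$rings)
  ann <- tapply(b$BAI, b$year, mean)
  expect_lt(ann[["1997"]], ann[["1996"]])
  expect_lt(ann[["1997"]], ann[["1998"]])
  expect_lt(ann[["2002"]], ann[["2001"]])
  expect_lt(ann[["2002"]], ann[["2003"]])
})

test_that("population variance chosen for Q_ST 0.09 is recovered by the model chain", {
  # generator-level parameter recovery: sigma2_pop set so that the true
  # Q_ST = pop / (pop + 2 fam / r) equals 0.09 at r = 0.25
  s_fam <- 0.02
  q_true <- 0.09
  s_pop <- q_true / (1 - q_true) * 2 * s_fam / 0.25
  ests <- vapply(1:20, function(s) {
    p <- sim_params(n_prov = 43, n_fam = 197, n_blocks = 6, trees_per_plot = 1,
                    years = 2000:2001, drought_years = integer(0),
                    sigma2_pop = s_pop, sigma2_fam = s_fam,
                    sigma2_plot = 0.01, sigma2_e = 0.04,
                    sigma2_pop_year = 0, sigma2_fam_year = 0, seed = 900 + s)
    d <- gen_design(p)
    m <- flat_monthly(2000:2001); sm <- compute_smi(m)
    rg <- gen_rings(d, sm, p)
    x <- as.data.frame(rg$rings)
    x$lrw <- log(x$RW)
    per_tree <- aggregate(x$lrw, by = list(tree = x$tree), FUN = mean)
    names(per_tree)[2] <- "resp"   # "y" would collide with the coordinate
    dd <- merge(per_tree, as.data.frame(d), by = "tree")
    dd$plot <- paste(dd$family, dd$block, sep = "/")
    vc <- fit_lmm(dd, "resp", fixed = "block",
                  random = c("provenance", "family"))
    qst(vc$components$provenance, vc$components$family, r = 0.25)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - q_true), 0.03)
})
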