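# Shared small fixtures, built in code at test time.

tiny_params <- function(seed = 7) {
  sim_params(n_prov = 4, n_fam = 10, n_blocks = 2, trees_per_plot = 2,
             years = 1990:2006, drought_years = c(1997, 2002),
             n_snps = 400, seed = seed)
}

# flat monthly climate: constant temperature/precip, complete months
flat_monthly <- function(years, tmean = 12, prcp = 80, vpd = 0.5) {
  g <- expand.grid(month = 1:12, year = years)
  data.frame(year = g$year, month = g$month, tmin = tmean - 4,
             tmean = tmean, tmax = tmean + 4, prcp = prcp, rh = 70,
             vpd = vpd, dry_days = 0L,
             n_days = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[g$month])
}

# one-way balanced random-effects data for REML oracle checks
one_way <- function(seed, n_grp = 50, n_rep = 10, s_b = 2, s_w = 1) {
  set.seed(seed)
  g <- gl(n_grp, n_rep)
  data.frame(y = rnorm(n_grp, 0, sqrt(s_b))[g] + rnorm(n_grp * n_rep, 0, sqrt(s_w)),
             grp = g)
}
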