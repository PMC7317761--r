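#' Simulation parameters for the synthetic common garden
#'
#' Defaults emulate the real trial the package is designed around: 43
#' provenances carrying one to five open-pollinated half-sib families each
#' (197 families in total), each family planted as a five-tree row-plot in
#' each of six randomized complete blocks at 1.2 m within-row spacing and
#' 2.4 m between rows; ring series spanning 1979-2007 with imposed drought
#' years 1997, 2001-2002 and 2005; and 6386 biallelic SNPs differentiated
#' among provenances near F_ST 0.043. Genetic effects enter ring generation
#' on the log scale so variance ratios are scale-free. The clinal link
#' `beta` couples a provenance's drought response to its origin summer soil
#' moisture: provenances of drier origin are hit less by a drought and
#' rebound better, so resilience declines with origin Summer_SMI.
#'
#' @param n_prov number of provenances.
#' @param n_fam total number of half-sib families (distributed 1-5 per
#'   provenance).
#' @param n_blocks complete blocks.
#' @param trees_per_plot trees per family row-plot within a block.
#' @param years calendar years of the ring record.
#' @param drought_years years receiving the drought treatment.
#' @param severity multiplicative Jun-Sep precipitation factor in drought
#'   years (< 1 means drier).
#' @param sigma2_pop,sigma2_fam,sigma2_plot,sigma2_e variance components on
#'   the log ring-width scale (population, family-within-population, plot,
#'   tree-year residual).
#' @param sigma2_pop_year,sigma2_fam_year interaction components.
#' @param rho AR(1) correlation of the tree-level residual across years.
#' @param beta clinal slope: log-scale drought-response penalty per unit of
#'   standardized origin Summer_SMI (positive = humid origins suffer more).
#' @param n_snps,fst SNP panel size and target Balding-Nichols
#'   differentiation.
#' @param seed RNG seed recorded with every simulated dataset.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_prov = 43, n_fam = 197, n_blocks = 6,
                       trees_per_plot = 5, years = 1979:2007,
                       drought_years = c(1997, 2001, 2002, 2005),
                       severity = 0.35,
                       sigma2_pop = 0.010, sigma2_fam = 0.020,
                       sigma2_plot = 0.010, sigma2_e = 0.040,
                       sigma2_pop_year = 0.004, sigma2_fam_year = 0.008,
                       rho = 0.3, beta = 0.06,
                       n_snps = 6386, fst = 0.043, seed = 1) {
  stopifnot(n_prov >= 1, n_fam >= n_prov, n_fam <= 5 * n_prov,
            n_blocks >= 1, trees_per_plot >= 1, length(years) >= 2,
            abs(rho) < 1, fst >= 0, fst < 1)
  vs <- c(sigma2_pop, sigma2_fam, sigma2_plot, sigma2_e,
          sigma2_pop_year, sigma2_fam_year)
  if (any(vs < 0)) qg_stop("variance components must be >= 0")
  structure(list(n_prov = n_prov, n_fam = n_fam, n_blocks = n_blocks,
                 trees_per_plot = trees_per_plot, years = years,
                 drought_years = drought_years, severity = severity,
                 sigma2_pop = sigma2_pop, sigma2_fam = sigma2_fam,
                 sigma2_plot = sigma2_plot, sigma2_e = sigma2_e,
                 sigma2_pop_year = sigma2_pop_year,
                 sigma2_fam_year = sigma2_fam_year,
                 rho = rho, beta = beta, n_snps = n_snps, fst = fst,
                 seed = seed), class = "sim_params")
}

#' Generate daily weather
#'
#' Humid-continental synthetic weather: daily mean temperature is a seasonal
#' sinusoid plus AR(1) noise, with Tmin/Tmax offset symmetrically;
#' precipitation occurrence follows a two-state Markov chain with
#' gamma-distributed wet-day amounts; relative humidity is bounded noise and
#' the vapour-pressure deficit is derived from temperature and RH (hence
#' always non-negative and internally consistent). Drought years multiply
#' June-September precipitation amounts by `severity` and add a temperature
#' bump over the same months.
#'
#' @param years integer vector of calendar years (365-day years).
#' @param seed RNG seed.
#' @param drought_years years receiving the drought treatment.
#' @param severity Jun-Sep precipitation multiplier in drought years.
#' @param t_mean,t_amp annual mean and seasonal amplitude of daily mean
#'   temperature, degC.
#' @param t_range mean diurnal Tmax - Tmin range, degC.
#' @param ar_phi,ar_sd AR(1) parameters of the temperature noise.
#' @param p01,p11 Markov occurrence probabilities (wet after dry, wet after
#'   wet).
#' @param gamma_shape,gamma_mean wet-day amount distribution (mm).
#' @param t_bump drought-year Jun-Sep temperature addition, degC.
#' @return data.frame of class `daily_climate`: `year`, `month`, `day`,
#'   `doy`, `tmin`, `tmean`, `tmax`, `prcp`, `rh`, `vpd`.
#' @export
gen_weather <- function(years, seed = 1, drought_years = integer(0),
                        severity = 0.35, t_mean = 4, t_amp = 16,
                        t_range = 9, ar_phi = 0.7, ar_sd = 2.2,
                        p01 = 0.35, p11 = 0.55,
                        gamma_shape = 0.9, gamma_mean = 6.5, t_bump = 2) {
  if (length(years) < 2) qg_stop("need at least 2 years of weather")
  set.seed(seed)
  dim_tab <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month_of <- rep(1:12, dim_tab)
  day_of <- unlist(lapply(dim_tab, seq_len))
  n_per <- 365L
  n <- n_per * length(years)
  doy <- rep(seq_len(n_per), length(years))
  year <- rep(years, each = n_per)
  month <- rep(month_of, length(years))
  day <- rep(day_of, length(years))

  eps <- stats::filter(stats::rnorm(n, 0, ar_sd * sqrt(1 - ar_phi^2)),
                       ar_phi, method = "recursive")
  tmean <- t_mean - t_amp * cos(2 * pi * (doy - 15) / 365) + as.numeric(eps)
  half <- t_range / 2 + abs(stats::rnorm(n, 0, 0.8))
  tmax <- tmean + half
  tmin <- tmean - half

  wet <- logical(n)
  wet[1] <- stats::runif(1) < p01 / (1 + p01 - p11)
  u <- stats::runif(n)
  for (i in 2:n) wet[i] <- u[i] < (if (wet[i - 1]) p11 else p01)
  amt <- numeric(n)
  amt[wet] <- stats::rgamma(sum(wet), shape = gamma_shape,
                            scale = gamma_mean / gamma_shape)
  dry_mod <- year %in% drought_years & month %in% 6:9
  amt[dry_mod] <- amt[dry_mod] * severity
  tmean[dry_mod] <- tmean[dry_mod] + t_bump
  tmax[dry_mod] <- tmax[dry_mod] + t_bump
  tmin[dry_mod] <- tmin[dry_mod] + t_bump

  rh <- pmin(pmax(72 + stats::rnorm(n, 0, 8) - 8 * dry_mod, 20), 100)
  vpd <- pmax(svp_kpa(tmean) * (1 - rh / 100), 0)

  out <- data.frame(year = year, month = month, day = day, doy = doy,
                    tmin = tmin, tmean = tmean, tmax = tmax, prcp = amt,
                    rh = rh, vpd = vpd)
  class(out) <- c("daily_climate", "data.frame")
  out
}

# deterministic 1..5 family allocation summing to n_fam, then seed-shuffled
alloc_families <- function(n_prov, n_fam) {
  base <- rep(n_fam %/% n_prov, n_prov)
  extra <- n_fam %% n_prov
  if (extra) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  if (any(base < 1) || any(base > 5)) {
    qg_stop("family total not representable with 1-5 families per provenance")
  }
  base
}

#' Generate a randomized complete block design
#'
#' Every family appears once per block as a `trees_per_plot`-tree row-plot;
#' family order within a block is randomized independently per block. Tree
#' coordinates place trees 1.2 m apart within a row and rows 2.4 m apart,
#' blocks side by side. Provenance-origin climate normals (MAT, MAP, ADD,
#' Summer_SMI) are assigned along a joint gradient spanning the provenance
#' range (MAT -1.1 to 5.6 degC, MAP 841-1359 mm) with small seed-controlled
#' jitter, so origin Summer_SMI rankings are monotone along the gradient.
#'
#' @param params a [sim_params()].
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a [design_table()] with the `origins` attribute filled in.
#' @export
gen_design <- function(params, seed = params$seed) {
  set.seed(seed)
  fam_per_prov <- alloc_families(params$n_prov, params$n_fam)
  prov_ids <- sprintf("P%02d", seq_len(params$n_prov))
  fam_prov <- rep(prov_ids, fam_per_prov)
  fam_ids <- sprintf("F%03d", seq_len(params$n_fam))

  rows <- list()
  tree_counter <- 0L
  for (b in seq_len(params$n_blocks)) {
    ord <- sample.int(params$n_fam)
    for (pos in seq_along(ord)) {
      j <- ord[pos]
      k <- seq_len(params$trees_per_plot)
      ids <- sprintf("T%05d", tree_counter + k)
      tree_counter <- tree_counter + params$trees_per_plot
      rows[[length(rows) + 1L]] <- data.frame(
        tree = ids, family = fam_ids[j], provenance = fam_prov[j],
        block = sprintf("B%d", b),
        x = (k - 1) * 1.2,
        y = (b - 1) * (params$n_fam * 2.4 + 10) + (pos - 1) * 2.4)
    }
  }
  x <- do.call(rbind, rows)

  grad <- seq(0, 1, length.out = params$n_prov)
  origins <- data.frame(
    provenance = prov_ids,
    MAT = -1.1 + grad * (5.6 - (-1.1)) + stats::rnorm(params$n_prov, 0, 0.2),
    MAP = 841 + grad * (1359 - 841) + stats::rnorm(params$n_prov, 0, 15),
    ADD = round(250 - grad * 60 + stats::rnorm(params$n_prov, 0, 3)),
    Summer_SMI = 55 + grad * 40  # dry (55%) to humid (95%), strictly monotone
  )
  design_table(x, origins = origins)
}

#' Generate SNP genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniform on (0.1, 0.9); each
#' provenance draws its own frequency from
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` so the expected
#' differentiation equals `F`. Half-sib structure is induced with explicit
#' parent alleles: each family has one mother genotyped from its
#' provenance's frequencies, and every offspring receives one allele sampled
#' from the mother and one from the provenance pollen pool, giving expected
#' within-family relatedness 0.25 while letting realized genomic relatedness
#' vary.
#'
#' @param design a [design_table()].
#' @param n_snps number of SNPs.
#' @param fst target differentiation, `0 <= fst < 1` (0 means panmixia).
#' @param seed RNG seed.
#' @return integer matrix (trees x SNPs), rownames = tree ids.
#' @export
gen_genotypes <- function(design, n_snps, fst, seed = 1) {
  if (fst < 0 || fst >= 1) qg_stop("fst must lie in [0, 1)")
  set.seed(seed)
  provs <- unique(design$provenance)
  p_anc <- stats::runif(n_snps, 0.1, 0.9)
  p_prov <- matrix(NA_real_, length(provs), n_snps,
                   dimnames = list(provs, NULL))
  for (i in seq_along(provs)) {
    p_prov[i, ] <- if (fst == 0) p_anc else
      stats::rbeta(n_snps, p_anc * (1 - fst) / fst,
                   (1 - p_anc) * (1 - fst) / fst)
  }
  fams <- unique(design[c("family", "provenance")])
  mother <- list()
  for (j in seq_len(nrow(fams))) {
    pp <- p_prov[fams$provenance[j], ]
    mother[[fams$family[j]]] <- rbind(stats::rbinom(n_snps, 1, pp),
                                      stats::rbinom(n_snps, 1, pp))
  }
  M <- matrix(NA_integer_, nrow(design), n_snps,
              dimnames = list(design$tree, NULL))
  for (i in seq_len(nrow(design))) {
    mo <- mother[[design$family[i]]]
    pick <- stats::rbinom(n_snps, 1, 0.5)
    a1 <- ifelse(pick == 1, mo[1, ], mo[2, ])
    a2 <- stats::rbinom(n_snps, 1, p_prov[design$provenance[i], ])
    M[i, ] <- a1 + a2
  }
  M
}

#' Generate climate-driven ring series with known ground truth
#'
#' Log ring width per tree-year is a negative-exponential cambial-age trend,
#' plus a common year effect proportional to the standardized summer soil
#' moisture index of the site, plus random population, family, plot,
#' population-by-year and family-by-year effects at the requested variances,
#' plus an AR(rho) tree-level residual. In drought years (and, attenuated,
#' the following year) every tree takes an extra log-scale penalty whose
#' size declines with the dryness of its provenance's origin -- the clinal
#' link `beta` -- so drier-origin provenances are more resistant and more
#' resilient by construction. Tracheid traits are generated with the same
#' family/population structure and a negative wood-density-lumen coupling.
#'
#' @param design a [design_table()] from [gen_design()].
#' @param smi an `smi_series` for the site covering `params$years` (from
#'   [compute_smi()] on generated weather).
#' @param params a [sim_params()].
#' @param seed RNG seed (defaults to `params$seed`).
#' @return list with `rings` (a [ring_set()] carrying RW, WD, CWT, TDr,
#'   TDt) and `truth` (generating parameters plus realized per-level
#'   effects).
#' @export
gen_rings <- function(design, smi, params, seed = params$seed) {
  set.seed(seed)
  years <- params$years
  miss <- setdiff(years, unique(smi$year))
  if (length(miss)) {
    qg_stop(paste("smi does not cover ring years:", paste(miss, collapse = ", ")))
  }
  s <- smi[smi$month %in% 6:8 & smi$year %in% years, ]
  ssmi <- tapply(s$SMI, s$year, mean)[as.character(years)]
  z_smi <- if (stats::sd(ssmi) > 0) (ssmi - mean(ssmi)) / stats::sd(ssmi) else ssmi * 0

  origins <- attr(design, "origins")
  o_smi <- origins$Summer_SMI[match(unique(design$provenance), origins$provenance)]
  names(o_smi) <- unique(design$provenance)
  z_origin <- (o_smi - mean(o_smi)) / stats::sd(o_smi)

  provs <- unique(design$provenance)
  fams <- unique(design$family)
  plots <- unique(paste(design$family, design$block, sep = "/"))
  eff_pop <- stats::setNames(stats::rnorm(length(provs), 0, sqrt(params$sigma2_pop)), provs)
  eff_fam <- stats::setNames(stats::rnorm(length(fams), 0, sqrt(params$sigma2_fam)), fams)
  eff_plot <- stats::setNames(stats::rnorm(length(plots), 0, sqrt(params$sigma2_plot)), plots)
  ny <- length(years)
  eff_py <- matrix(stats::rnorm(length(provs) * ny, 0, sqrt(params$sigma2_pop_year)),
                   length(provs), ny, dimnames = list(provs, years))
  eff_fy <- matrix(stats::rnorm(length(fams) * ny, 0, sqrt(params$sigma2_fam_year)),
                   length(fams), ny, dimnames = list(fams, years))

  # Drought-year dip is common to all provenances; the cline sits in the
  # post-drought recovery deficit, which grows with origin humidity (beta):
  # drier origins rebound faster, so Rl declines with origin Summer_SMI.
  sev_scale <- 1 - params$severity
  dip <- 0.35 * sev_scale
  rec_def <- pmax(0.15 + params$beta * z_origin, 0) * sev_scale
  dry_flag <- as.integer(years %in% params$drought_years)
  carry1 <- c(0, dry_flag[-ny])                    # first post-drought year
  carry2 <- c(0, 0, dry_flag[seq_len(ny - 2)])     # second, attenuated

  age <- seq_len(ny)
  trend <- log(3.5) - 0.025 * age + 0.8 * exp(-age / 4)  # mm, negative exponential
  year_eff <- 0.10 * z_smi

  n_tree <- nrow(design)
  res_sd <- sqrt(params$sigma2_e)
  out <- vector("list", n_tree)
  for (i in seq_len(n_tree)) {
    pr <- design$provenance[i]
    fm <- design$family[i]
    pl <- paste(fm, design$block[i], sep = "/")
    e <- if (res_sd > 0) {
      as.numeric(stats::filter(stats::rnorm(ny, 0, res_sd * sqrt(1 - params$rho^2)),
                               params$rho, method = "recursive"))
    } else numeric(ny)
    lrw <- trend + year_eff + eff_pop[[pr]] + eff_fam[[fm]] + eff_plot[[pl]] +
      eff_py[pr, ] + eff_fy[fm, ] + e -
      dip * dry_flag - rec_def[[pr]] * (carry1 + 0.5 * carry2)
    rw <- exp(lrw)
    # tracheid traits: shared genetic structure, WD-lumen trade-off
    g_i <- eff_pop[[pr]] + eff_fam[[fm]]
    ld_lat <- 28 + 25 * g_i + 1.5 * z_smi + stats::rnorm(ny, 0, 1.2)
    cwt <- pmax(2.6 - 0.02 * (ld_lat - 28) + stats::rnorm(ny, 0, 0.15), 0.8)
    wd <- 420 - 6 * (ld_lat - 28) + 150 * cwt / ld_lat + stats::rnorm(ny, 0, 12)
    out[[i]] <- data.frame(tree = design$tree[i], year = years, RW = rw,
                           WD = wd, CWT = cwt,
                           TDr = ld_lat + cwt + abs(stats::rnorm(ny, 1.5, 0.3)),
                           TDt = ld_lat + cwt + abs(stats::rnorm(ny, 1.5, 0.3)))
  }
  rings <- ring_set(do.call(rbind, out))
  truth <- list(params = params, seed = seed,
                eff_pop = eff_pop, eff_fam = eff_fam, eff_plot = eff_plot,
                dip = dip, rec_def = rec_def, z_origin = z_origin,
                year_eff = year_eff, summer_smi = ssmi)
  list(rings = rings, truth = truth)
}

#' Simulate a complete common-garden dataset
#'
#' Convenience wrapper: weather for the ring years (plus two lead years for
#' bucket spin-up), monthly aggregation and soil moisture, the block design,
#' genotypes, and ring series. Everything is reproducible from
#' `(params, seed)`; the ground truth is returned alongside.
#'
#' @param params a [sim_params()].
#' @return list `design`, `daily`, `monthly`, `smi`, `rings`, `genotypes`,
#'   `truth`.
#' @export
simulate_trial <- function(params = sim_params()) {
  wx_years <- (min(params$years) - 2):max(params$years)
  daily <- gen_weather(wx_years, seed = params$seed,
                       drought_years = params$drought_years,
                       severity = params$severity)
  monthly <- aggregate_monthly(daily)
  smi <- compute_smi(monthly)
  design <- gen_design(params)
  geno <- gen_genotypes(design, params$n_snps, params$fst,
                        seed = params$seed + 1L)
  rg <- gen_rings(design, smi, params, seed = params$seed + 2L)
  list(design = design, daily = daily, monthly = monthly, smi = smi,
       rings = rg$rings, genotypes = geno, truth = rg$truth)
}
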