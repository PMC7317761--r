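#' Aggregate daily weather to monthly climate
#'
#' Temperatures, relative humidity and vapour-pressure deficit are averaged;
#' precipitation is summed; `dry_days` counts days with precipitation below
#' 0.2 mm (the building block of the annual dry-day count ADD). Each month in
#' the record must be complete.
#'
#' @param daily data.frame with columns `year`, `month`, `day`, `tmin`,
#'   `tmean`, `tmax`, `prcp`, and optionally `rh`, `vpd`.
#' @return data.frame of class `monthly_climate`: `year`, `month`, `tmin`,
#'   `tmean`, `tmax`, `prcp`, `rh`, `vpd`, `dry_days`, `n_days`.
#' @export
aggregate_monthly <- function(daily) {
  need <- c("year", "month", "day", "tmin", "tmean", "tmax", "prcp")
  miss <- setdiff(need, names(daily))
  if (length(miss)) qg_stop(paste("daily: missing columns:", paste(miss, collapse = ", ")))
  dim_tab <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) # fixed 365-day years
  key <- interaction(daily$year, daily$month, drop = TRUE)
  cnt <- tapply(daily$day, key, length)
  exp_n <- dim_tab[as.integer(sub(".*\\.", "", names(cnt)))]
  short <- names(cnt)[cnt < exp_n]
  if (length(short)) {
    qg_stop(paste("incomplete months (year.month):", paste(short, collapse = ", ")),
            class = "dendroQG_missing_days")
  }
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  out <- data.frame(
    year = as.integer(tapply(daily$year, key, `[`, 1)),
    month = as.integer(tapply(daily$month, key, `[`, 1)),
    tmin = agg(daily$tmin, mean),
    tmean = agg(daily$tmean, mean),
    tmax = agg(daily$tmax, mean),
    prcp = agg(daily$prcp, sum),
    rh = if ("rh" %in% names(daily)) agg(daily$rh, mean) else NA_real_,
    vpd = if ("vpd" %in% names(daily)) agg(daily$vpd, mean) else NA_real_,
    dry_days = as.integer(tapply(daily$prcp < 0.2, key, sum)),
    n_days = as.integer(cnt)
  )
  out <- out[order(out$year, out$month), ]
  rownames(out) <- NULL
  class(out) <- c("monthly_climate", "data.frame")
  out
}

#' Potential evapotranspiration, simplified Penman-Monteith
#'
#' A closed-form reduction of Penman-Monteith for when radiation and wind
#' inputs are unavailable: daily PET is proportional to vapour-pressure
#' deficit weighted by the fraction of available energy partitioned to
#' evaporation, `delta / (delta + gamma)`, where `delta` is the slope of the
#' saturation vapour-pressure curve at air temperature and `gamma` the
#' psychrometric constant (0.066 kPa/degC). The proportionality constant
#' `alpha` (mm/day/kPa) absorbs the canopy and aerodynamic terms. PET is zero
#' at or below freezing.
#'
#' @param tmean mean air temperature, degC.
#' @param vpd vapour-pressure deficit, kPa (>= 0).
#' @param alpha canopy-aerodynamic constant, mm/day/kPa; the default 5 gives
#'   mid-summer monthly PET near 100 mm under humid-continental conditions.
#' @return daily PET in mm/day.
#' @export
pet_pm <- function(tmean, vpd, alpha = 5) {
  gamma <- 0.066
  delta <- 4098 * svp_kpa(tmean) / (tmean + 237.3)^2
  pet <- alpha * pmax(vpd, 0) * delta / (delta + gamma)
  ifelse(tmean <= 0, 0, pet)
}

#' Soil moisture index from a monthly water-balance bucket
#'
#' Monthly recursion of plant-available soil water `W` in a bucket of
#' capacity `w_max`: gains are monthly precipitation (snow accumulated in
#' months with mean temperature below 0 degC is delivered at the first
#' subsequent above-freezing month), losses are actual evapotranspiration
#' `AET = PET * g(W)`, with PET from [pet_pm()] and the drawdown function `g`
#' quadratic below the critical store `w_crit` --
#' `g(W) = 2(W/w_crit) - (W/w_crit)^2` -- and 1 (energy-limited, linear
#' regime) above it. With the default `w_crit` (400 mm) above `w_max`
#' (300 mm) the store never leaves the quadratic regime. `W` is clamped to
#' `[0, w_max]` with the clipped surplus recorded as overflow, so the mass
#' balance `sum(dW) = sum(gain) - sum(AET) - sum(overflow)` closes exactly.
#' SMI is the store as a percentage of capacity.
#'
#' @param monthly a `monthly_climate` table (needs `tmean`, `prcp`, `vpd`).
#' @param w_max bucket capacity, mm (> 0).
#' @param w_crit critical store of the drawdown function, mm (> 0).
#' @param w_init initial store, mm; defaults to a full bucket.
#' @param snow if `TRUE` (default), sub-zero months bank their precipitation
#'   as snowpack released at the next above-zero month; if `FALSE`
#'   precipitation always enters the bucket immediately.
#' @return data.frame of class `smi_series`: `year`, `month`, `W` (mm),
#'   `SMI` (%), plus bookkeeping columns `gain`, `aet`, `overflow` (mm).
#' @export
compute_smi <- function(monthly, w_max = 300, w_crit = 400,
                        w_init = w_max, snow = TRUE) {
  if (w_max <= 0 || w_crit <= 0) qg_stop("w_max and w_crit must be positive")
  check_complete_months(monthly)
  m <- monthly[order(monthly$year, monthly$month), ]
  n <- nrow(m)
  W <- numeric(n); gain <- numeric(n); aet <- numeric(n); over <- numeric(n)
  w_prev <- min(max(w_init, 0), w_max)
  pack <- 0
  g <- function(w) {
    x <- pmin(w / w_crit, 1)
    2 * x - x^2
  }
  vpd <- if (all(is.na(m$vpd))) pmax(svp_kpa(m$tmean) * 0.3, 0) else m$vpd
  for (i in seq_len(n)) {
    pet_m <- pet_pm(m$tmean[i], vpd[i]) * m$n_days[i]
    if (snow && m$tmean[i] < 0) {
      pack <- pack + m$prcp[i]
      gain[i] <- 0
    } else {
      gain[i] <- m$prcp[i] + pack
      pack <- 0
    }
    aet[i] <- min(pet_m * g(w_prev), w_prev + gain[i])
    w_new <- w_prev + gain[i] - aet[i]
    over[i] <- max(w_new - w_max, 0)
    W[i] <- min(max(w_new, 0), w_max)
    w_prev <- W[i]
  }
  out <- data.frame(year = m$year, month = m$month, W = W,
                    SMI = 100 * W / w_max, gain = gain, aet = aet,
                    overflow = over)
  attr(out, "w_max") <- w_max
  attr(out, "w_crit") <- w_crit
  attr(out, "w_init") <- w_init
  class(out) <- c("smi_series", "data.frame")
  out
}

#' Per-location annual climate normals
#'
#' MAT is the mean of monthly mean temperatures, MAP the mean annual
#' precipitation total, ADD the mean annual count of days with precipitation
#' below 0.2 mm, and Summer_SMI the June-August mean of the soil moisture
#' index, all averaged over `period`.
#'
#' @param monthly a `monthly_climate` table.
#' @param smi matching `smi_series` from [compute_smi()]; if `NULL`,
#'   `Summer_SMI` is `NA`.
#' @param period integer years to average over; defaults to all years present.
#' @return one-row data.frame: `MAT`, `MAP`, `ADD`, `Summer_SMI`.
#' @export
annual_normals <- function(monthly, smi = NULL, period = NULL) {
  if (is.null(period)) period <- sort(unique(monthly$year))
  m <- monthly[monthly$year %in% period, ]
  if (!nrow(m)) qg_stop("empty averaging period")
  ann_prcp <- tapply(m$prcp, m$year, sum)
  ann_dry <- tapply(m$dry_days, m$year, sum)
  ssmi <- NA_real_
  if (!is.null(smi)) {
    s <- smi[smi$year %in% period & smi$month %in% 6:8, ]
    ssmi <- mean(s$SMI)
  }
  data.frame(MAT = mean(tapply(m$tmean, m$year, mean)),
             MAP = mean(ann_prcp), ADD = mean(ann_dry), Summer_SMI = ssmi)
}

#' Summer anomaly ratios
#'
#' Per-year ratio of the June-August mean of a monthly series to its mean
#' over a baseline period; 1 means a normal summer, values below 1 a deficit.
#'
#' @param monthly data.frame with `year`, `month` and the column `var`.
#' @param var name of the column to summarize (e.g. `"SMI"`, `"prcp"`).
#' @param baseline integer years defining the long-term mean; defaults to all
#'   years present.
#' @return data.frame `year`, `summer_mean`, `ratio`.
#' @export
summer_anomaly <- function(monthly, var = "SMI", baseline = NULL) {
  s <- monthly[monthly$month %in% 6:8, c("year", var)]
  sm <- tapply(s[[var]], s$year, mean)
  yrs <- as.integer(names(sm))
  if (is.null(baseline)) baseline <- yrs
  base <- mean(sm[yrs %in% baseline])
  if (!is.finite(base) || base == 0) {
    qg_stop("baseline summer mean is zero or undefined")
  }
  data.frame(year = yrs, summer_mean = as.numeric(sm),
             ratio = as.numeric(sm) / base, row.names = NULL)
}

#' Detect drought events from summer anomaly ratios
#'
#' Years whose anomaly ratio falls below a low quantile of the ratio
#' distribution are flagged; runs of consecutive flagged years are merged
#' into one event dated at the run's final year (so a two-year dry spell is
#' indexed at its second year). Because flags are defined by a quantile of
#' the ratios, detection is invariant to affine rescaling of the baseline.
#'
#' @param anomalies output of [summer_anomaly()].
#' @param quantile flagging quantile of the ratio distribution (default
#'   0.15).
#' @param threshold optional absolute ratio cutoff applied in addition to the
#'   quantile rule (flag only years with `ratio < threshold`); `NULL` to
#'   disable.
#' @return integer vector of event years (possibly empty).
#' @export
detect_droughts <- function(anomalies, quantile = 0.15, threshold = NULL) {
  if (nrow(anomalies) < 5) qg_stop("need at least 5 years of anomalies")
  q <- stats::quantile(anomalies$ratio, quantile, names = FALSE)
  flag <- anomalies$ratio <= q
  if (!is.null(threshold)) flag <- flag & anomalies$ratio < threshold
  # degenerate flat series: nothing stands out
  if (stats::sd(anomalies$ratio) == 0) return(integer(0))
  yrs <- sort(anomalies$year[flag])
  if (!length(yrs)) return(integer(0))
  run_end <- yrs[c(diff(yrs) != 1L, TRUE)]
  as.integer(run_end)
}
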