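# The dendroclimatic month window: May of the previous year through October
# of the current year, 18 slots.
window_slots <- function() {
  data.frame(
    slot = 1:18,
    rel_year = c(rep(-1L, 8), rep(0L, 10)),
    month = c(5:12, 1:10),
    label = c(paste0("prev-", month.abb[5:12]), paste0("curr-", month.abb[1:10]))
  )
}

# climate matrix: rows = chronology years, cols = the 18 window slots
window_matrix <- function(monthly, var, years) {
  ws <- window_slots()
  m <- matrix(NA_real_, length(years), nrow(ws),
              dimnames = list(years, ws$label))
  for (j in seq_len(nrow(ws))) {
    yy <- years + ws$rel_year[j]
    idx <- match(paste(yy, ws$month[j]), paste(monthly$year, monthly$month))
    m[, j] <- monthly[[var]][idx]
  }
  m
}

# stationary bootstrap indices (Politis-Romano): geometric block lengths
stationary_boot_idx <- function(n, mean_block = 4) {
  p <- 1 / mean_block
  idx <- integer(n)
  i <- sample.int(n, 1)
  for (t in seq_len(n)) {
    idx[t] <- i
    i <- if (stats::runif(1) < p) sample.int(n, 1) else (i %% n) + 1L
  }
  idx
}

#' Monthly climate-growth correlations
#'
#' Pearson correlations between a (typically residual) chronology and each
#' monthly climate slot in the 18-month window from May of the previous year
#' to October of the current year. Significance comes from a stationary
#' bootstrap over years (geometric blocks, mean length `mean_block`): a slot
#' is flagged when the 95% percentile interval of the bootstrapped
#' correlation excludes zero. A parametric two-sided p-value is emitted
#' alongside for cross-checking.
#'
#' @param chron data.frame `year`, `mean` (one chronology).
#' @param monthly a `monthly_climate` or `smi_series` table.
#' @param var climate column name (e.g. `"SMI"`, `"prcp"`, `"tmax"`).
#' @param n_boot bootstrap iterations (default 1000).
#' @param mean_block mean bootstrap block length, years (default 4).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return data.frame with one row per window slot: `label`, `r`, `ci_lo`,
#'   `ci_hi`, `sig_boot`, `p_param`, `sig_param`.
#' @export
monthly_correlations <- function(chron, monthly, var, n_boot = 1000,
                                 mean_block = 4, seed = 1) {
  years <- sort(chron$year)
  if (length(years) < 15) qg_stop("need at least 15 overlapping years")
  y <- chron$mean[order(chron$year)]
  cm <- window_matrix(monthly, var, years)
  keep <- rowSums(is.na(cm)) == 0 & is.finite(y)
  if (sum(keep) < 15) qg_stop("need at least 15 overlapping years")
  y <- y[keep]; cm <- cm[keep, , drop = FALSE]
  n <- length(y)
  # slots with a constant climate series (e.g. a saturated winter soil
  # store) have undefined correlation and are reported as NA, unflagged
  r <- suppressWarnings(as.numeric(stats::cor(y, cm)))
  set.seed(seed)
  boot_r <- matrix(NA_real_, n_boot, ncol(cm))
  for (b in seq_len(n_boot)) {
    idx <- stationary_boot_idx(n, mean_block)
    yb <- y[idx]
    if (stats::sd(yb) == 0) next
    boot_r[b, ] <- suppressWarnings(as.numeric(stats::cor(yb, cm[idx, , drop = FALSE])))
  }
  ci <- suppressWarnings(apply(boot_r, 2, function(v) {
    if (all(is.na(v))) c(NA_real_, NA_real_) else
      stats::quantile(v, c(0.025, 0.975), na.rm = TRUE)
  }))
  p_param <- vapply(seq_len(ncol(cm)), function(j) {
    if (!is.finite(r[j]) || stats::sd(cm[, j]) == 0) return(NA_real_)
    stats::cor.test(y, cm[, j])$p.value
  }, numeric(1))
  out <- window_slots()["label"]
  out$r <- r
  out$ci_lo <- ci[1, ]
  out$ci_hi <- ci[2, ]
  out$sig_boot <- is.finite(out$ci_lo) & (out$ci_lo > 0 | out$ci_hi < 0)
  out$p_param <- p_param
  out$sig_param <- !is.na(p_param) & p_param < 0.05
  out
}

#' Climate-sensitivity traits per provenance
#'
#' For a chosen climate variable and window slot, the per-provenance Pearson
#' correlation between each provenance's mean residual chronology and that
#' month's climate series. The resulting vector of correlations is itself a
#' trait ("climate sensitivity") usable in downstream clinal analysis.
#'
#' @param chrons data.frame `group`, `year`, `mean` (one chronology per
#'   provenance, as from [build_chronology()]).
#' @param monthly climate table containing `var`.
#' @param var climate column name.
#' @param slot_label window slot, e.g. `"curr-Jul"` (see the 18-slot window
#'   of [monthly_correlations()]).
#' @return data.frame `group`, `r`, `n`, `flag`.
#' @export
climate_sensitivity <- function(chrons, monthly, var, slot_label = "curr-Jul") {
  ws <- window_slots()
  if (!slot_label %in% ws$label) qg_stop(paste("unknown window slot:", slot_label))
  out <- lapply(split(chrons, chrons$group), function(g) {
    years <- sort(g$year)
    if (length(years) < 15) {
      return(data.frame(r = NA_real_, n = length(years), flag = "short overlap"))
    }
    cm <- window_matrix(monthly, var, years)[, slot_label]
    y <- g$mean[order(g$year)]
    ok <- is.finite(y) & is.finite(cm)
    if (sum(ok) < 15) {
      return(data.frame(r = NA_real_, n = sum(ok), flag = "short overlap"))
    }
    if (stats::sd(y[ok]) == 0 || stats::sd(cm[ok]) == 0) {
      return(data.frame(r = NA_real_, n = sum(ok), flag = "constant series"))
    }
    data.frame(r = stats::cor(y[ok], cm[ok]), n = sum(ok), flag = "")
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}
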