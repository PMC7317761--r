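#' Convert ring widths to basal area increments
#'
#' Assuming circular stems measured from the pith outward, the cumulative
#' radius after year t is the running sum of ring widths, and the basal area
#' increment is the annular area added that year,
#' `BAI_t = pi * (R_t^2 - R_(t-1)^2)` (mm^2). The conversion telescopes:
#' the BAI sum equals the total basal area `pi * R_n^2`, and is exactly
#' invertible back to ring widths given `R_0 = 0`.
#'
#' @param rings a [ring_set()] (contiguous `RW` from the innermost ring).
#' @return data.frame `tree`, `year`, `BAI` (mm^2).
#' @export
rw_to_bai <- function(rings) {
  if (any(rings$RW <= 0)) qg_stop("ring widths must be positive")
  parts <- lapply(split(rings[c("tree", "year", "RW")], rings$tree), function(df) {
    df <- df[order(df$year), ]
    r <- cumsum(df$RW)
    data.frame(tree = df$tree, year = df$year,
               BAI = pi * (r^2 - c(0, r[-length(r)])^2))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Derived tracheid traits
#'
#' Lumen diameters are tracheid diameters minus the cell-wall thickness:
#' `LDr = TDr - CWT`, `LDt = TDt - CWT`, averaged to `LD`. Conduit wall
#' reinforcement -- a proxy for xylem resistance to drought-induced embolism
#' -- follows the (t/b)^2 convention of squaring the wall-to-lumen span
#' ratio: with the default double-wall numerator,
#' `CWRr = (2 * CWT / LDr)^2`, likewise tangentially, averaged to `CWR`.
#' CWR is dimensionless and invariant to rescaling all lengths.
#'
#' @param rings a [ring_set()] carrying `TDr`, `TDt`, `CWT` (um).
#' @param wall `"double"` (default) or `"single"`: whether the squared
#'   numerator is `2*CWT` or `CWT`.
#' @return the input with columns `LDr`, `LDt`, `LD`, `CWRr`, `CWRt`, `CWR`
#'   appended.
#' @export
derive_tracheid <- function(rings, wall = c("double", "single")) {
  wall <- match.arg(wall)
  need <- c("TDr", "TDt", "CWT")
  miss <- setdiff(need, names(rings))
  if (length(miss)) qg_stop(paste("missing tracheid columns:", paste(miss, collapse = ", ")))
  bad <- which(rings$CWT >= pmin(rings$TDr, rings$TDt))
  if (length(bad)) {
    qg_stop(sprintf("CWT >= tracheid diameter at ring(s): %s",
                    paste(sprintf("%s/%d", rings$tree[bad], rings$year[bad])[
                      seq_len(min(5, length(bad)))], collapse = ", ")))
  }
  k <- if (wall == "double") 2 else 1
  rings$LDr <- rings$TDr - rings$CWT
  rings$LDt <- rings$TDt - rings$CWT
  rings$LD <- (rings$LDr + rings$LDt) / 2
  rings$CWRr <- (k * rings$CWT / rings$LDr)^2
  rings$CWRt <- (k * rings$CWT / rings$LDt)^2
  rings$CWR <- (rings$CWRr + rings$CWRt) / 2
  rings
}

#' Expressed population signal
#'
#' `EPS = N * rbar / (1 + (N - 1) * rbar)`: how faithfully a mean chronology
#' of N series with mean inter-series correlation `rbar` represents the
#' hypothetical population chronology. Monotone increasing in both arguments.
#'
#' @param n number of series.
#' @param rbar mean pairwise inter-series correlation.
#' @return EPS in `[0, 1]` (for `rbar >= 0`).
#' @export
eps_signal <- function(n, rbar) {
  n * rbar / (1 + (n - 1) * rbar)
}

#' Build mean chronologies per group
#'
#' Arithmetic group-year means of a per-tree value (typically prewhitened
#' residuals), with sample depth, the mean pairwise inter-series correlation
#' `rbar` over common years, and the expressed population signal per group.
#' Groups with a single tree have undefined `rbar`/EPS and are flagged.
#'
#' @param x data.frame with columns `tree`, `year`, and the value column.
#' @param group vector (length `nrow(x)`) of group labels, e.g. provenance.
#' @param value name of the value column (default `"value"`).
#' @return list with `chronology` (group, year, mean, depth) and `stats`
#'   (group, n_trees, rbar, eps, flagged).
#' @export
build_chronology <- function(x, group, value = "value") {
  if (!value %in% names(x)) qg_stop(paste("no column", value))
  x$group <- as.character(group)
  chron <- stats::aggregate(x[[value]], by = list(group = x$group, year = x$year),
                            FUN = mean)
  names(chron)[3] <- "mean"
  depth <- stats::aggregate(x[[value]], by = list(group = x$group, year = x$year),
                            FUN = length)
  chron$depth <- depth$x
  chron <- chron[order(chron$group, chron$year), ]
  rownames(chron) <- NULL
  stats_ls <- lapply(split(x, x$group), function(g) {
    wide <- stats::reshape(g[c("tree", "year", value)], direction = "wide",
                           idvar = "year", timevar = "tree")
    m <- as.matrix(wide[-1])
    n <- ncol(m)
    if (n < 2) {
      return(data.frame(n_trees = n, rbar = NA_real_, eps = NA_real_,
                        flagged = TRUE))
    }
    cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    rbar <- mean(cc[upper.tri(cc)], na.rm = TRUE)
    data.frame(n_trees = n, rbar = rbar, eps = eps_signal(n, rbar),
               flagged = FALSE)
  })
  st <- do.call(rbind, stats_ls)
  st <- cbind(group = names(stats_ls), st)
  rownames(st) <- NULL
  list(chronology = chron, stats = st)
}

#' Simplified cross-dating check
#'
#' A light surrogate for segment-based dating programs: each series is
#' first-differenced (a cheap prewhitening that removes trend and most
#' persistence), then correlated against the leave-one-out master chronology
#' at lags within `max_lag` years. Series whose lag-0 correlation falls below
#' `threshold`, or whose best lag is non-zero, are flagged for inspection;
#' series with insufficient overlap are flagged, not failed.
#'
#' @param rings a [ring_set()].
#' @param value column to date on (default `"RW"`).
#' @param threshold flagging correlation (default 0.32, the conventional
#'   99% one-tailed critical value for 50-year segments).
#' @param max_lag maximum dating offset examined, years (default 3).
#' @param min_overlap minimum overlap with the master, years (default 15).
#' @return data.frame `tree`, `r0` (lag-0 correlation), `best_lag`,
#'   `r_best`, `n_overlap`, `flag`, `reason`.
#' @export
crossdate_check <- function(rings, value = "RW", threshold = 0.32,
                            max_lag = 3, min_overlap = 15) {
  yrs <- sort(unique(rings$year))
  wide <- matrix(NA_real_, length(yrs), length(unique(rings$tree)),
                 dimnames = list(yrs, unique(rings$tree)))
  wide[cbind(match(rings$year, yrs), match(rings$tree, colnames(wide)))] <-
    rings[[value]]
  dw <- apply(wide, 2, function(v) c(NA, diff(v)))   # first-difference prewhitening
  out <- lapply(colnames(dw), function(id) {
    x <- dw[, id]
    master <- rowMeans(dw[, colnames(dw) != id, drop = FALSE], na.rm = TRUE)
    ok <- is.finite(x) & is.finite(master)
    if (sum(ok) < min_overlap) {
      return(data.frame(tree = id, r0 = NA_real_, best_lag = NA_integer_,
                        r_best = NA_real_, n_overlap = sum(ok), flag = TRUE,
                        reason = "insufficient overlap"))
    }
    lags <- -max_lag:max_lag
    rl <- vapply(lags, function(l) {
      xi <- seq_along(x) + l
      keep <- xi >= 1 & xi <= length(x)
      a <- x[xi[keep]]; b <- master[keep]
      use <- is.finite(a) & is.finite(b)
      if (sum(use) < min_overlap || stats::sd(a[use]) == 0 || stats::sd(b[use]) == 0) {
        return(NA_real_)
      }
      stats::cor(a[use], b[use])
    }, numeric(1))
    if (all(is.na(rl))) {
      return(data.frame(tree = id, r0 = NA_real_, best_lag = NA_integer_,
                        r_best = NA_real_, n_overlap = sum(ok), flag = TRUE,
                        reason = "degenerate series"))
    }
    r0 <- rl[lags == 0]
    # report the correction to apply: a series recorded one year late (+1 shift)
    # aligns after shifting its year labels by -1
    best <- -lags[which.max(rl)]
    low <- is.na(r0) || r0 < threshold
    misdated <- !is.na(best) && best != 0 && max(rl, na.rm = TRUE) > r0 + 0.05
    data.frame(tree = id, r0 = r0, best_lag = as.integer(best),
               r_best = max(rl, na.rm = TRUE), n_overlap = sum(ok),
               flag = low || misdated,
               reason = if (low) "low correlation" else if (misdated) "lag offset" else "")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
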