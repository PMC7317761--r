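#' Hegyi-type competition index
#'
#' For each subject tree, the sum over neighbours within `radius` metres of
#' the neighbour-to-subject size ratio divided by their distance:
#' `CI_i = sum_j (size_j / size_i) / d_ij`. Larger, closer neighbours press
#' harder; an isolated tree scores 0.
#'
#' @param design a [design_table()] (uses planting coordinates `x`, `y`).
#' @param sizes named numeric vector of tree sizes (names = tree ids), e.g.
#'   cumulative basal area in a given year.
#' @param radius neighbourhood radius in metres (default 3.6, three planting
#'   spacings of 1.2 m).
#' @return data.frame `tree`, `ci`.
#' @export
competition_index <- function(design, sizes, radius = 3.6) {
  if (any(!is.finite(design$x)) || any(!is.finite(design$y))) {
    qg_stop("missing planting coordinates")
  }
  idx <- match(design$tree, names(sizes))
  if (anyNA(idx)) qg_stop("sizes missing for some design trees")
  s <- as.numeric(sizes[idx])
  d <- as.matrix(stats::dist(design[c("x", "y")]))
  ci <- vapply(seq_len(nrow(design)), function(i) {
    nb <- which(d[i, ] <= radius & d[i, ] > 0)
    if (!length(nb)) return(0)
    sum((s[nb] / s[i]) / d[i, nb])
  }, numeric(1))
  data.frame(tree = design$tree, ci = ci)
}

#' Step 1 of standardization: remove non-climatic trends
#'
#' Fits an additive model of a ring trait on cambial age, cumulative tree
#' basal area, and (optionally) a competition index, each as a penalized
#' regression spline with smoothness chosen by generalized cross-validation.
#' The residuals (response-scale: observed minus fitted) carry the
#' year-to-year climate signal onward; the fitted trend and effective degrees
#' of freedom are reported.
#'
#' @param x data.frame with columns `tree`, `year`, the response, and the
#'   covariates.
#' @param trait name of the response column.
#' @param covariates character vector of covariate columns (default
#'   `c("age", "ba")`; add `"ci"` when a competition index is present).
#' @param k spline basis dimension per covariate (default 10).
#' @return list with `data` (input plus `fitted`, `residual`), `edf` (named
#'   effective degrees of freedom), and the `gam` fit.
#' @export
fit_trend <- function(x, trait, covariates = c("age", "ba"), k = 10) {
  miss <- setdiff(c(trait, covariates), names(x))
  if (length(miss)) qg_stop(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(x) < 30) qg_stop("need at least 30 observations to fit smooths")
  if (stats::sd(x[[trait]]) == 0) {
    x$fitted <- x[[trait]]
    x$residual <- 0
    return(list(data = x, edf = stats::setNames(rep(0, length(covariates)),
                                                covariates), fit = NULL))
  }
  usable <- covariates[vapply(covariates, function(v) {
    length(unique(x[[v]])) > 3
  }, logical(1))]
  dropped <- setdiff(covariates, usable)
  if (length(dropped)) {
    warning("dropping near-constant covariate(s): ", paste(dropped, collapse = ", "))
  }
  if (!length(usable)) qg_stop("no usable covariates (all near-constant)")
  terms <- vapply(usable, function(v) {
    kk <- min(k, length(unique(x[[v]])) - 1)
    sprintf("s(%s, k = %d)", v, kk)
  }, character(1))
  fml <- stats::as.formula(paste(trait, "~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, data = x, method = "GCV.Cp")
  x$fitted <- as.numeric(stats::fitted(fit))
  x$residual <- x[[trait]] - x$fitted
  edf <- stats::setNames(summary(fit)$edf, usable)
  list(data = x, edf = edf, fit = fit)
}

#' Step 2 of standardization: autoregressive prewhitening
#'
#' Removes serial persistence from each tree's step-1 residual series by
#' fitting an AR(p) model per series with the order chosen by AIC over
#' `0..p_max`, and keeping the innovations. Innovations are mean-centred and
#' rescaled to the input series' variance so chronologies built from either
#' series are on a comparable scale. Constant series are degenerate and
#' flagged; series shorter than `min_years` are skipped.
#'
#' @param x data.frame with columns `tree`, `year`, and the residual column.
#' @param value name of the residual column (default `"residual"`).
#' @param p_max maximum AR order considered (default 3).
#' @param min_years minimum series length (default 15).
#' @return data.frame `tree`, `year`, input value, `p` (chosen order),
#'   `white` (prewhitened value, NA where undefined), `flag`.
#' @export
prewhiten <- function(x, value = "residual", p_max = 3, min_years = 15) {
  parts <- lapply(split(x, x$tree), function(df) {
    df <- df[order(df$year), ]
    v <- df[[value]]
    out <- data.frame(tree = df$tree, year = df$year, input = v,
                      p = NA_integer_, white = NA_real_, flag = "")
    if (length(v) < min_years) {
      out$flag <- "too short"
      return(out)
    }
    if (stats::sd(v) == 0) {
      out$flag <- "constant"
      return(out)
    }
    fit <- try(stats::ar(v, aic = TRUE, order.max = p_max, method = "yule-walker"),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      out$flag <- "ar fit failed"
      return(out)
    }
    p <- fit$order
    innov <- as.numeric(fit$resid)
    innov <- innov - mean(innov, na.rm = TRUE)
    s_in <- stats::sd(v)
    s_out <- stats::sd(innov, na.rm = TRUE)
    if (is.finite(s_out) && s_out > 0) innov <- innov * s_in / s_out
    out$p <- p
    out$white <- innov
    out
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Full two-step standardization of a ring trait
#'
#' Convenience wrapper chaining [fit_trend()] and [prewhiten()]: computes
#' cambial age and cumulative basal area per tree, optionally a competition
#' index, removes the non-climatic trend, prewhitens the residuals, and
#' drops years before `cut_year` (juvenile phase) from the output.
#'
#' @param rings a [ring_set()].
#' @param design a [design_table()] (needed when `use_competition` is TRUE).
#' @param trait response column (default `"RW"`).
#' @param cut_year first year retained in the standardized output (default
#'   1989); use `-Inf` to keep everything.
#' @param use_competition include a Hegyi competition index covariate.
#' @param p_max maximum AR order for prewhitening.
#' @return data.frame `tree`, `year`, raw value, `fitted`, `residual`, `p`,
#'   `white`.
#' @export
standardize_rings <- function(rings, design = NULL, trait = "RW",
                              cut_year = 1989, use_competition = FALSE,
                              p_max = 3) {
  x <- as.data.frame(rings)
  fy <- first_ring_year(rings)
  x$age <- x$year - fy[x$tree] + 1L
  ba <- lapply(split(x, x$tree), function(df) {
    df <- df[order(df$year), ]
    df$ba <- pi * cumsum(df$RW)^2
    df
  })
  x <- do.call(rbind, ba)
  covs <- c("age", "ba")
  if (use_competition) {
    if (is.null(design)) qg_stop("design required for the competition index")
    med_year <- as.integer(stats::median(x$year))
    sz <- x[x$year == med_year, ]
    ci <- competition_index(design[design$tree %in% sz$tree, ],
                            stats::setNames(sz$ba, sz$tree))
    x$ci <- ci$ci[match(x$tree, ci$tree)]
    covs <- c(covs, "ci")
  }
  st1 <- fit_trend(x, trait, covariates = covs)
  st2 <- prewhiten(st1$data, value = "residual", p_max = p_max)
  out <- merge(st1$data[c("tree", "year", trait, "fitted", "residual")],
               st2[c("tree", "year", "p", "white")], by = c("tree", "year"))
  out <- out[out$year >= cut_year & !is.na(out$white), ]
  out <- out[order(out$tree, out$year), ]
  rownames(out) <- NULL
  out
}
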