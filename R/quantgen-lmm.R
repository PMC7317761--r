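#' REML variance components for common-garden mixed models
#'
#' Fits the two model shapes used for provenance-trial ring data by REML:
#'
#' * the single-record model for per-tree indices (e.g. drought-resilience
#'   traits): fixed block and tree-size effects plus random provenance,
#'   family-within-provenance, and family-by-block (plot) effects with
#'   independent residuals;
#' * the repeated-measures model for annual traits: fixed year and
#'   block-within-year effects, random provenance, family, provenance-by-year
#'   and family-by-year effects, plot effects, and within-tree residuals
#'   correlated across years.
#'
#' The caller chooses terms by naming data columns. `random` entries may be
#' interactions written `"a:b"`. The residual structure is `"independent"`,
#' `"AR1"` (within-tree first-order autoregressive correlation with a common
#' variance, represented as an `ar1` within-tree term plus an independent
#' nugget), or `"ARH1"` (the AR1 correlation combined with year-specific
#' residual variances via the dispersion model -- a heterogeneous-variance
#' autoregressive structure). Variances are estimated on the log-standard-
#' deviation scale so they are bounded at zero by construction; asymptotic
#' standard errors and the covariance of the variance estimates come from the
#' observed information at the optimum, delta-transformed to the variance
#' scale.
#'
#' @param data data.frame of one record per tree (or per tree-year).
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect terms (model-formula syntax,
#'   e.g. `c("block", "tree_size")`); `NULL` for intercept only.
#' @param random character vector of random grouping columns, e.g.
#'   `c("provenance", "family", "plot")` or with `"provenance:year"`.
#' @param residual residual structure (see above).
#' @param year,tree column names used by the autoregressive structures.
#' @param reml use REML (default) or ML.
#' @return object of class `var_comp`: list with `components` (named
#'   variances; autoregressive fits add `residual_ar` and `residual_nugget`
#'   plus their sum `residual`), `se`, `vcov` (variance-scale covariance of
#'   the named components), `rho` (AR correlation or `NA`), `sigma2_year`
#'   (year-specific residual variances for ARH1), `logLik`, `fixef`,
#'   `convergence`, and the underlying `fit`.
#' @export
fit_lmm <- function(data, response, fixed = NULL,
                    random = c("provenance", "family"),
                    residual = c("independent", "AR1", "ARH1"),
                    year = "year", tree = "tree", reml = TRUE) {
  residual <- match.arg(residual)
  d <- as.data.frame(data)
  if (!response %in% names(d)) qg_stop(paste("no response column", response))
  if (stats::var(d[[response]], na.rm = TRUE) == 0) {
    # degenerate: nothing to partition
    comps <- stats::setNames(rep(0, length(random) + 1),
                             c(random, "residual"))
    return(structure(list(components = comps,
                          se = comps * NA, vcov = NULL, rho = NA_real_,
                          sigma2_year = NULL, logLik = NA_real_,
                          fixef = NULL, convergence = "degenerate",
                          fit = NULL), class = "var_comp"))
  }
  label_of <- list()
  re_terms <- character(0)
  for (r in random) {
    col <- paste0(".g_", gsub(":", "_x_", r))
    if (grepl(":", r, fixed = TRUE)) {
      parts <- strsplit(r, ":", fixed = TRUE)[[1]]
      miss <- setdiff(parts, names(d))
      if (length(miss)) qg_stop(paste("random term uses missing column(s):",
                                      paste(miss, collapse = ", ")))
      d[[col]] <- interaction(d[[parts[1]]], d[[parts[2]]], drop = TRUE)
    } else {
      if (!r %in% names(d)) qg_stop(paste("random term uses missing column:", r))
      d[[col]] <- factor(d[[r]])
    }
    label_of[[col]] <- r
    re_terms <- c(re_terms, sprintf("(1 | %s)", col))
  }
  disp <- "~1"
  if (residual %in% c("AR1", "ARH1")) {
    if (!all(c(year, tree) %in% names(d))) {
      qg_stop("autoregressive residuals need year and tree columns")
    }
    d$.yearf <- factor(d[[year]])
    d$.treef <- factor(d[[tree]])
    if (anyDuplicated(d[c(".yearf", ".treef")])) {
      qg_stop("repeated-measures model needs at most one record per tree-year")
    }
    re_terms <- c(re_terms, "ar1(0 + .yearf | .treef)")
    if (residual == "ARH1") disp <- "~ 0 + .yearf"
  }
  fx <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  rhs <- paste(c(fx, re_terms), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- glmmTMB::glmmTMB(fml, dispformula = stats::as.formula(disp),
                          data = d, REML = reml, family = stats::gaussian())
  conv <- if (isTRUE(fit$fit$convergence == 0)) "converged" else "not converged"

  vc <- glmmTMB::VarCorr(fit)$cond
  comps <- c(); rho <- NA_real_
  for (nm in names(vc)) {
    sd_vec <- attr(vc[[nm]], "stddev")
    if (nm == ".treef") {
      comps[["residual_ar"]] <- sd_vec[[1]]^2
      rho <- attr(vc[[nm]], "correlation")[1, 2]
    } else {
      comps[[label_of[[nm]]]] <- sd_vec[[1]]^2
    }
  }
  sigma2_year <- NULL
  if (disp == "~1") {
    comps[["residual_nugget"]] <- glmmTMB::sigma(fit)^2
  } else {
    bd <- glmmTMB::fixef(fit)$disp
    sigma2_year <- exp(2 * bd)  # dispersion parameters are log-sd
    names(sigma2_year) <- sub("^\\.yearf", "", names(bd))
    comps[["residual_nugget"]] <- mean(sigma2_year)
  }
  if (residual == "independent") {
    names(comps)[names(comps) == "residual_nugget"] <- "residual"
  } else {
    comps[["residual"]] <- comps[["residual_ar"]] + comps[["residual_nugget"]]
  }

  # variance-scale covariance of the (1|g) components + homogeneous residual
  vcv <- NULL
  se <- stats::setNames(rep(NA_real_, length(comps)), names(comps))
  full <- try(stats::vcov(fit, full = TRUE), silent = TRUE)
  if (!inherits(full, "try-error")) {
    pn <- colnames(full)
    theta_idx <- grep("^theta", pn)
    # theta order follows the RE term order; (1|g) takes 1 param, ar1 takes 2
    slots <- list()
    k <- 1
    for (nm in names(vc)) {
      npar <- if (nm == ".treef") 2L else 1L
      slots[[nm]] <- theta_idx[k:(k + npar - 1L)]
      k <- k + npar
    }
    keep_lbl <- c(); keep_idx <- c(); keep_var <- c()
    for (nm in names(vc)) {
      if (nm == ".treef") next
      keep_lbl <- c(keep_lbl, label_of[[nm]])
      keep_idx <- c(keep_idx, slots[[nm]][1])
      keep_var <- c(keep_var, comps[[label_of[[nm]]]])
    }
    disp_idx <- grep("^d~", pn)
    if (disp == "~1" && length(disp_idx) == 1) {
      keep_lbl <- c(keep_lbl, if (residual == "independent") "residual" else "residual_nugget")
      keep_idx <- c(keep_idx, disp_idx)
      keep_var <- c(keep_var, comps[[if (residual == "independent") "residual" else "residual_nugget"]])
    }
    if (length(keep_idx)) {
      sub <- as.matrix(full[keep_idx, keep_idx, drop = FALSE])
      # both theta and the Gaussian dispersion parameter are log-sd,
      # so var = exp(2 par) and d var / d par = 2 var
      jac <- 2 * keep_var
      vcv <- sub * tcrossprod(jac)
      dimnames(vcv) <- list(keep_lbl, keep_lbl)
      se[keep_lbl] <- sqrt(pmax(diag(vcv), 0))
    }
  }

  structure(list(components = comps, se = se, vcov = vcv, rho = rho,
                 sigma2_year = sigma2_year,
                 logLik = as.numeric(stats::logLik(fit)),
                 fixef = glmmTMB::fixef(fit)$cond,
                 convergence = conv, fit = fit),
            class = "var_comp")
}

#' @export
print.var_comp <- function(x, ...) {
  cat("<var_comp> REML variance components (", x$convergence, ")\n", sep = "")
  df <- data.frame(variance = unlist(x$components),
                   se = x$se[names(x$components)])
  print(df, digits = 4)
  if (is.finite(x$rho)) cat("AR correlation rho =", round(x$rho, 4), "\n")
  cat("logLik:", x$logLik, "\n")
  invisible(x)
}

#' Likelihood-ratio test for one random term
#'
#' Refits the model with and without a single random term (same fixed
#' effects, so the REML likelihoods are comparable) and refers twice the
#' log-likelihood difference to the boundary mixture
#' `0.5 * chi2_0 + 0.5 * chi2_1`, the correct null for testing a variance
#' component pinned at zero.
#'
#' @inheritParams fit_lmm
#' @param term one entry of `random` to test.
#' @return list `statistic`, `p_value`, `full`, `reduced`.
#' @export
lrt_random <- function(data, response, fixed = NULL, random, term,
                       residual = "independent", year = "year", tree = "tree") {
  if (!term %in% random) qg_stop("term must be one of the random terms")
  full <- fit_lmm(data, response, fixed, random, residual, year, tree)
  red <- fit_lmm(data, response, fixed, setdiff(random, term),
                 residual, year, tree)
  stat <- max(2 * (full$logLik - red$logLik), 0)
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, full = full, reduced = red)
}
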