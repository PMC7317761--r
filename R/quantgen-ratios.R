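ratio_estimate <- function(est, se) {
  structure(list(estimate = est, se = se,
                 ci = c(lower = est - 1.96 * se, upper = est + 1.96 * se)),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
              x$estimate, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Individual narrow-sense heritability from variance components
#'
#' `h2 = (1/r) * sigma2_fam / sigma2_p`, where `sigma2_fam` is the
#' family-within-provenance variance, `r` the average relatedness of trees
#' within a family (0.25 for idealized half-sibs; a realized genomic estimate
#' may be substituted), and `sigma2_p` the phenotypic variance -- the sum of
#' the family, family-by-year, plot, and residual components, with
#' year-specific components averaged across years. The family variance
#' estimates a fraction `r` of the additive variance, hence the `1/r`
#' expansion. The standard error is by the delta method from the covariance
#' of the two inputs; the confidence interval is `estimate +/- 1.96 SE`.
#'
#' @param sigma2_fam family-within-provenance variance component.
#' @param sigma2_p phenotypic variance (see [phenotypic_variance()]).
#' @param r average within-family relatedness, in (0, 0.5].
#' @param vcov optional 2x2 covariance matrix of
#'   `(sigma2_fam, sigma2_p)`; when absent the SE is `NA`.
#' @return a `ratio_estimate` (estimate, SE, 95% CI).
#' @export
heritability <- function(sigma2_fam, sigma2_p, r = 0.25, vcov = NULL) {
  if (r <= 0 || r > 0.5) qg_stop("r must lie in (0, 0.5]")
  if (sigma2_p <= 0) qg_stop("phenotypic variance must be positive")
  h2 <- sigma2_fam / (r * sigma2_p)
  se <- NA_real_
  if (!is.null(vcov)) {
    g <- c(1 / (r * sigma2_p), -sigma2_fam / (r * sigma2_p^2))
    se <- sqrt(drop(t(g) %*% vcov %*% g))
  }
  ratio_estimate(h2, se)
}

#' Among-population differentiation Q_ST from variance components
#'
#' `Q_ST = sigma2_pop / (sigma2_pop + 2 * sigma2_A)` with the additive
#' variance recovered from the family component as
#' `sigma2_A = sigma2_fam / r`. This is the form consistent with half-sib
#' theory (the family variance is `r` times the additive variance) and with
#' published variance-component tables for such trials; the alternative
#' literal placement of `r` as a multiplier (`2 r sigma2_fam`) is not, and is
#' deliberately not implemented. SE by the delta method, CI
#' `estimate +/- 1.96 SE`.
#'
#' @param sigma2_pop among-population variance component.
#' @param sigma2_fam family-within-population variance component.
#' @param r average within-family relatedness, in (0, 0.5].
#' @param vcov optional 2x2 covariance matrix of
#'   `(sigma2_pop, sigma2_fam)`.
#' @return a `ratio_estimate`.
#' @export
qst <- function(sigma2_pop, sigma2_fam, r = 0.25, vcov = NULL) {
  if (r <= 0 || r > 0.5) qg_stop("r must lie in (0, 0.5]")
  denom <- sigma2_pop + 2 * sigma2_fam / r
  if (denom <= 0) qg_stop("Q_ST undefined: both variance components are zero")
  q <- sigma2_pop / denom
  se <- NA_real_
  if (!is.null(vcov)) {
    g <- c((2 * sigma2_fam / r) / denom^2, -(2 * sigma2_pop / r) / denom^2)
    se <- sqrt(drop(t(g) %*% vcov %*% g))
  }
  ratio_estimate(q, se)
}

#' Phenotypic variance from a fitted variance-component object
#'
#' The phenotypic variance used by the heritability denominator: the sum of
#' the family-within-provenance, family-by-year, plot (family-by-block), and
#' residual variances. Year-specific plot or residual variances enter as
#' their across-year average. The among-population components are excluded
#' by convention (they separate populations rather than individuals within
#' them).
#'
#' @param vc a `var_comp` from [fit_lmm()].
#' @param family,family_year,plot component names in `vc$components`
#'   (set to `NULL` if absent from the model).
#' @return list `sigma2_p`, `weights` (named 0/1 vector over components
#'   marking which entered the sum).
#' @export
phenotypic_variance <- function(vc, family = "family",
                                family_year = "family:year", plot = "plot") {
  nm <- names(vc$components)
  want <- c(family, family_year, plot, "residual")
  use <- intersect(want, nm)
  if (!length(use)) qg_stop("no phenotypic components found")
  w <- stats::setNames(as.numeric(nm %in% use), nm)
  list(sigma2_p = sum(unlist(vc$components)[use]), weights = w)
}

#' Heritability and Q_ST from one repeated-measures fit
#'
#' Applies [heritability()] and [qst()] to the components of a [fit_lmm()]
#' fit, propagating the component covariance into both delta-method SEs.
#'
#' @param vc a `var_comp` with `provenance` and `family` components.
#' @param r average within-family relatedness.
#' @param pop,family component names.
#' @return list with `h2` and `qst`, both `ratio_estimate`s.
#' @export
herit_qst <- function(vc, r = 0.25, pop = "provenance", family = "family") {
  comps <- unlist(vc$components)
  if (!all(c(pop, family) %in% names(comps))) {
    qg_stop("fit lacks population or family components")
  }
  pv <- phenotypic_variance(vc, family = family)
  v_h <- v_q <- NULL
  if (!is.null(vc$vcov)) {
    nm <- colnames(vc$vcov)
    # cov(fam, p) via linear combination over available components
    a_f <- as.numeric(nm == family)
    a_p <- pv$weights[nm]
    # residual of AR fits is a sum whose parts may not all be in vcov;
    # use the nugget as a conservative stand-in when needed
    if (!"residual" %in% nm && "residual_nugget" %in% nm) {
      a_p["residual_nugget"] <- 1
    }
    lin <- function(a, b) drop(t(a) %*% vc$vcov %*% b)
    v_h <- matrix(c(lin(a_f, a_f), lin(a_f, a_p),
                    lin(a_f, a_p), lin(a_p, a_p)), 2, 2)
    a_pop <- as.numeric(nm == pop)
    v_q <- matrix(c(lin(a_pop, a_pop), lin(a_pop, a_f),
                    lin(a_pop, a_f), lin(a_f, a_f)), 2, 2)
  }
  list(h2 = heritability(comps[[family]], pv$sigma2_p, r, vcov = v_h),
       qst = qst(comps[[pop]], comps[[family]], r, vcov = v_q))
}
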