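# hinge basis evaluation for one term: a product of hinge factors
# term: list(vars = character(), knots = numeric(), signs = +1/-1)
eval_term <- function(term, xmat) {
  if (!length(term$vars)) return(rep(1, nrow(xmat)))
  out <- rep(1, nrow(xmat))
  for (k in seq_along(term$vars)) {
    x <- xmat[, term$vars[k]]
    h <- if (term$signs[k] > 0) pmax(x - term$knots[k], 0) else
      pmax(term$knots[k] - x, 0)
    out <- out * h
  }
  out
}

term_label <- function(term) {
  if (!length(term$vars)) return("(Intercept)")
  paste(mapply(function(v, k, s) {
    if (s > 0) sprintf("h(%s-%.4g)", v, k) else sprintf("h(%.4g-%s)", k, v)
  }, term$vars, term$knots, term$signs), collapse = "*")
}

mars_gcv <- function(rss, n, n_terms, penalty) {
  c_m <- n_terms + penalty * (n_terms - 1) / 2
  if (c_m >= n) return(Inf)
  (rss / n) / (1 - c_m / n)^2
}

fit_ls <- function(B, y) {
  fit <- stats::lm.fit(B, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss, rank = fit$rank)
}

#' Hinge-basis adaptive regression splines
#'
#' Piecewise-linear regression in the style of multivariate adaptive
#' regression splines: the forward pass greedily adds mirror-image hinge
#' pairs `max(0, x - k)` / `max(0, k - x)` (optionally multiplied into an
#' existing term, up to interaction degree `max_degree`) at observed
#' predictor values, choosing at each step the addition with the largest
#' residual-sum-of-squares drop, until `max_terms` terms or no further
#' improvement. The backward pass then deletes terms one at a time, keeping
#' the subset with the lowest generalized cross-validation score
#' `GCV = (RSS/n) / (1 - C(M)/n)^2` with effective parameter count
#' `C(M) = M + penalty * (M - 1) / 2`. Because the full forward model is in
#' the candidate subset sequence, the selected GCV never exceeds the
#' forward-pass GCV. Predictors are standardized internally; knots are
#' reported on the original scale, so fits are invariant to affine
#' predictor rescaling.
#'
#' @param y numeric response (e.g. provenance means of a trait).
#' @param X data.frame or matrix of predictors (e.g. MAT, MAP, ADD,
#'   Summer_SMI at provenance origin).
#' @param max_degree maximum interaction degree (1 = additive, default 2).
#' @param max_terms forward-pass term cap including the intercept (default
#'   21).
#' @param penalty GCV penalty per knot (default 3, the canonical choice when
#'   interactions are allowed; use 2 for additive models).
#' @param min_span minimum number of observations between candidate knots
#'   (default 1 = every distinct observed value).
#' @return object of class `mars_model`: terms, coefficients, knots, GCV,
#'   R-squared, fitted values.
#' @export
mars_fit <- function(y, X, max_degree = 2, max_terms = 21, penalty = 3,
                     min_span = 1) {
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n) qg_stop("y and X sizes differ")
  if (n < 10) qg_stop("need at least 10 observations")
  vars <- names(X)
  Xorig <- as.matrix(X)
  # standardize predictors so knot selection (greedy, with floating-point
  # ties) is identical under affine rescaling of the inputs; knots are
  # mapped back to the original scale at the end
  ctr <- colMeans(Xorig)
  scl <- apply(Xorig, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xm <- sweep(sweep(Xorig, 2, ctr), 2, scl, "/")
  tss <- sum((y - mean(y))^2)
  intercept_only <- list(
    terms = list(list(vars = character(0), knots = numeric(0), signs = numeric(0))),
    coef = mean(y), rss = tss)
  if (tss == 0) {
    mdl <- structure(list(terms = intercept_only$terms, coef = mean(y),
                          labels = "(Intercept)", gcv = 0, r2 = 1,
                          forward_gcv = 0, forward_r2 = 1,
                          fitted = rep(mean(y), n), vars = vars,
                          ranges = apply(Xorig, 2, range)),
                     class = "mars_model")
    return(mdl)
  }

  terms <- intercept_only$terms
  B <- matrix(1, n, 1)
  rss <- tss
  repeat {
    if (length(terms) + 2 > max_terms) break
    best <- NULL
    for (ti in seq_along(terms)) {
      parent <- terms[[ti]]
      if (length(parent$vars) >= max_degree) next
      for (v in setdiff(vars, parent$vars)) {
        kn <- sort(unique(Xm[, v]))
        if (min_span > 1) kn <- kn[seq(1, length(kn), by = min_span)]
        kn <- kn[-length(kn)]      # a hinge at the max is identically zero
        pb <- eval_term(parent, Xm)
        for (k in kn) {
          b1 <- pb * pmax(Xm[, v] - k, 0)
          b2 <- pb * pmax(k - Xm[, v], 0)
          Bc <- cbind(B, b1, b2)
          f <- fit_ls(Bc, y)
          if (is.null(best) || f$rss < best$rss - 1e-12) {
            best <- list(rss = f$rss, v = v, k = k, parent = parent)
          }
        }
      }
    }
    if (is.null(best) || best$rss >= rss * (1 - 1e-9)) break
    p <- best$parent
    t1 <- list(vars = c(p$vars, best$v), knots = c(p$knots, best$k),
               signs = c(p$signs, 1))
    t2 <- list(vars = c(p$vars, best$v), knots = c(p$knots, best$k),
               signs = c(p$signs, -1))
    terms <- c(terms, list(t1), list(t2))
    B <- cbind(B, eval_term(t1, Xm), eval_term(t2, Xm))
    rss <- best$rss
    if (rss <= tss * 1e-12) break
  }

  forward_fit <- fit_ls(B, y)
  forward_gcv <- mars_gcv(forward_fit$rss, n, length(terms), penalty)
  forward_r2 <- 1 - forward_fit$rss / tss

  # backward pruning: delete the term (never the intercept) whose removal
  # yields the lowest GCV; keep the best subset seen
  cur <- seq_along(terms)
  best_sub <- cur
  best_gcv <- forward_gcv
  while (length(cur) > 1) {
    step_best <- NULL
    for (drop_i in cur[-1]) {
      sub <- setdiff(cur, drop_i)
      f <- fit_ls(B[, sub, drop = FALSE], y)
      g <- mars_gcv(f$rss, n, length(sub), penalty)
      if (is.null(step_best) || g < step_best$g) step_best <- list(g = g, sub = sub)
    }
    cur <- step_best$sub
    if (step_best$g < best_gcv) {
      best_gcv <- step_best$g
      best_sub <- cur
    }
  }
  terms <- terms[best_sub]
  # map knots from standardized to original predictor units and refit the
  # coefficients on the original-unit basis (hinges are scale-equivariant,
  # so the fitted values are unchanged)
  terms <- lapply(terms, function(tm) {
    if (length(tm$vars)) {
      tm$knots <- tm$knots * scl[tm$vars] + ctr[tm$vars]
    }
    tm
  })
  Bo <- vapply(terms, eval_term, numeric(n), xmat = Xorig)
  if (n == 1) Bo <- matrix(Bo, nrow = 1)
  ff <- fit_ls(as.matrix(Bo), y)
  fitted <- drop(as.matrix(Bo) %*% ifelse(is.na(ff$coef), 0, ff$coef))
  structure(list(terms = terms, coef = ff$coef,
                 labels = vapply(terms, term_label, character(1)),
                 gcv = best_gcv, r2 = 1 - ff$rss / tss,
                 forward_gcv = forward_gcv, forward_r2 = forward_r2,
                 fitted = fitted, vars = vars,
                 ranges = apply(Xorig, 2, range)),
            class = "mars_model")
}

#' @export
print.mars_model <- function(x, ...) {
  cat("<mars_model>", length(x$terms), "terms, R2 =", round(x$r2, 4),
      ", GCV =", signif(x$gcv, 5), "\n")
  df <- data.frame(term = x$labels, coef = unname(x$coef))
  print(df, digits = 4)
  invisible(x)
}

#' @export
predict.mars_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[object$vars])
  B <- vapply(object$terms, eval_term, numeric(nrow(X)), xmat = X)
  if (nrow(X) == 1) B <- matrix(B, nrow = 1)
  cf <- ifelse(is.na(object$coef), 0, object$coef)
  drop(B %*% cf)
}

#' Gridded response surface over two predictors
#'
#' Predictions of a fitted hinge-spline model on a regular grid over two
#' predictors (remaining predictors held at their training medians, passed
#' via `at`). Grid cells outside the observed bounding box of the training
#' predictors are flagged as extrapolation.
#'
#' @param model a `mars_model`.
#' @param var1,var2 predictor names spanning the grid.
#' @param n grid resolution per axis (default 25).
#' @param at named list of values for the remaining predictors (default:
#'   midpoint of their training range).
#' @return data.frame `var1`, `var2`, `pred`, `extrapolated`.
#' @export
response_surface <- function(model, var1, var2, n = 25, at = NULL) {
  rng <- model$ranges
  if (!all(c(var1, var2) %in% model$vars)) qg_stop("unknown grid predictors")
  g1 <- seq(rng[1, var1], rng[2, var1], length.out = n)
  g2 <- seq(rng[1, var2], rng[2, var2], length.out = n)
  grid <- expand.grid(g1, g2)
  names(grid) <- c(var1, var2)
  for (v in setdiff(model$vars, c(var1, var2))) {
    grid[[v]] <- if (!is.null(at) && v %in% names(at)) at[[v]] else
      mean(rng[, v])
  }
  inside <- grid[[var1]] >= rng[1, var1] & grid[[var1]] <= rng[2, var1] &
    grid[[var2]] >= rng[1, var2] & grid[[var2]] <= rng[2, var2]
  if (!any(inside)) qg_stop("grid entirely outside the observed predictor range")
  out <- grid[c(var1, var2)]
  out$pred <- predict(model, grid)
  out$extrapolated <- !inside
  out
}
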