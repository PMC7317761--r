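#' Pipeline run configuration
#'
#' Collects every knob of the analysis chain: the analysis window, drought
#' events (an explicit year list or `"auto"` detection from summer soil
#' moisture anomalies), pre/post resilience window lengths, the soil
#' moisture bucket parameters, the within-family relatedness used by the
#' heritability and Q_ST estimators, bootstrap effort, the residual
#' structure of the repeated-measures model, and the RNG seed (recorded in
#' all outputs). When `sim` is supplied the pipeline generates its own
#' inputs; otherwise reader paths must be given.
#'
#' @param sim optional [sim_params()] for a synthetic run.
#' @param rwl_path,long_path,design_path,genotypes_path input file paths
#'   (used when `sim` is `NULL`; give one of `rwl_path`/`long_path`).
#' @param first_year,last_year analysis window (calendar years); `NA` means
#'   use the data range.
#' @param cut_year first year kept in residual chronologies (juvenile
#'   exclusion).
#' @param drought_years integer vector or `"auto"`.
#' @param pre_n,post_n resilience window lengths, years (>= 1).
#' @param w_max,w_crit soil moisture bucket parameters, mm.
#' @param r within-family relatedness in (0, 0.5]; `"genomic"` to estimate
#'   it from the G-matrix.
#' @param n_boot bootstrap iterations for dendroclimatic significance.
#' @param residual residual structure for the repeated-measures model.
#' @param seed RNG seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, rwl_path = NULL, long_path = NULL,
                       design_path = NULL, genotypes_path = NULL,
                       first_year = NA, last_year = NA, cut_year = 1989,
                       drought_years = "auto", pre_n = 2, post_n = 2,
                       w_max = 300, w_crit = 400, r = 0.25, n_boot = 200,
                       residual = c("ARH1", "AR1", "independent"),
                       seed = 1) {
  residual <- match.arg(residual)
  if (pre_n < 1 || post_n < 1) qg_stop("window lengths must be >= 1")
  if (w_max <= 0) qg_stop("w_max must be positive")
  if (is.numeric(r) && (r <= 0 || r > 0.5)) qg_stop("r must lie in (0, 0.5]")
  structure(list(sim = sim, rwl_path = rwl_path, long_path = long_path,
                 design_path = design_path, genotypes_path = genotypes_path,
                 first_year = first_year, last_year = last_year,
                 cut_year = cut_year, drought_years = drought_years,
                 pre_n = pre_n, post_n = post_n, w_max = w_max,
                 w_crit = w_crit, r = r, n_boot = n_boot,
                 residual = residual, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; a `sim:` mapping, when
#' present, is passed through [sim_params()]. Unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) qg_stop(paste("file not found:", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_params, y$sim)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    qg_stop(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  }
  do.call(run_config, y)
}

stage_write <- function(out_dir, stage, tables) {
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(out_dir, sprintf("%s_%s.csv", stage, nm)),
                     row.names = FALSE)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the chain stage by stage -- simulate (or read), climate,
#' rings, detrend, dendroclim, resilience, quantgen, cline -- writing a
#' machine-readable CSV per stage plus a JSON log of the parameters used
#' into `out_dir`. Outputs depend only on (inputs, config, seed); the same
#' config run twice produces identical numbers. Any stage failure aborts
#' with the stage name attached.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of the main per-stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, params = config[!vapply(config, is.null, TRUE)])
  stage <- "setup"
  res <- list()
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      qg_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              class = "dendroQG_stage_error")
    })
  }

  inputs <- run_stage("inputs", {
    if (!is.null(config$sim)) {
      simulate_trial(config$sim)
    } else {
      rings <- if (!is.null(config$long_path)) read_long_csv(config$long_path)
        else if (!is.null(config$rwl_path)) read_rwl(config$rwl_path)
        else qg_stop("no ring input configured")
      if (is.null(config$design_path)) qg_stop("no design input configured")
      design <- read_design(config$design_path)
      check_trees_in_design(rings, design)
      geno <- if (!is.null(config$genotypes_path)) read_genotypes(config$genotypes_path)
      list(design = design, rings = rings, genotypes = geno,
           monthly = NULL, smi = NULL)
    }
  })
  if (is.numeric(config$r) || is.null(inputs$genotypes)) {
    if (identical(config$r, "genomic")) {
      qg_stop("stage 'quantgen' requires a genotype input when r = \"genomic\"")
    }
  }

  # note: stage expressions must not use return(); they are promises whose
  # environment is this function, so return() would abort the whole run
  clim <- run_stage("climate", {
    if (is.null(inputs$monthly)) NULL else {
      smi <- if (is.null(inputs$smi)) {
        compute_smi(inputs$monthly, w_max = config$w_max, w_crit = config$w_crit)
      } else inputs$smi
      anom <- summer_anomaly(smi, "SMI")
      events <- if (identical(config$drought_years, "auto")) {
        detect_droughts(anom)
      } else as.integer(config$drought_years)
      stage_write(out_dir, "climate", list(smi = smi, anomalies = anom))
      list(smi = smi, anom = anom, events = events)
    }
  })
  events <- if (!is.null(clim)) clim$events else {
    if (identical(config$drought_years, "auto")) {
      qg_stop("drought_years = \"auto\" needs climate inputs")
    }
    as.integer(config$drought_years)
  }
  log$drought_events <- events

  rings_out <- run_stage("rings", {
    bai <- rw_to_bai(inputs$rings)
    tr <- if (all(c("TDr", "TDt", "CWT") %in% names(inputs$rings))) {
      derive_tracheid(as.data.frame(inputs$rings))
    }
    stage_write(out_dir, "rings", c(list(bai = bai),
                                    if (!is.null(tr)) list(tracheid = tr)))
    list(bai = bai, tracheid = tr)
  })

  det <- run_stage("detrend", {
    std <- standardize_rings(inputs$rings, inputs$design,
                             cut_year = config$cut_year)
    stage_write(out_dir, "detrend", list(residuals = std))
    std
  })

  chron <- run_stage("chronology", {
    grp <- inputs$design$provenance[match(det$tree, inputs$design$tree)]
    ch <- build_chronology(det, grp, value = "white")
    stage_write(out_dir, "chronology", ch)
    ch
  })

  dc <- run_stage("dendroclim", {
    if (is.null(clim)) NULL else {
      site <- stats::aggregate(det$white, by = list(year = det$year), FUN = mean)
      names(site)[2] <- "mean"
      ct <- monthly_correlations(site, clim$smi, "SMI", n_boot = config$n_boot,
                                 seed = config$seed)
      stage_write(out_dir, "dendroclim", list(correlations = ct))
      ct
    }
  })

  resil <- run_stage("resilience", {
    rec <- lloret_indices(rings_out$bai, events,
                          pre_n = config$pre_n, post_n = config$post_n)
    mi <- mean_indices(rec)
    stage_write(out_dir, "resilience", list(records = as.data.frame(rec),
                                            means = mi))
    list(records = rec, means = mi)
  })

  qg <- run_stage("quantgen", {
    r_use <- config$r
    r_src <- "configured"
    if (identical(config$r, "genomic")) {
      if (is.null(inputs$genotypes)) {
        qg_stop("genotype input required for r = \"genomic\"")
      }
      G <- gmatrix(inputs$genotypes)
      r_use <- avg_within_family(G, inputs$design)$r_hat
      r_src <- "genomic"
    }
    ev <- max(events)
    d <- merge(resil$records[resil$records$event == ev, ], inputs$design,
               by = "tree")
    sz <- stats::aggregate(rings_out$bai$BAI, by = list(tree = rings_out$bai$tree),
                           FUN = sum)
    d$tree_size <- sz$x[match(d$tree, sz$tree)]
    d$plot <- paste(d$family, d$block, sep = "/")
    vc <- fit_lmm(d, "Rl", fixed = c("block", "tree_size"),
                  random = c("provenance", "family", "plot"),
                  residual = "independent")
    hq <- herit_qst(vc, r = r_use)
    fst <- if (!is.null(inputs$genotypes)) {
      fst_wc(inputs$genotypes,
             inputs$design$provenance[match(rownames(inputs$genotypes),
                                            inputs$design$tree)])
    }
    tab <- data.frame(
      trait = paste0("Rl_", ev), r = r_use, r_source = r_src,
      h2 = hq$h2$estimate, h2_se = hq$h2$se,
      qst = hq$qst$estimate, qst_se = hq$qst$se,
      fst = if (!is.null(fst)) fst$theta else NA_real_)
    stage_write(out_dir, "quantgen",
                list(summary = tab,
                     varcomp = data.frame(component = names(vc$components),
                                          variance = unlist(vc$components),
                                          se = vc$se[names(vc$components)])))
    list(vc = vc, hq = hq, fst = fst, table = tab, r = r_use)
  })

  cline <- run_stage("cline", {
    origins <- attr(inputs$design, "origins")
    if (is.null(origins)) NULL else {
      ev <- max(events)
      d <- merge(resil$records[resil$records$event == ev, ], inputs$design,
                 by = "tree")
      pm <- stats::aggregate(d$Rl, by = list(provenance = d$provenance),
                             FUN = mean)
      names(pm)[2] <- "Rl"
      pm <- merge(pm, origins, by = "provenance")
      # spline fitting needs a reasonable number of provenance means
      mdl <- if (nrow(pm) >= 10) mars_fit(pm$Rl, pm[c("MAT", "Summer_SMI")])
      stage_write(out_dir, "cline", c(
        list(provenance_means = pm),
        if (!is.null(mdl)) list(terms = data.frame(term = mdl$labels,
                                                   coef = unname(mdl$coef)))))
      list(means = pm, model = mdl)
    }
  })

  log$stages <- c("inputs", "climate", "rings", "detrend", "chronology",
                  "dendroclim", "resilience", "quantgen", "cline")
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(inputs = inputs, climate = clim, rings = rings_out,
                 detrend = det, chronology = chron, dendroclim = dc,
                 resilience = resil, quantgen = qg, cline = cline))
}
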