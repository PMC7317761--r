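#' Ring series sets
#'
#' A ring series set is the package's container for per-tree annual tree-ring
#' measurements: one row per (tree, year), with ring width `RW` (mm) always
#' present and optional wood-trait columns (`WD` kg m-3, `CWT` um, `TDr` um,
#' `TDt` um). Cambial age is year - first ring year + 1 (1-based). Per-tree
#' year ranges must be contiguous: missing rings are never imputed, trees with
#' gaps are rejected at construction so downstream stages can rely on
#' alignment by calendar year.
#'
#' @param x data.frame with columns `tree`, `year`, `RW` and optionally
#'   `WD`, `CWT`, `TDr`, `TDt`.
#' @return object of class `ring_set` (a validated data.frame).
#' @export
ring_set <- function(x) {
  need <- c("tree", "year", "RW")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    qg_stop(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  x$tree <- as.character(x$tree)
  x$year <- as.integer(x$year)
  x <- x[order(x$tree, x$year), , drop = FALSE]
  if (anyDuplicated(x[c("tree", "year")])) {
    qg_stop("duplicate (tree, year) records")
  }
  if (any(!is.finite(x$RW)) || any(x$RW <= 0)) {
    qg_stop("ring widths must be positive and finite")
  }
  # contiguity per tree
  sp <- split(x$year, x$tree)
  for (id in names(sp)) {
    yrs <- sp[[id]]
    gap <- setdiff(seq(min(yrs), max(yrs)), yrs)
    if (length(gap)) {
      qg_stop(sprintf("series %s has internal gap year(s): %s",
                      id, paste(gap, collapse = ", ")),
              class = "dendroQG_gap_year")
    }
  }
  if (all(c("CWT", "TDr", "TDt") %in% names(x))) {
    ok <- is.na(x$CWT) | (x$CWT < pmin(x$TDr, x$TDt))
    if (!all(ok)) {
      qg_stop("cell-wall thickness must be below both tracheid diameters")
    }
  }
  rownames(x) <- NULL
  class(x) <- c("ring_set", "data.frame")
  x
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("<ring_set> %d trees, %d records, years %d-%d\n",
              length(unique(x$tree)), nrow(x), min(x$year), max(x$year)))
  cat("traits:", paste(intersect(c("RW", "WD", "CWT", "TDr", "TDt"), names(x)),
                       collapse = " "), "\n")
  invisible(x)
}

#' First ring year per tree
#' @param rings a [ring_set()].
#' @return named integer vector, one entry per tree.
#' @export
first_ring_year <- function(rings) {
  vapply(split(rings$year, rings$tree), min, integer(1))
}

#' Read a Tucson (decadal) RWL file
#'
#' Parses the decadal interchange layout used by measurement programs: each
#' line carries a series id, the calendar year of the first value, and values
#' until the end of the decade; the series ends with a stop marker. Values are
#' stored in units of 0.01 mm with stop marker 999, or 0.001 mm with stop
#' marker -9999; both are rescaled to mm and the marker is consumed, not
#' stored.
#'
#' @param path path to an RWL file.
#' @return a [ring_set()] with column `RW` in mm.
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) qg_stop(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  series <- list()   # id -> data.frame(year, raw)
  scale <- list()    # id -> divisor
  done <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 3) {
      qg_stop(sprintf("line %d: malformed decade line (need id, year, values)", i),
              class = "dendroQG_parse_error")
    }
    id <- tok[[1]]
    yr <- suppressWarnings(as.integer(tok[[2]]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(yr) || anyNA(vals)) {
      qg_stop(sprintf("line %d: non-numeric year or value", i),
              class = "dendroQG_parse_error")
    }
    if (id %in% done) {
      qg_stop(sprintf("line %d: duplicate series id %s", i, id),
              class = "dendroQG_duplicate_series")
    }
    stop_at <- which(vals == 999 | vals == -9999)
    if (length(stop_at)) {
      marker <- vals[stop_at[[1]]]
      scale[[id]] <- if (marker == -9999) 1000 else 100
      vals <- vals[seq_len(stop_at[[1]] - 1L)]
      done <- c(done, id)
    }
    if (length(vals)) {
      series[[id]] <- rbind(
        series[[id]],
        data.frame(year = yr + seq_along(vals) - 1L, raw = vals)
      )
    }
  }
  open_ids <- setdiff(names(series), done)
  if (length(open_ids)) {
    qg_stop(paste("series without stop marker:", paste(open_ids, collapse = ", ")),
            class = "dendroQG_parse_error")
  }
  out <- do.call(rbind, lapply(names(series), function(id) {
    df <- series[[id]]
    data.frame(tree = id, year = df$year, RW = df$raw / scale[[id]])
  }))
  ring_set(out)
}

#' Write a ring series set to Tucson RWL
#'
#' Decadal layout at 0.01 mm precision with the conventional 999 terminator.
#' `write_rwl` followed by [read_rwl()] round-trips ring widths to within
#' 0.01 mm.
#'
#' @param rings a [ring_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(rings$tree)) {
    df <- rings[rings$tree == id, ]
    df <- df[order(df$year), ]
    v <- round(df$RW * 100)
    v[v == 999] <- 1000   # a true 9.99 mm would read as the stop marker
    vals <- c(v, 999)
    yrs <- c(df$year, max(df$year) + 1L)
    while (length(vals)) {
      y0 <- yrs[[1]]
      n <- min(10L - (y0 %% 10L), length(vals))
      writeLines(sprintf("%-8s%4d%s", id, y0,
                         paste(sprintf("%6d", vals[seq_len(n)]), collapse = "")),
                 con)
      vals <- vals[-seq_len(n)]
      yrs <- yrs[-seq_len(n)]
    }
  }
  invisible(path)
}
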