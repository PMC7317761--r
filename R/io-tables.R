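# CSV dialect everywhere: UTF-8, comma separated, mandatory header row.

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) qg_stop(paste("file not found:", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    qg_stop(sprintf("%s: missing required column(s): %s",
                    basename(path), paste(miss, collapse = ", ")))
  }
  x
}

#' Read a long-format ring trait CSV
#'
#' Long layout with one row per (tree, year): columns `tree`, `year`, `RW`
#' and optionally `WD`, `CWT`, `TDr`, `TDt`. This is the interchange format
#' for multi-trait tracheid data that the decadal RWL layout cannot carry.
#'
#' @param path CSV path.
#' @return a [ring_set()].
#' @export
read_long_csv <- function(path) {
  ring_set(read_csv_strict(path, c("tree", "year", "RW")))
}

#' Write a ring series set as long CSV
#' @param rings a [ring_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(rings, path) {
  utils::write.csv(as.data.frame(rings), path, row.names = FALSE)
  invisible(path)
}

#' Design tables
#'
#' The field design of a common-garden trial: each tree belongs to a half-sib
#' `family`, each family to a seed-source `provenance`, and is planted as
#' part of a row-plot in one `block`, at grid coordinates `x`, `y` (metres).
#' Provenance-origin climate normals (MAT, MAP, ADD, Summer_SMI per
#' provenance) may be attached as the `origins` attribute.
#'
#' @param x data.frame with columns `tree`, `family`, `provenance`, `block`,
#'   `x`, `y`.
#' @param origins optional data.frame of per-provenance origin climate
#'   normals (column `provenance` plus climate columns).
#' @return object of class `design_table`.
#' @export
design_table <- function(x, origins = NULL) {
  need <- c("tree", "family", "provenance", "block", "x", "y")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    qg_stop(paste("design: missing columns:", paste(miss, collapse = ", ")))
  }
  x$tree <- as.character(x$tree)
  if (anyDuplicated(x$tree)) qg_stop("design: duplicate tree ids")
  for (f in c("family", "provenance", "block")) x[[f]] <- as.character(x[[f]])
  # each family must live inside exactly one provenance
  fp <- unique(x[c("family", "provenance")])
  if (anyDuplicated(fp$family)) {
    qg_stop("design: a family is assigned to more than one provenance")
  }
  if (!is.null(origins)) {
    if (!"provenance" %in% names(origins)) {
      qg_stop("origins: missing provenance column")
    }
    attr(x, "origins") <- origins
  }
  rownames(x) <- NULL
  class(x) <- c("design_table", "data.frame")
  x
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d trees | %d provenances | %d families | %d blocks\n",
              nrow(x), length(unique(x$provenance)),
              length(unique(x$family)), length(unique(x$block))))
  invisible(x)
}

#' Read a design CSV
#' @param path CSV with columns tree, family, provenance, block, x, y.
#' @param origins_path optional CSV of provenance-origin climate normals.
#' @return a [design_table()].
#' @export
read_design <- function(path, origins_path = NULL) {
  x <- read_csv_strict(path, c("tree", "family", "provenance", "block", "x", "y"))
  origins <- if (!is.null(origins_path)) {
    read_csv_strict(origins_path, "provenance")
  }
  design_table(x, origins = origins)
}

#' Read a genotype CSV
#'
#' Rows are trees (first column `tree`), remaining columns are biallelic SNPs
#' coded as minor-allele counts 0/1/2; empty cells are missing. Any other
#' coding is rejected.
#'
#' @param path CSV path.
#' @return integer matrix (trees x SNPs) with tree ids as rownames.
#' @export
read_genotypes <- function(path) {
  x <- read_csv_strict(path, "tree")
  ids <- as.character(x$tree)
  m <- as.matrix(x[setdiff(names(x), "tree")])
  storage.mode(m) <- "integer"
  bad <- !is.na(m) & !(m %in% 0:2)
  if (any(bad)) {
    qg_stop(sprintf("non-biallelic genotype coding (values outside 0/1/2) in %d cell(s)",
                    sum(bad)), class = "dendroQG_genotype_coding")
  }
  rownames(m) <- ids
  m
}

#' Check that ring trees are covered by the design
#' @param rings a [ring_set()].
#' @param design a [design_table()].
#' @return `TRUE` invisibly; errors listing orphan tree ids otherwise.
#' @export
check_trees_in_design <- function(rings, design) {
  orphans <- setdiff(unique(rings$tree), design$tree)
  if (length(orphans)) {
    qg_stop(paste("trees present in ring data but absent from design:",
                  paste(orphans, collapse = ", ")),
            class = "dendroQG_orphan_trees")
  }
  invisible(TRUE)
}
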