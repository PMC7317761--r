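#' Realized genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 * sum_k p_k (1 - p_k))` where `W = M - 2p` centres each
#' SNP's minor-allele counts on its observed allele frequency. Missing
#' genotypes are mean-imputed per SNP before centring (so they contribute
#' zero to `W`). Monomorphic SNPs carry no information and are dropped; a
#' panel with no polymorphic SNPs is an error. Under Hardy-Weinberg
#' proportions the mean diagonal is close to 1.
#'
#' @param M trees x SNPs matrix of 0/1/2 minor-allele counts (`NA` allowed).
#' @param min_snps minimum polymorphic SNP count (default 100).
#' @return trees x trees numeric matrix with tree ids as dimnames.
#' @export
gmatrix <- function(M, min_snps = 100) {
  M <- as.matrix(M)
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) qg_stop("all SNPs monomorphic: G-matrix undefined")
  if (sum(poly) < min_snps) {
    qg_stop(sprintf("only %d polymorphic SNPs (< %d): panel too small",
                    sum(poly), min_snps))
  }
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(M, 2, 2 * p)
  if (anyNA(W)) W[is.na(W)] <- 0  # mean imputation after centring
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Average within-family genomic relatedness
#'
#' Mean of the off-diagonal G-matrix entries taken over pairs of trees
#' belonging to the same family. For idealized half-sib families the
#' pedigree expectation is 0.25; the realized value replaces the pedigree
#' constant in [heritability()] and [qst()].
#'
#' @param G matrix from [gmatrix()] with tree ids as dimnames.
#' @param design a [design_table()] covering the genotyped trees.
#' @return list `r_hat` (mean within-family relatedness), `n_pairs`.
#' @export
avg_within_family <- function(G, design) {
  fam <- design$family[match(rownames(G), design$tree)]
  if (anyNA(fam)) qg_stop("genotyped trees missing from design")
  vals <- c(); n <- 0L
  for (f in unique(fam)) {
    i <- which(fam == f)
    if (length(i) < 2) next
    g <- G[i, i]
    vals <- c(vals, g[upper.tri(g)])
    n <- n + sum(upper.tri(g))
  }
  if (!n) qg_stop("no within-family pairs")
  list(r_hat = mean(vals), n_pairs = n)
}

#' Weir-Cockerham F_ST from genotype counts
#'
#' Per-SNP theta from the Weir-Cockerham (1984) variance decomposition for
#' biallelic markers with unequal deme sizes, combined over SNPs by the
#' ratio-of-sums estimator `sum(a) / sum(a + b + c)`. SNPs monomorphic
#' across the whole sample are undefined per SNP and excluded from the sums.
#' A Nei-style G_ST (`1 - Hs / Ht` from sample-size-weighted heterozygosity)
#' is emitted alongside as an independent convention for cross-checking.
#'
#' @param M trees x SNPs matrix of 0/1/2 counts (`NA` allowed).
#' @param pops vector of deme (provenance) labels, length `nrow(M)`.
#' @return list `per_snp` (data.frame `snp`, `theta`), `theta` (overall
#'   ratio-of-sums), `gst` (overall Nei-style), `n_snps_used`.
#' @export
fst_wc <- function(M, pops) {
  M <- as.matrix(M)
  pops <- factor(pops)
  if (nlevels(pops) < 2) qg_stop("need at least 2 demes")
  tab <- table(pops)
  if (any(tab < 2)) qg_stop("each deme needs at least 2 trees")
  obs <- !is.na(M)
  n_i <- rowsum(obs + 0, pops)                       # deme x snp sample sizes
  sum_i <- rowsum(ifelse(obs, M, 0), pops)
  het_i <- rowsum(ifelse(obs, (M == 1) + 0, 0), pops)
  p_i <- sum_i / (2 * n_i)
  h_i <- het_i / n_i

  r <- colSums(n_i > 0)
  N <- colSums(n_i)
  nbar <- N / r
  nc <- (N - colSums(n_i^2) / N) / (r - 1)
  pbar <- colSums(n_i * p_i) / N
  s2 <- colSums(n_i * (p_i - pbar[col(p_i)])^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / N

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  mono <- pbar <= 0 | pbar >= 1
  theta_snp <- ifelse(mono, NA_real_, a / (a + b + cc))
  use <- !mono & is.finite(a + b + cc)
  if (!any(use)) qg_stop("no polymorphic SNPs")
  theta_all <- sum(a[use]) / sum((a + b + cc)[use])

  hs <- colSums(n_i * 2 * p_i * (1 - p_i)) / N
  ht <- 2 * pbar * (1 - pbar)
  gst_all <- 1 - sum(hs[use]) / sum(ht[use])

  snp_names <- colnames(M)
  if (is.null(snp_names)) snp_names <- paste0("snp", seq_len(ncol(M)))
  list(per_snp = data.frame(snp = snp_names, theta = theta_snp),
       theta = theta_all, gst = gst_all, n_snps_used = sum(use))
}
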