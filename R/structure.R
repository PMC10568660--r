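#' Prune sites in high linkage disequilibrium
#'
#' Slides windows of `window_snps` sites (stepped by `step_snps`) along the
#' genome; within each window, for every pair of sites whose squared Pearson
#' correlation of alternate-allele dosages exceeds `r2_threshold`, the later
#' site is removed. Passes repeat until a full sweep removes nothing, so the
#' result is a fixed point: no retained pair within any window exceeds the
#' threshold. Correlations are computed on unphased dosages (Rogers-Huff
#' style), which is all RNA-seq genotypes and pooled libraries can support.
#'
#' Zero-variance sites have no defined correlation; they are retained and
#' counted in the returned attributes.
#'
#' @param d Dosage matrix (sites x samples) as from [dosage_matrix()];
#'   rows must be in genome order.
#' @param window_snps,step_snps Window and step in number of SNPs.
#' @param r2_threshold Sites with r^2 strictly greater than this are pruned.
#' @return The dosage matrix restricted to retained sites, with attributes
#'   `kept` (logical over input rows), `n_pruned`, `n_zero_variance`, and
#'   `chrom`/`pos` subset accordingly.
#' @export
ld_prune <- function(d, window_snps = 500L, step_snps = 250L,
                     r2_threshold = 0.01) {
  n <- nrow(d)
  if (n < 2) stop("LD pruning needs at least 2 sites")
  keep <- rep(TRUE, n)
  vars <- apply(d, 1, stats::var, na.rm = TRUE)
  zero_var <- !is.na(vars) & vars == 0 | is.na(vars)
  repeat {
    removed_any <- FALSE
    idx <- which(keep)   # window grid fixed for the pass; removals via keep
    starts <- seq.int(1L, max(1L, length(idx)), by = step_snps)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1L, length(idx))]
      w <- w[keep[w] & !zero_var[w]]
      if (length(w) < 2) next
      cc <- suppressWarnings(stats::cor(t(d[w, , drop = FALSE]),
                                        use = "pairwise.complete.obs"))
      r2 <- cc^2
      for (i in seq_along(w)) {
        if (!keep[w[i]]) next
        for (j in seq_along(w)) {
          if (j <= i || !keep[w[j]]) next
          if (!is.na(r2[i, j]) && r2[i, j] > r2_threshold) {
            keep[w[j]] <- FALSE
            removed_any <- TRUE
          }
        }
      }
    }
    if (!removed_any) break
  }
  out <- d[keep, , drop = FALSE]
  attr(out, "chrom") <- attr(d, "chrom")[keep]
  attr(out, "pos") <- attr(d, "pos")[keep]
  attr(out, "kept") <- keep
  attr(out, "n_pruned") <- sum(!keep)
  attr(out, "n_zero_variance") <- sum(zero_var)
  out
}

#' PCA of samples from genotype dosages
#'
#' Centres each site on its mean dosage (mean-imputing missing entries
#' first) and decomposes the samples x sites matrix by SVD. The sign of
#' each component is fixed by making its largest-magnitude site loading
#' positive, so results are fully deterministic.
#'
#' @param d Dosage matrix (sites x samples).
#' @param n_components Number of components to return (default
#'   `min(10, n_samples - 1)`).
#' @return List of class `pca_result`: `coords` (samples x k matrix),
#'   `explained` (variance fraction per component), `n_imputed`.
#' @export
pca_dosage <- function(d, n_components = NULL) {
  n_samp <- ncol(d)
  if (n_samp < 2) stop("PCA needs at least 2 samples")
  if (is.null(n_components)) n_components <- min(10L, n_samp - 1L)
  if (n_components > n_samp - 1L) {
    stop("n_components must be <= n_samples - 1 (= ", n_samp - 1L, ")")
  }
  m <- d
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    rm_ <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rm_[idx[, 1]]
  }
  x <- t(m)                               # samples x sites
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_components, nv = n_components)
  dvals <- sv$d[seq_len(n_components)]
  coords <- sv$u %*% diag(dvals, n_components, n_components)
  # sign convention: largest-|loading| positive per component
  for (k in seq_len(n_components)) {
    ld <- sv$v[, k]
    top <- which.max(abs(ld))
    if (ld[top] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- colnames(d)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  tot <- sum(sv$d^2)
  explained <- if (tot > 0) sv$d[seq_len(n_components)]^2 / tot
               else rep(0, n_components)
  structure(list(coords = coords, explained = explained,
                 n_imputed = n_imputed),
            class = "pca_result")
}
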