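#' Per-site components of Hudson's F_ST
#'
#' For two populations with alternate-allele frequencies p1, p2 estimated
#' from n1, n2 haplotypes, the Hudson estimator (in the Bhatia et al.
#' ratio-of-averages form) has per-site numerator and denominator
#' \deqn{N = (p_1 - p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#' \deqn{D = p_1(1-p_2) + p_2(1-p_1)}
#' Sites with fewer than 2 observed haplotypes in either population are
#' masked (N, D set to `NA`). Negative per-site numerators are kept: the
#' estimator is unbiased only if they enter the sums.
#'
#' @param ac_a,ac_b Integer matrices sites x 2 (`ref`, `alt` counts), e.g.
#'   two elements of [biallelic_counts()].
#' @return `data.frame` of class `hudson_components` with columns `N`, `D`,
#'   `fst` (per-site ratio where `D > 0`, else `NA`), `masked`.
#' @export
hudson_fst_components <- function(ac_a, ac_b) {
  stopifnot(ncol(ac_a) == 2, ncol(ac_b) == 2, nrow(ac_a) == nrow(ac_b))
  n1 <- rowSums(ac_a); n2 <- rowSums(ac_b)
  if (all(n1 < 2) || all(n2 < 2)) {
    stop("insufficient haplotypes: a population has n < 2 at every site")
  }
  masked <- n1 < 2 | n2 < 2
  p1 <- ac_a[, 2] / n1
  p2 <- ac_b[, 2] / n2
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  N[masked] <- NA_real_
  D[masked] <- NA_real_
  fst <- ifelse(!masked & D > 0, N / D, NA_real_)
  structure(data.frame(N = N, D = D, fst = fst, masked = masked),
            class = c("hudson_components", "data.frame"))
}

#' Tile a chromosome into windows
#' @noRd
window_index <- function(pos, window_size, step = window_size, max_pos = NULL) {
  if (is.null(max_pos)) max_pos <- max(pos, 1L)
  starts <- seq.int(1L, max(1L, max_pos), by = step)
  data.frame(start = starts, end = starts + window_size - 1L)
}

#' Windowed statistic from per-site Hudson components
#'
#' Aggregates per-site numerators and denominators into windows as a ratio
#' of averages: window F_ST = sum(N) / sum(D) over contained, unmasked
#' sites. Windows with no sites or zero summed denominator get `NA`.
#' Windows tile each chromosome from position 1; with the default
#' `step = window_size` they are nonoverlapping; a smaller step gives
#' overlapping (sliding) windows.
#'
#' @param comp A `hudson_components`.
#' @param chrom,pos Site coordinates aligned with `comp` rows (1-based).
#' @param window_size Window span in bp (default 20000).
#' @param step Step between window starts in bp.
#' @return `data.frame` (class `windowed_stat`): `chrom`, `start`, `end`
#'   (1-based inclusive), `value`, `n_variants`.
#' @export
windowed_fst <- function(comp, chrom, pos, window_size = 20000L,
                         step = window_size) {
  windowed_ratio(comp$N, comp$D, chrom, pos, window_size, step)
}

windowed_ratio <- function(N, D, chrom, pos, window_size, step) {
  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome")
    w <- window_index(p, window_size, step)
    nsel <- N[sel]; dsel <- D[sel]
    res <- lapply(seq_len(nrow(w)), function(i) {
      inw <- p >= w$start[i] & p <= w$end[i]
      nv <- sum(inw & !is.na(dsel))
      sD <- sum(dsel[inw], na.rm = TRUE)
      val <- if (nv > 0 && sD > 0) sum(nsel[inw], na.rm = TRUE) / sD else NA_real_
      c(val, sum(inw))
    })
    m <- do.call(rbind, res)
    out[[ch]] <- data.frame(chrom = ch, start = w$start, end = w$end,
                            value = m[, 1], n_variants = as.integer(m[, 2]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("windowed_stat", "data.frame")
  res
}

#' Population branch statistic
#'
#' Converts pairwise F_ST into population-scaled branch lengths
#' \eqn{T = -\log(1 - F_{ST})} and returns the branch length of the focal
#' population A in the (A, B; C) tree:
#' \deqn{PBS_A = (T_{AB} + T_{AC} - T_{BC}) / 2}
#' F_ST values are clipped to `[0, 1 - eps]` before the log so that fixed
#' differences yield finite branch lengths; clipped entries are flagged.
#'
#' @param fst_ab,fst_ac,fst_bc Aligned numeric vectors (or `windowed_stat`
#'   tables on identical windows) of pairwise F_ST: focal-vs-close,
#'   focal-vs-outgroup, close-vs-outgroup.
#' @param eps Clipping margin (default 1e-6).
#' @return `data.frame` with `T_ab`, `T_ac`, `T_bc`, `pbs`, `clipped`; when
#'   window tables were supplied, prefixed by their `chrom`,`start`,`end`.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc, eps = 1e-6) {
  meta <- NULL
  if (is.data.frame(fst_ab)) {
    for (other in list(fst_ac, fst_bc)) {
      if (!is.data.frame(other) ||
          !identical(fst_ab[c("chrom", "start", "end")],
                     other[c("chrom", "start", "end")])) {
        stop("PBS inputs are not aligned on identical windows")
      }
    }
    meta <- fst_ab[c("chrom", "start", "end")]
    fst_ab <- fst_ab$value; fst_ac <- fst_ac$value; fst_bc <- fst_bc$value
  }
  if (length(fst_ab) != length(fst_ac) || length(fst_ab) != length(fst_bc)) {
    stop("PBS inputs must have equal length")
  }
  clip <- function(x) pmin(pmax(x, 0), 1 - eps)
  clipped <- (fst_ab > 1 - eps | fst_ac > 1 - eps | fst_bc > 1 - eps)
  clipped[is.na(clipped)] <- FALSE
  T_ab <- -log(1 - clip(fst_ab))
  T_ac <- -log(1 - clip(fst_ac))
  T_bc <- -log(1 - clip(fst_bc))
  res <- data.frame(T_ab = T_ab, T_ac = T_ac, T_bc = T_bc,
                    pbs = (T_ab + T_ac - T_bc) / 2, clipped = clipped)
  if (!is.null(meta)) res <- cbind(meta, res)
  res
}

harmonic_number <- function(k) {
  vapply(k, function(m) if (m < 1) NA_real_ else sum(1 / seq_len(m)), 0)
}

# per-site mean pairwise difference from an allele-count row
site_pi <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  (n^2 - sum(counts^2)) / (n * (n - 1))
}

#' Windowed nucleotide diversity and Watterson's theta for one group
#'
#' Per window, nucleotide diversity is the sum over sites of the mean
#' pairwise difference \eqn{\sum_{j<k} c_j c_k / \binom{n}{2}} divided by
#' the full window span in bp, and Watterson's theta is
#' \eqn{S / (a_{n-1} L)} with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i} the
#' harmonic number and S the number of segregating sites. The window span
#' is used as-is: coverage gaps inherent to RNA-seq are not corrected for,
#' so absolute values are comparable between groups of the same experiment
#' but depressed relative to whole-genome sequencing.
#'
#' Genome-wide means are accompanied by a seeded percentile bootstrap over
#' windows (95% CI). Samples can be down-sampled to a common replicate
#' number before counting, as one does when comparing groups of unequal
#' size.
#'
#' @param v A `called_variants`.
#' @param sheet A `sample_sheet`.
#' @param group Treatment group to analyse.
#' @param window_size,step Window span and step in bp.
#' @param downsample_n Optional number of samples drawn (without
#'   replacement, seeded) from the group before counting.
#' @param n_boot Bootstrap replicates for the genome-wide CI (default 10000).
#' @param seed Seed for down-sampling and bootstrap.
#' @return List of class `diversity_result`: `windows` (chrom, start, end,
#'   pi, theta_w, S, n_variants), `summary` (one row: group, mean and 95% CI
#'   for pi and theta), `a_n` (harmonic number at the group's full haplotype
#'   count), `samples_used`.
#' @export
diversity <- function(v, sheet, group, window_size = 20000L,
                      step = window_size, downsample_n = NULL,
                      n_boot = 10000L, seed = 1L) {
  samps <- group_samples(sheet)[[group]]
  if (is.null(samps)) stop("unknown group: ", group)
  rng <- seeded_rng(seed, "diversity", group)
  if (!is.null(downsample_n)) {
    if (downsample_n > length(samps)) stop("downsample_n exceeds group size")
    samps <- sort(sample(samps, downsample_n))
  }
  sub_sheet <- sheet[sheet$sampleID %in% samps, , drop = FALSE]
  class(sub_sheet) <- class(sheet)
  if (length(samps) * v$ploidy < 2) stop("need at least 2 haplotypes")
  gac <- group_allele_counts(v, sub_sheet)
  cm <- gac$counts[[group]]
  pi_site <- apply(cm, 1, site_pi)
  n_hap <- rowSums(cm)
  seg <- rowSums(cm > 0) >= 2
  theta_site <- ifelse(seg & n_hap >= 2, 1 / harmonic_number(pmax(n_hap - 1, 1)), 0)

  chrom <- v$sites$chrom; pos <- v$sites$pos
  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    w <- window_index(pos[sel], window_size, step)
    p <- pos[sel]
    rows <- lapply(seq_len(nrow(w)), function(i) {
      inw <- p >= w$start[i] & p <= w$end[i]
      L <- window_size
      c(pi = sum(pi_site[sel][inw], na.rm = TRUE) / L,
        theta_w = sum(theta_site[sel][inw], na.rm = TRUE) / L,
        S = sum(seg[sel] & inw),
        n_variants = sum(inw))
    })
    m <- do.call(rbind, rows)
    out[[ch]] <- data.frame(chrom = ch, start = w$start, end = w$end, m)
  }
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL

  boot_ci <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    means <- vapply(seq_len(n_boot), function(i) {
      mean(x[sample.int(length(x), replace = TRUE)])
    }, 0)
    stats::quantile(means, c(0.025, 0.975), names = FALSE)
  }
  ci_pi <- boot_ci(windows$pi)
  ci_th <- boot_ci(windows$theta_w)
  summary <- data.frame(
    group = group, n_samples = length(samps),
    pi = mean(windows$pi, na.rm = TRUE),
    pi_ci_low = ci_pi[1], pi_ci_high = ci_pi[2],
    theta = mean(windows$theta_w, na.rm = TRUE),
    theta_ci_low = ci_th[1], theta_ci_high = ci_th[2])
  structure(list(windows = windows, summary = summary,
                 a_n = harmonic_number(length(samps) * v$ploidy - 1),
                 samples_used = samps),
            class = "diversity_result")
}

#' Per-group inbreeding coefficient
#'
#' F_IS = 1 - mean(H_obs) / mean(H_exp) over sites where the group is
#' polymorphic, with H_obs the fraction of non-missing samples carrying at
#' least two distinct alleles and H_exp = 1 - sum(p_a^2) the expected
#' heterozygosity from the group's allele frequencies (no small-sample
#' correction; the estimator choice is documented in the package vignette).
#'
#' @param v A `called_variants` with ploidy >= 2.
#' @param sheet A `sample_sheet`.
#' @return `data.frame` with `group`, `f_is`, `n_sites` (polymorphic sites
#'   used). Groups monomorphic everywhere get `NA` with a warning.
#' @export
inbreeding_coefficient <- function(v, sheet) {
  if (v$ploidy < 2) stop("inbreeding coefficient needs ploidy >= 2")
  gac <- group_allele_counts(v, sheet)
  gs <- group_samples(sheet)
  res <- lapply(names(gs), function(g) {
    j <- match(gs[[g]], v$samples)
    sub <- v$gt[, j, , drop = FALSE]
    same <- matrix(TRUE, nrow(v$sites), length(j))
    for (h in seq_len(v$ploidy)[-1]) {
      same <- same & (sub[, , h] == sub[, , 1])
    }
    het <- ifelse(rowSums(is.na(sub), dims = 2) > 0, NA,
                  as.integer(!same))
    h_obs <- rowMeans(het, na.rm = TRUE)
    cm <- gac$counts[[g]]
    n <- rowSums(cm)
    h_exp <- ifelse(n > 0, 1 - rowSums((cm / pmax(n, 1))^2), NA_real_)
    use <- !is.na(h_exp) & h_exp > 0 & !is.nan(h_obs)
    if (!any(use)) {
      warning("group ", g, ": all sites monomorphic, F_IS undefined")
      return(data.frame(group = g, f_is = NA_real_, n_sites = 0L))
    }
    data.frame(group = g,
               f_is = 1 - mean(h_obs[use]) / mean(h_exp[use]),
               n_sites = sum(use))
  })
  do.call(rbind, res)
}

#' Per-gene F_ST with top-percentile flagging
#'
#' Averages Hudson components over the variants inside each gene span
#' (ratio of averages, as for windows), ranks genes that contain at least
#' one variant by percentile, and flags the top `top_percentile` percent.
#' Percentile rank of the r-th of n ordered genes is 100 (r - 1) / (n - 1)
#' (100 when n = 1), so the best gene always ranks 100 and with 100
#' distinct genes and the default 5, exactly five are flagged.
#'
#' @param comp A `hudson_components`.
#' @param chrom,pos Site coordinates aligned with `comp`.
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [gff_genes()].
#' @param top_percentile Percent of genes to flag (default 5).
#' @return `data.frame` (class `gene_stat`): `gene_id`, `chrom`, `start`,
#'   `end`, `fst`, `n_variants`, `percentile`, `top_flag`.
#' @export
per_gene_fst <- function(comp, chrom, pos, genes, top_percentile = 5) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    ing <- chrom == genes$chrom[i] & pos >= genes$start[i] & pos <= genes$end[i]
    nv <- sum(ing & !is.na(comp$D))
    sD <- sum(comp$D[ing], na.rm = TRUE)
    val <- if (nv > 0 && sD > 0) sum(comp$N[ing], na.rm = TRUE) / sD else NA_real_
    c(val, nv)
  })
  m <- do.call(rbind, rows)
  res <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    fst = m[, 1], n_variants = as.integer(m[, 2]),
                    percentile = NA_real_, top_flag = FALSE)
  has <- !is.na(res$fst)
  if (any(has)) {
    r <- rank(res$fst[has], ties.method = "average")
    nh <- sum(has)
    res$percentile[has] <- if (nh == 1) 100 else 100 * (r - 1) / (nh - 1)
    res$top_flag[has] <- res$percentile[has] >= 100 - top_percentile
  }
  class(res) <- c("gene_stat", "data.frame")
  res
}
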