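#' Pooled inversion karyotype frequency from tag SNPs
#'
#' Karyotype-tagging SNPs are alleles inside inversion breakpoints that are
#' (almost) fixed between the inverted and standard arrangements. For a
#' pooled library the inversion frequency is estimated as the unweighted
#' mean, over covered tag SNPs, of the fraction of reads carrying the
#' inverted allele: 0 means no inverted alleles anywhere, 1 means every
#' read at every tag carries the inverted allele. A depth-weighted variant
#' (`weighted = TRUE`) pools reads across tags instead.
#'
#' @param p A `pileup_counts` covering the tag loci.
#' @param panel A `tag_snps` marker panel (may carry several inversions).
#' @param weighted Depth-weighted pooling across tag SNPs.
#' @return `data.frame` of class `karyotype_result`: `sample`, `inversion`,
#'   `frequency`, `n_tags`, `n_covered`. Samples with zero covered tags get
#'   `NA` with a warning.
#' @export
karyotype_frequency <- function(p, panel, weighted = FALSE) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (inv in unique(panel$inversion)) {
    tags <- panel[panel$inversion == inv, , drop = FALSE]
    sub <- merge(p, tags[c("chrom", "pos", "inverted_allele")],
                 by = c("chrom", "pos"))
    inv_count <- as.integer(as.matrix(sub[bases])[
      cbind(seq_len(nrow(sub)), match(sub$inverted_allele, bases))])
    sub$inv_frac <- ifelse(sub$depth > 0, inv_count / sub$depth, NA_real_)
    sub$inv_count <- inv_count
    per <- lapply(split(sub, sub$sample), function(sdf) {
      cov <- sdf[sdf$depth > 0, , drop = FALSE]
      freq <- if (nrow(cov) == 0) {
        warning("sample ", sdf$sample[1], ": no covered tag SNPs for ", inv)
        NA_real_
      } else if (weighted) {
        sum(cov$inv_count) / sum(cov$depth)
      } else {
        mean(cov$inv_frac)
      }
      data.frame(sample = sdf$sample[1], inversion = inv, frequency = freq,
                 n_tags = nrow(tags), n_covered = nrow(cov))
    })
    out[[inv]] <- do.call(rbind, per)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("karyotype_result", "data.frame")
  res
}

#' Compare karyotype frequencies between treatment groups
#'
#' Two-sided Mann-Whitney U tests of per-replicate inversion frequencies
#' for each requested contrast, exact when group sizes are small and no
#' ties are present (R's `wilcox.test` convention: exact for n < 50, normal
#' approximation with continuity correction otherwise or when ties occur).
#' P-values are Benjamini-Hochberg adjusted across all contrasts x
#' inversions reported together.
#'
#' @param k A `karyotype_result`.
#' @param sheet A `sample_sheet`.
#' @param contrasts List of 2-vectors `c(groupA, groupB)`.
#' @return `data.frame`: `inversion`, `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `u_statistic`, `p_value`, `p_adjusted`. Contrasts with < 2
#'   replicates in a group are skipped with a warning.
#' @export
compare_karyotypes <- function(k, sheet, contrasts) {
  k <- merge(k, data.frame(sample = sheet$sampleID, group = sheet$treatment))
  rows <- list()
  for (inv in unique(k$inversion)) {
    for (ct in contrasts) {
      a <- k$frequency[k$inversion == inv & k$group == ct[1]]
      b <- k$frequency[k$inversion == inv & k$group == ct[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        warning("contrast ", ct[1], " vs ", ct[2], " (", inv,
                ") skipped: fewer than 2 replicates in a group")
        next
      }
      if (length(unique(c(a, b))) == 1) {
        # fully tied data carry no evidence either way
        u <- length(a) * length(b) / 2; pv <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                                  correct = TRUE))
        u <- unname(wt$statistic); pv <- min(wt$p.value, 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        inversion = inv, group_a = ct[1], group_b = ct[2],
        mean_a = mean(a), mean_b = mean(b),
        u_statistic = u, p_value = pv)
    }
  }
  if (!length(rows)) return(data.frame())
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  rownames(res) <- NULL
  res
}
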