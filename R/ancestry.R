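#' Ancestry fractions from ancestry-informative markers
#'
#' At each AIM with an observation, allele observations matching the
#' species-A or species-B diagnostic allele are tallied; observations
#' matching neither are counted as uninformative and never attributed to a
#' species (imported AIM panels may not be diagnostic outside the
#' population they were derived from). Fractions — not per-locus majority
#' votes — are reported, because pooled libraries are allele mixtures by
#' construction; a diploid heterozygote therefore contributes half a count
#' to each species.
#'
#' Genotype source is either filtered VCF calls (haplotype alleles at AIM
#' positions) or read pileups (base counts), the latter useful for loci
#' lost to missingness filters.
#'
#' @param x A `called_variants` or a `pileup_counts`.
#' @param panel An `aims` marker panel.
#' @param sheet A `sample_sheet`.
#' @return List of class `ancestry_result`: `per_chrom` (sample, chrom,
#'   n_called, count_a, count_b, count_other, frac_a), `per_sample`
#'   (genome-wide), `per_group` (group means of per-sample fractions).
#' @export
aim_ancestry <- function(x, panel, sheet) {
  if (nrow(panel) == 0) stop("empty AIM panel")
  if (inherits(x, "called_variants")) {
    obs <- aim_obs_from_calls(x, panel)
  } else if (inherits(x, "pileup_counts")) {
    obs <- aim_obs_from_pileup(x, panel)
  } else {
    stop("x must be called_variants or pileup_counts")
  }
  # obs: sample, chrom, pos, count_a, count_b, count_other
  obs$n_obs <- obs$count_a + obs$count_b + obs$count_other
  obs <- obs[obs$n_obs > 0, , drop = FALSE]
  agg <- stats::aggregate(obs[c("count_a", "count_b", "count_other")],
                          by = obs[c("sample", "chrom")], FUN = sum)
  ncall <- stats::aggregate(list(n_called = obs$pos),
                            by = obs[c("sample", "chrom")], FUN = length)
  per_chrom <- merge(agg, ncall)
  per_chrom$frac_a <- with(per_chrom,
    ifelse(count_a + count_b > 0, count_a / (count_a + count_b), NA_real_))
  per_chrom <- per_chrom[order(per_chrom$sample, per_chrom$chrom),
                         c("sample", "chrom", "n_called", "count_a",
                           "count_b", "count_other", "frac_a")]
  rownames(per_chrom) <- NULL

  per_sample <- stats::aggregate(
    per_chrom[c("n_called", "count_a", "count_b", "count_other")],
    by = per_chrom["sample"], FUN = sum)
  per_sample$frac_a <- with(per_sample,
    ifelse(count_a + count_b > 0, count_a / (count_a + count_b), NA_real_))
  per_sample <- merge(per_sample, data.frame(sample = sheet$sampleID,
                                             group = sheet$treatment))
  per_group <- stats::aggregate(list(frac_a = per_sample$frac_a,
                                     n_called = per_sample$n_called),
                                by = per_sample["group"], FUN = mean)
  structure(list(per_chrom = per_chrom, per_sample = per_sample,
                 per_group = per_group),
            class = "ancestry_result")
}

aim_obs_from_calls <- function(v, panel) {
  key_site <- paste(v$sites$chrom, v$sites$pos)
  key_panel <- paste(panel$chrom, panel$pos)
  idx <- match(key_panel, key_site)
  rows <- list()
  for (i in which(!is.na(idx))) {
    si <- idx[i]
    alleles <- c(v$sites$ref[si], v$sites$alt[[si]])   # index 0..k -> base
    for (j in seq_along(v$samples)) {
      calls <- v$gt[si, j, ]
      calls <- calls[!is.na(calls)]
      if (!length(calls)) next
      bases <- alleles[calls + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = v$samples[j], chrom = panel$chrom[i], pos = panel$pos[i],
        count_a = sum(bases == panel$alleleA[i]),
        count_b = sum(bases == panel$alleleB[i]),
        count_other = sum(bases != panel$alleleA[i] &
                          bases != panel$alleleB[i]))
    }
  }
  if (!length(rows)) {
    return(data.frame(sample = character(), chrom = character(),
                      pos = integer(), count_a = integer(),
                      count_b = integer(), count_other = integer()))
  }
  do.call(rbind, rows)
}

aim_obs_from_pileup <- function(p, panel) {
  sub <- merge(p, as.data.frame(panel)[c("chrom", "pos", "alleleA", "alleleB")],
               by = c("chrom", "pos"))
  bases <- c("A", "C", "G", "T")
  m <- as.matrix(sub[bases])
  ia <- match(sub$alleleA, bases); ib <- match(sub$alleleB, bases)
  ca <- m[cbind(seq_len(nrow(sub)), ia)]
  cb <- m[cbind(seq_len(nrow(sub)), ib)]
  data.frame(sample = sub$sample, chrom = sub$chrom, pos = sub$pos,
             count_a = as.integer(ca), count_b = as.integer(cb),
             count_other = as.integer(sub$depth - ca - cb))
}
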