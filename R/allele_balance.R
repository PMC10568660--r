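#' Collect per-sample base counts at panel loci
#'
#' The expressed allele balance is computed straight from read pileups, not
#' from called genotypes, so low-frequency alleles in pooled libraries are
#' not rounded away by the caller. Input is either a precomputed count
#' table (TSV with columns `sample, chrom, pos, A, C, G, T`) or one indexed
#' BAM per sample, counted via `Rsamtools::pileup` with conventional read
#' filters (base quality >= 13, mapping quality >= 1).
#'
#' Duplicate rows for the same sample/locus in a count TSV are summed, so
#' counts split across rows are equivalent to one row with the totals.
#'
#' @param source Path to a count TSV, or a named character vector of BAM
#'   paths (names = sample IDs).
#' @param panel A `marker_panel` (any kind with `chrom`/`pos` columns).
#' @param samples Character vector of expected sample IDs; for a TSV,
#'   samples absent from the table get zero counts at every locus.
#' @param min_base_quality,min_mapping_quality Read filters for BAM input.
#' @return `data.frame` of class `pileup_counts`: `sample`, `chrom`, `pos`,
#'   `A`, `C`, `G`, `T`, `depth` — one row per sample x panel locus.
#' @export
collect_pileup <- function(source, panel, samples = NULL,
                           min_base_quality = 13L, min_mapping_quality = 1L) {
  loci <- unique(data.frame(chrom = panel$chrom, pos = panel$pos))
  if (is.character(source) && length(source) == 1 && file.exists(source) &&
      !grepl("\\.bam$", source, ignore.case = TRUE)) {
    tab <- utils::read.delim(source, header = TRUE, sep = "\t",
                             check.names = FALSE)
    need <- c("sample", "chrom", "pos", "A", "C", "G", "T")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("count table missing column(s): ",
                           paste(miss, collapse = ", "))
    if (is.null(samples)) samples <- unique(tab$sample)
    bad <- setdiff(unique(tab$chrom), unique(loci$chrom))
    # extra contigs in the table are fine; unknown contigs in the panel are not
    grid <- merge(data.frame(sample = samples), loci)
    agg <- stats::aggregate(tab[c("A", "C", "G", "T")],
                            by = tab[c("sample", "chrom", "pos")], FUN = sum)
    out <- merge(grid, agg, by = c("sample", "chrom", "pos"), all.x = TRUE)
    for (b in c("A", "C", "G", "T")) out[[b]][is.na(out[[b]])] <- 0L
  } else {
    bams <- source
    if (is.null(names(bams))) stop("BAM input must be a named vector (names = sample IDs)")
    out <- do.call(rbind, lapply(names(bams), function(s) {
      bf <- Rsamtools::BamFile(bams[[s]])
      known <- names(Rsamtools::scanBamHeader(bf)$targets)
      bad <- setdiff(unique(loci$chrom), known)
      if (length(bad)) stop("panel locus on contig absent from BAM: ",
                            paste(bad, collapse = ", "))
      gr <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$pos, loci$pos))
      pp <- Rsamtools::PileupParam(max_depth = 100000L,
                                   min_base_quality = as.integer(min_base_quality),
                                   min_mapq = as.integer(min_mapping_quality),
                                   distinguish_strands = FALSE,
                                   distinguish_nucleotides = TRUE,
                                   include_deletions = FALSE,
                                   include_insertions = FALSE)
      res <- Rsamtools::pileup(bf,
                               scanBamParam = Rsamtools::ScanBamParam(which = gr),
                               pileupParam = pp)
      base <- data.frame(sample = s, chrom = loci$chrom, pos = loci$pos,
                         A = 0L, C = 0L, G = 0L, T = 0L)
      if (nrow(res)) {
        res <- res[res$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
        for (i in seq_len(nrow(res))) {
          r <- which(base$chrom == as.character(res$seqnames[i]) &
                     base$pos == res$pos[i])
          nb <- as.character(res$nucleotide[i])
          base[r, nb] <- base[r, nb] + res$count[i]
        }
      }
      base
    }))
  }
  out$depth <- out$A + out$C + out$G + out$T
  out <- out[order(out$sample, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pileup_counts", "data.frame")
  out
}

#' Expressed allele balance at variants of interest
#'
#' Per replicate and locus, the allele balance f is the fraction of reads
#' carrying the panel's alternate base. Only that base counts toward f;
#' reads carrying a third allele are tallied separately. A covered locus
#' with zero alternate reads is `not_detected` (the heatmap's blank cell),
#' a locus with no reads at all is `no_coverage`.
#'
#' Group summaries are unweighted means of per-replicate frequencies over
#' covered replicates — replicates, not reads, are the biological unit —
#' with a seeded percentile-bootstrap 95% CI (2000 resamples). A
#' depth-weighted pooled alternative is available via `weighted = TRUE`.
#'
#' @param p A `pileup_counts`.
#' @param panel A `variants_of_interest` marker panel.
#' @param sheet A `sample_sheet`.
#' @param weighted If `TRUE`, group frequency pools reads across replicates
#'   instead of averaging per-replicate frequencies.
#' @param n_boot Bootstrap resamples for the group CI.
#' @param seed Bootstrap seed.
#' @return List of class `allele_balance_result`: `per_sample`
#'   (sample, name, chrom, pos, ref_count, alt_count, other_count, depth,
#'   freq, state) and `per_group` (group, name, mean_freq, ci_low, ci_high,
#'   n_covered).
#' @export
allele_balance <- function(p, panel, sheet, weighted = FALSE,
                           n_boot = 2000L, seed = 1L) {
  key <- merge(p, as.data.frame(panel)[c("chrom", "pos", "ref", "alt", "name")],
               by = c("chrom", "pos"))
  bases <- c("A", "C", "G", "T")
  ref_count <- as.integer(as.matrix(key[bases])[cbind(seq_len(nrow(key)),
                                                      match(key$ref, bases))])
  alt_count <- as.integer(as.matrix(key[bases])[cbind(seq_len(nrow(key)),
                                                      match(key$alt, bases))])
  per_sample <- data.frame(
    sample = key$sample, name = key$name, chrom = key$chrom, pos = key$pos,
    ref_count = ref_count, alt_count = alt_count,
    other_count = key$depth - ref_count - alt_count, depth = key$depth)
  per_sample$freq <- ifelse(per_sample$depth > 0,
                            per_sample$alt_count / per_sample$depth, NA_real_)
  per_sample$state <- ifelse(per_sample$depth == 0, "no_coverage",
                      ifelse(per_sample$alt_count == 0, "not_detected",
                             "frequency"))
  per_sample <- merge(per_sample,
                      data.frame(sample = sheet$sampleID,
                                 group = sheet$treatment))
  per_sample <- per_sample[order(per_sample$name, per_sample$sample), ]
  rownames(per_sample) <- NULL

  seeded_rng(seed, "allele_balance")
  groups <- split(per_sample, list(per_sample$group, per_sample$name),
                  drop = TRUE)
  per_group <- do.call(rbind, lapply(groups, function(gdf) {
    cov <- gdf[gdf$depth > 0, , drop = FALSE]
    if (nrow(cov) == 0) {
      return(data.frame(group = gdf$group[1], name = gdf$name[1],
                        mean_freq = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_covered = 0L))
    }
    mf <- if (weighted) sum(cov$alt_count) / sum(cov$depth) else mean(cov$freq)
    ci <- c(NA_real_, NA_real_)
    if (nrow(cov) >= 2) {
      bs <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(nrow(cov), replace = TRUE)
        if (weighted) sum(cov$alt_count[idx]) / sum(cov$depth[idx])
        else mean(cov$freq[idx])
      }, 0)
      ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    }
    data.frame(group = gdf$group[1], name = gdf$name[1], mean_freq = mf,
               ci_low = ci[1], ci_high = ci[2], n_covered = nrow(cov))
  }))
  rownames(per_group) <- NULL
  structure(list(per_sample = per_sample, per_group = per_group),
            class = "allele_balance_result")
}
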