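#' @importFrom methods as is
NULL

#' Construct a CalledVariants object
#'
#' The in-memory representation of a filtered (or unfiltered) multi-sample
#' callset. Genotypes are stored as an integer array of allele indices
#' (0 = reference, 1 = first alternate, ...) with dimensions
#' `sites x samples x ploidy`; a missing haplotype call is `NA`. This keeps
#' arbitrary ploidy (pooled libraries are samples of ploidy 2 x pool size)
#' and keeps MISSING distinguishable from homozygous reference.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (list column of character vectors), `qual`, and optionally `ann`
#'   (list column of SnpEff-style ANN strings).
#' @param gt Integer array `sites x samples x ploidy`.
#' @param samples Character vector of sample IDs (column order of `gt`).
#' @return An object of class `called_variants`.
#' @export
called_variants <- function(sites, gt, samples) {
  stopifnot(is.data.frame(sites), length(dim(gt)) == 3,
            nrow(sites) == dim(gt)[1], length(samples) == dim(gt)[2])
  if (!is.list(sites$alt)) sites$alt <- strsplit(as.character(sites$alt), ",")
  if (is.null(sites$ann)) sites$ann <- rep(list(character(0)), nrow(sites))
  if (nrow(sites) > 0) {
    stopifnot(all(sites$pos >= 1), all(nzchar(sites$ref)),
              all(lengths(sites$alt) >= 1))
    nall <- 1L + lengths(sites$alt)
    mx <- suppressWarnings(apply(gt, 1, max, na.rm = TRUE))
    mx[!is.finite(mx)] <- 0L
    if (any(mx >= nall)) stop("allele index exceeds number of alleles at site")
  }
  structure(list(sites = sites, gt = gt, samples = samples,
                 ploidy = dim(gt)[3]),
            class = "called_variants")
}

#' @export
print.called_variants <- function(x, ...) {
  cat(sprintf("called_variants: %d sites x %d samples (ploidy %d)\n",
              nrow(x$sites), length(x$samples), x$ploidy))
  invisible(x)
}

#' @export
dim.called_variants <- function(x) dim(x$gt)

#' Subset sites of a called_variants object
#' @param x A `called_variants`.
#' @param i Site index (logical or integer).
#' @param ... Ignored.
#' @export
`[.called_variants` <- function(x, i, ...) {
  sites <- x$sites[i, , drop = FALSE]
  rownames(sites) <- NULL
  called_variants(sites, x$gt[i, , , drop = FALSE], x$samples)
}

parse_gt_strings <- function(gt_chr, ploidy) {
  # gt_chr: character matrix sites x samples, entries like "0/1", "0|1|1", "."
  n_sites <- nrow(gt_chr); n_samp <- ncol(gt_chr)
  parts <- strsplit(gt_chr, "[/|]")
  lens <- lengths(parts)
  obs <- unique(lens[vapply(parts, function(p) !all(p == "."), TRUE)])
  if (length(obs) && any(obs != ploidy)) {
    stop("ploidy mismatch: observed GT ploidy ", paste(obs, collapse = "/"),
         " vs configured ", ploidy)
  }
  arr <- array(NA_integer_, c(n_sites, n_samp, ploidy))
  flat <- vapply(parts, function(p) {
    p <- suppressWarnings(as.integer(p))
    c(p, rep(NA_integer_, ploidy))[seq_len(ploidy)]
  }, integer(ploidy))
  # flat is ploidy x (sites*samples), column-major over gt_chr
  for (k in seq_len(ploidy)) {
    arr[, , k] <- matrix(flat[k, ], n_sites, n_samp)
  }
  arr
}

#' Load a VCF into a called_variants object
#'
#' Reads a VCF (any ploidy encoded in GT), restricts columns to the samples
#' in the sheet, sorts records by (chrom, pos) and collapses duplicate
#' identical records to one, mirroring a `vcfuniq` pass. Contig names are
#' taken verbatim; no "chr" normalisation is applied.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sheet A `sample_sheet`; every sample must be present in the VCF.
#' @param config An `analysis_config`; its `ploidy` is checked against the
#'   GT fields.
#' @return A `called_variants`.
#' @export
load_vcf <- function(path, sheet, config) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf_samples <- colnames(vcf)
  missing <- setdiff(sheet$sampleID, vcf_samples)
  if (length(missing)) {
    stop("sample(s) in sheet absent from VCF: ", paste(missing, collapse = ", "))
  }
  vcf <- vcf[, sheet$sampleID]
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(as.list(S4Vectors::split(as.character(unlist(alt)),
              rep(seq_along(alt), lengths(alt)))), unname)
  names(alt_chr) <- NULL
  ann <- rep(list(character(0)), length(vcf))
  info_df <- VariantAnnotation::info(vcf)
  if ("ANN" %in% names(info_df)) {
    ann <- lapply(as.list(info_df$ANN), as.character)
  }
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    stringsAsFactors = FALSE)
  sites$alt <- alt_chr
  sites$ann <- ann
  gt_chr <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt_chr)) stop("VCF has no GT genotype field")
  gt <- parse_gt_strings(gt_chr, config$ploidy)

  alt_key <- vapply(sites$alt, paste, "", collapse = ",")
  key <- paste(sites$chrom, sites$pos, sites$ref, alt_key, sep = "\r")
  keep <- !duplicated(key)
  ord <- order(sites$chrom[keep], sites$pos[keep])
  idx <- which(keep)[ord]
  sites <- sites[idx, , drop = FALSE]
  rownames(sites) <- NULL
  called_variants(sites, gt[idx, , , drop = FALSE], sheet$sampleID)
}

#' Write a called_variants object to VCF
#'
#' Emits a minimal, deterministic VCF v4.2 with GT (and ANN when present)
#' that round-trips through [load_vcf()].
#'
#' @param v A `called_variants`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path) {
  s <- v$sites
  contigs <- unique(s$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popscan",
           paste0("##contig=<ID=", contigs, ">"),
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", v$samples), collapse = "\t"))
  n <- nrow(s)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt_txt <- apply(v$gt, c(1, 2), function(a) {
    a <- ifelse(is.na(a), ".", as.character(a))
    paste(a, collapse = "/")
  })
  gt_txt <- matrix(gt_txt, n, length(v$samples))
  info <- vapply(s$ann, function(a) {
    if (length(a)) paste0("ANN=", paste(a, collapse = ",")) else "."
  }, "")
  qual <- ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE, scientific = FALSE))
  body <- paste(s$chrom, s$pos, ".", s$ref,
                vapply(s$alt, paste, "", collapse = ","),
                qual, ".", info, "GT",
                apply(gt_txt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply SNP, quality and missingness filters
#'
#' Retains sites that are single-nucleotide (every REF and ALT allele length
#' 1), have QUAL at or above `config$qual_min`, and have at most
#' `config$max_missing_fraction` of samples with a missing genotype. The
#' default configuration (QUAL >= 30, zero missingness) keeps only variants
#' called in every sample. A per-filter removal report is attached as
#' attribute `"filter_report"`.
#'
#' @param v A `called_variants`.
#' @param config An `analysis_config`.
#' @return Filtered `called_variants` with a `filter_report` attribute
#'   (named integer vector: n_input, removed_non_snp, removed_qual,
#'   removed_missing, n_retained). Filters are assessed on the input
#'   independently, so the report's removal counts are attributable.
#' @export
filter_variants <- function(v, config) {
  n <- nrow(v$sites)
  if (n == 0) {
    out <- v
    attr(out, "filter_report") <- c(n_input = 0L, removed_non_snp = 0L,
                                    removed_qual = 0L, removed_missing = 0L,
                                    n_retained = 0L)
    return(out)
  }
  is_snp <- nchar(v$sites$ref) == 1 &
    vapply(v$sites$alt, function(a) all(nchar(a) == 1), TRUE)
  qual_ok <- !is.na(v$sites$qual) & v$sites$qual >= config$qual_min
  miss <- sample_missing_matrix(v)
  miss_frac <- rowMeans(miss)
  miss_ok <- miss_frac <= config$max_missing_fraction
  keep <- is_snp & qual_ok & miss_ok
  out <- v[keep]
  attr(out, "filter_report") <- c(
    n_input = n,
    removed_non_snp = sum(!is_snp),
    removed_qual = sum(!qual_ok),
    removed_missing = sum(!miss_ok),
    n_retained = sum(keep))
  out
}

# sites x samples logical: TRUE when the sample's genotype is missing
# (any haplotype call absent)
sample_missing_matrix <- function(v) {
  rowSums(is.na(v$gt), dims = 2) > 0
}

#' Per-group allele counts
#'
#' Tallies, for every treatment group and site, how many non-missing
#' haplotype calls carry each allele. This matrix is the substrate of all
#' downstream population-genetic statistics; `n` (the haplotype sample size
#' after missingness) is the sum over alleles.
#'
#' @param v A `called_variants`.
#' @param sheet A `sample_sheet` covering `v$samples`.
#' @return Object of class `grouped_allele_counts`: list with `counts`
#'   (named list of group -> integer matrix sites x alleles, columns
#'   0..max_alt), `sites` (the site table), `groups`.
#' @export
group_allele_counts <- function(v, sheet) {
  if (nrow(v$sites) == 0) stop("no variants to count")
  gs <- group_samples(sheet)
  max_all <- max(1L + lengths(v$sites$alt))
  n_sites <- nrow(v$sites)
  counts <- lapply(gs, function(samps) {
    j <- match(samps, v$samples)
    if (anyNA(j)) stop("sheet sample absent from variants object")
    sub <- v$gt[, j, , drop = FALSE]
    m <- matrix(0L, n_sites, max_all,
                dimnames = list(NULL, as.character(0:(max_all - 1L))))
    for (a in 0:(max_all - 1L)) {
      m[, a + 1L] <- rowSums(sub == a, na.rm = TRUE)
    }
    m
  })
  structure(list(counts = counts, sites = v$sites, groups = names(gs)),
            class = "grouped_allele_counts")
}

#' Reduce grouped allele counts to biallelic (ref vs major alt)
#'
#' The Hudson F_ST estimator, LD pruning and PCA are defined for biallelic
#' sites. Multiallelic sites are reduced to reference vs the alternate
#' allele most frequent across all groups combined; remaining alleles are
#' dropped from both the count and the sample size. The number of reduced
#' sites is recorded in attribute `"n_reduced"`.
#'
#' @param gac A `grouped_allele_counts`.
#' @return List of group -> integer matrix sites x 2 (columns `ref`, `alt`),
#'   with attributes `alt_index` (chosen alternate allele index per site)
#'   and `n_reduced`.
#' @export
biallelic_counts <- function(gac) {
  total <- Reduce(`+`, gac$counts)
  n_alt <- ncol(total) - 1L
  alt_part <- total[, -1L, drop = FALSE]
  alt_idx <- max.col(alt_part, ties.method = "first")
  n_reduced <- sum(rowSums(alt_part > 0) > 1)
  out <- lapply(gac$counts, function(m) {
    cbind(ref = m[, 1L],
          alt = m[cbind(seq_len(nrow(m)), alt_idx + 1L)])
  })
  attr(out, "alt_index") <- alt_idx
  attr(out, "n_reduced") <- n_reduced
  out
}

#' Alternate-allele dosage matrix
#'
#' Per sample and site, the number of haplotype calls carrying the (major)
#' alternate allele, in `[0, ploidy]`; `NA` when the sample's genotype is
#' missing. Multiallelic sites are reduced as in [biallelic_counts()].
#'
#' @param v A `called_variants`.
#' @return Integer matrix sites x samples with attribute `pos`/`chrom`.
#' @export
dosage_matrix <- function(v) {
  n_sites <- nrow(v$sites)
  total_alt <- matrix(0L, n_sites, max(1L, max(lengths(v$sites$alt))))
  for (a in seq_len(ncol(total_alt))) {
    total_alt[, a] <- apply(v$gt == a, 1, sum, na.rm = TRUE)
  }
  alt_idx <- max.col(total_alt, ties.method = "first")
  d <- vapply(seq_len(dim(v$gt)[2]), function(j) {
    rowSums(v$gt[, j, , drop = FALSE] == alt_idx, na.rm = TRUE)
  }, numeric(n_sites))
  d <- matrix(as.integer(d), n_sites, length(v$samples),
              dimnames = list(NULL, v$samples))
  d[sample_missing_matrix(v)] <- NA_integer_
  attr(d, "chrom") <- v$sites$chrom
  attr(d, "pos") <- v$sites$pos
  d
}
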