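#' Simulation configuration
#'
#' Collects the parameters of the synthetic world: a Balding-Nichols island
#' model (each population's allele frequency is Beta-distributed around an
#' ancestral frequency with drift parameter F, so the expected Hudson F_ST
#' of a pair of populations equals F), binomial genotype and read sampling,
#' and toy annotation/marker panels. Defaults mirror a small RNA-seq
#' selection experiment: two populations of six replicates, one 20-Mb
#' chromosomal arm, 10,000 SNPs, mean read depth 30, Illumina-scale error
#' rate 0.001, and a genome that is 46% genic.
#'
#' @param n_pops Number of populations.
#' @param f_target Balding-Nichols drift parameter F in `[0, 1)`; may be a
#'   vector of per-population values.
#' @param n_sites Number of variant sites.
#' @param chrom,chrom_length Contig name and length in bp.
#' @param n_samples Samples (replicates) per population.
#' @param ploidy Haplotypes per sample (2 x pool size for pooled libraries).
#' @param depth_mean Mean read depth for pileup simulation (Poisson).
#' @param error_rate Per-base sequencing error rate.
#' @param genic_fraction,exon_fraction Toy-GFF3 composition: fraction of the
#'   genome inside genes, and fraction of each gene that is exonic.
#' @param n_genes,n_tags,n_aims,n_voi Panel sizes for the toy annotation,
#'   inversion tag SNPs, ancestry-informative markers and variants of
#'   interest.
#' @param seed Global seed; all per-component streams are derived from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2L, f_target = 0.1, n_sites = 10000L,
                       chrom = "2L", chrom_length = 20000000L,
                       n_samples = 6L, ploidy = 2L,
                       depth_mean = 30, error_rate = 0.001,
                       genic_fraction = 0.46, exon_fraction = 0.5,
                       n_genes = 100L, n_tags = 200L, n_aims = 100L,
                       n_voi = 4L, seed = 1L) {
  if (any(f_target < 0) || any(f_target >= 1)) {
    stop("f_target must lie in [0, 1); F = 1 is degenerate")
  }
  if (depth_mean < 0) stop("depth_mean must be >= 0")
  structure(list(n_pops = as.integer(n_pops), f_target = f_target,
                 n_sites = as.integer(n_sites), chrom = chrom,
                 chrom_length = as.integer(chrom_length),
                 n_samples = as.integer(n_samples),
                 ploidy = as.integer(ploidy), depth_mean = depth_mean,
                 error_rate = error_rate,
                 genic_fraction = genic_fraction,
                 exon_fraction = exon_fraction,
                 n_genes = as.integer(n_genes), n_tags = as.integer(n_tags),
                 n_aims = as.integer(n_aims), n_voi = as.integer(n_voi),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate populations under the Balding-Nichols model
#'
#' Per site, an ancestral frequency p ~ Uniform(0.05, 0.95) is drawn; each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) (equal to p
#' exactly when F = 0); each sample's alternate-allele dosage is
#' Binomial(ploidy, population frequency). Sites are biallelic SNPs at
#' distinct sorted positions.
#'
#' @param cfg A `sim_config`.
#' @return List: `variants` (`called_variants`), `sheet` (`sample_sheet`
#'   with groups pop1, pop2, ...), `truth` (`data.frame` of ancestral and
#'   per-population frequencies per site).
#' @export
simulate_populations <- function(cfg) {
  seeded_rng(cfg$seed, "populations")
  L <- cfg$n_sites
  f <- rep(cfg$f_target, length.out = cfg$n_pops)
  pos <- sort(sample.int(cfg$chrom_length, L))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1), ""))
  qual <- round(stats::runif(L, 50, 2000), 1)
  p_anc <- stats::runif(L, 0.05, 0.95)

  groups <- paste0("pop", seq_len(cfg$n_pops))
  samples <- unlist(lapply(groups, function(g)
    paste0(g, "_rep", seq_len(cfg$n_samples))))
  sheet <- data.frame(sampleID = samples,
                      treatment = rep(groups, each = cfg$n_samples))
  class(sheet) <- c("sample_sheet", "data.frame")

  truth <- data.frame(chrom = cfg$chrom, pos = pos, p_anc = p_anc)
  gt <- array(NA_integer_, c(L, length(samples), cfg$ploidy))
  for (i in seq_len(cfg$n_pops)) {
    q <- if (f[i] == 0) p_anc else
      stats::rbeta(L, p_anc * (1 - f[i]) / f[i],
                   (1 - p_anc) * (1 - f[i]) / f[i])
    truth[[paste0("freq_", groups[i])]] <- q
    for (j in seq_len(cfg$n_samples)) {
      col <- (i - 1L) * cfg$n_samples + j
      k <- stats::rbinom(L, cfg$ploidy, q)
      for (h in seq_len(cfg$ploidy)) {
        gt[, col, h] <- as.integer(h <= k)
      }
    }
  }
  sites <- data.frame(chrom = cfg$chrom, pos = pos, ref = ref, qual = qual)
  sites$alt <- as.list(alt)
  v <- called_variants(sites, gt, samples)
  list(variants = v, sheet = sheet, truth = truth)
}

#' Simulate pooled read pileups at known allele frequencies
#'
#' Per locus and sample, depth ~ Poisson(`depth_mean`); alternate reads ~
#' Binomial(depth, q') with q' the true frequency folded with the error
#' rate (q' = q(1-e) + (1-q)e/3); the remaining reads are reference except
#' for errors scattered to the two off-target bases.
#'
#' @param loci `data.frame` with `chrom`, `pos`, `ref`, `alt` (bases).
#' @param freqs True alternate frequencies: vector (shared by samples) or
#'   matrix loci x samples.
#' @param samples Character vector of sample names.
#' @param depth_mean Mean depth (Poisson); 0 gives uncovered loci.
#' @param error_rate Per-base error rate.
#' @param seed Seed.
#' @return A `pileup_counts` with attribute `truth` (the frequency matrix).
#' @export
simulate_pool_pileup <- function(loci, freqs, samples, depth_mean = 30,
                                 error_rate = 0.001, seed = 1L) {
  seeded_rng(seed, "pileup")
  n <- nrow(loci); m <- length(samples)
  qmat <- if (is.matrix(freqs)) freqs else matrix(freqs, n, m)
  if (any(qmat < 0 | qmat > 1)) stop("frequencies must lie in [0, 1]")
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (j in seq_len(m)) {
    depth <- stats::rpois(n, depth_mean)
    qadj <- qmat[, j] * (1 - error_rate) + (1 - qmat[, j]) * error_rate / 3
    alt_n <- stats::rbinom(n, depth, qadj)
    rest <- depth - alt_n
    err_n <- stats::rbinom(n, rest, 2 * error_rate / 3)
    ref_n <- rest - err_n
    cnt <- matrix(0L, n, 4, dimnames = list(NULL, bases))
    for (i in seq_len(n)) {
      cnt[i, loci$alt[i]] <- cnt[i, loci$alt[i]] + alt_n[i]
      cnt[i, loci$ref[i]] <- cnt[i, loci$ref[i]] + ref_n[i]
      if (err_n[i] > 0) {
        off <- setdiff(bases, c(loci$ref[i], loci$alt[i]))
        split1 <- stats::rbinom(1, err_n[i], 0.5)
        cnt[i, off[1]] <- split1
        cnt[i, off[2]] <- err_n[i] - split1
      }
    }
    rows[[j]] <- data.frame(sample = samples[j], chrom = loci$chrom,
                            pos = loci$pos, cnt)
  }
  out <- do.call(rbind, rows)
  out$depth <- out$A + out$C + out$G + out$T
  out <- out[order(out$sample, out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("pileup_counts", "data.frame")
  attr(out, "truth") <- qmat
  out
}

#' Simulate marker panels and a toy GFF3
#'
#' Builds, from one seed: an inversion tag-SNP panel (tags uniformly inside
#' a declared breakpoint span on chromosome 2), an AIM panel with distinct
#' diagnostic alleles per species, a small variants-of-interest panel, and
#' a toy GFF3 whose genic fraction is exactly `cfg$genic_fraction` by
#' construction (equal-length, evenly spaced genes, each with two exons
#' covering `cfg$exon_fraction` of the gene).
#'
#' @param cfg A `sim_config`.
#' @return List: `tag_snps`, `aims`, `voi` (marker panels), `gff_lines`
#'   (character vector; write with `writeLines`), `genes` (the gene table),
#'   `inversion_span` (c(start, end)).
#' @export
simulate_panels <- function(cfg) {
  seeded_rng(cfg$seed, "panels")
  bases <- c("A", "C", "G", "T")
  inv_start <- round(cfg$chrom_length * 0.3)
  inv_end <- round(cfg$chrom_length * 0.7)
  tag_pos <- sort(sample(inv_start:inv_end, cfg$n_tags))
  tags <- data.frame(inversion = "2La", chrom = cfg$chrom,
                     start_bp = inv_start, end_bp = inv_end, pos = tag_pos,
                     inverted_allele = sample(bases, cfg$n_tags,
                                              replace = TRUE))
  class(tags) <- c("marker_panel", "data.frame")
  attr(tags, "panel_kind") <- "tag_snps"

  aim_pos <- sort(sample.int(cfg$chrom_length, cfg$n_aims))
  aA <- sample(bases, cfg$n_aims, replace = TRUE)
  aB <- unname(vapply(aA, function(a) sample(setdiff(bases, a), 1), ""))
  aims <- data.frame(chrom = cfg$chrom, pos = aim_pos, alleleA = aA,
                     alleleB = aB, panel = "speciesA_vs_speciesB")
  class(aims) <- c("marker_panel", "data.frame")
  attr(aims, "panel_kind") <- "aims"

  voi_pos <- sort(sample.int(cfg$chrom_length, cfg$n_voi))
  vref <- sample(bases, cfg$n_voi, replace = TRUE)
  valt <- unname(vapply(vref, function(r) sample(setdiff(bases, r), 1), ""))
  voi <- data.frame(chrom = cfg$chrom, pos = voi_pos, ref = vref, alt = valt,
                    name = sprintf("VOI-%02d", seq_len(cfg$n_voi)))
  class(voi) <- c("marker_panel", "data.frame")
  attr(voi, "panel_kind") <- "variants_of_interest"

  gene_len <- floor(cfg$chrom_length * cfg$genic_fraction / cfg$n_genes)
  gap <- floor(cfg$chrom_length * (1 - cfg$genic_fraction) / cfg$n_genes)
  starts <- 1L + (seq_len(cfg$n_genes) - 1L) * (gene_len + gap) + gap %/% 2L
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
                      chrom = cfg$chrom, start = starts,
                      end = starts + gene_len - 1L)
  exon_len <- floor(gene_len * cfg$exon_fraction / 2)
  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", cfg$chrom, cfg$chrom_length))
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[i, ]
    e1 <- c(g$start, g$start + exon_len - 1L)
    e2 <- c(g$end - exon_len + 1L, g$end)
    gff <- c(gff,
      sprintf("%s\tpopscan_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s", g$chrom,
              g$start, g$end, g$gene_id),
      sprintf("%s\tpopscan_sim\tmRNA\t%d\t%d\t.\t+\t.\tID=%s-RA;Parent=%s",
              g$chrom, g$start, g$end, g$gene_id, g$gene_id),
      sprintf("%s\tpopscan_sim\texon\t%d\t%d\t.\t+\t.\tID=%s-E1;Parent=%s-RA",
              g$chrom, e1[1], e1[2], g$gene_id, g$gene_id),
      sprintf("%s\tpopscan_sim\texon\t%d\t%d\t.\t+\t.\tID=%s-E2;Parent=%s-RA",
              g$chrom, e2[1], e2[2], g$gene_id, g$gene_id))
  }
  list(tag_snps = tags, aims = aims, voi = voi, gff_lines = gff,
       genes = genes, inversion_span = c(inv_start, inv_end))
}

#' Simulate a group-structured expression-like count table
#'
#' A simple negative-binomial count matrix with a subset of genes shifted
#' between two groups — enough structure for PCA and gene-family clustering
#' tests, with no claim to model real RNA-seq dispersion trends.
#'
#' @param n_genes,n_per_group Matrix dimensions.
#' @param frac_de Fraction of genes shifted between groups.
#' @param lfc Log2 fold-change of shifted genes.
#' @param dispersion NB size parameter.
#' @param seed Seed.
#' @return List: `counts` (genes x samples), `group` (factor), `de_genes`.
#' @export
simulate_expression <- function(n_genes = 500L, n_per_group = 6L,
                                frac_de = 0.1, lfc = 2, dispersion = 10,
                                seed = 1L) {
  seeded_rng(seed, "expression")
  mu <- exp(stats::rnorm(n_genes, log(200), 1))
  de <- sample.int(n_genes, round(frac_de * n_genes))
  group <- rep(c("A", "B"), each = n_per_group)
  counts <- matrix(0L, n_genes, 2 * n_per_group,
                   dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                   paste0(group, rep(seq_len(n_per_group), 2))))
  for (j in seq_len(2 * n_per_group)) {
    mj <- mu
    if (group[j] == "B") mj[de] <- mj[de] * 2^lfc
    counts[, j] <- stats::rnbinom(n_genes, mu = mj, size = dispersion)
  }
  list(counts = counts, group = factor(group),
       de_genes = rownames(counts)[de])
}

#' Write a full synthetic data set to a directory
#'
#' Emits everything the analysis layer consumes: a VCF, sample sheet,
#' YAML config, the three marker panels, a toy GFF3, a pileup count table
#' at the panel loci, and ground-truth tables for every estimator.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pops <- simulate_populations(cfg)
  panels <- simulate_panels(cfg)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    samples = file.path(dir, "samples.tsv"),
    config = file.path(dir, "config.yaml"),
    gff = file.path(dir, "annotation.gff3"),
    tag_snps = file.path(dir, "tag_snps.tsv"),
    aims = file.path(dir, "aims.tsv"),
    voi = file.path(dir, "voi.tsv"),
    pileup = file.path(dir, "pileup_counts.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_pools = file.path(dir, "truth_pools.tsv"))
  write_vcf(pops$variants, paths["vcf"])
  write_tsv(as.data.frame(pops$sheet), paths["samples"])
  yaml::write_yaml(list(ploidy = cfg$ploidy, qual_min = 30,
                        max_missing_fraction = 0,
                        window_size_bp = 20000L,
                        contrasts = list(c("pop1", "pop2")),
                        random_seed = cfg$seed),
                   paths["config"])
  writeLines(panels$gff_lines, paths["gff"])
  write_tsv(as.data.frame(panels$tag_snps), paths["tag_snps"])
  write_tsv(as.data.frame(panels$aims), paths["aims"])
  write_tsv(as.data.frame(panels$voi), paths["voi"])
  # pooled pileups at VOI + tag loci, true frequencies drawn per group
  seeded_rng(cfg$seed, "dataset_pools")
  loci <- rbind(panels$voi[c("chrom", "pos", "ref", "alt")],
                data.frame(chrom = panels$tag_snps$chrom,
                           pos = panels$tag_snps$pos,
                           ref = vapply(panels$tag_snps$inverted_allele,
                                        function(a) sample(setdiff(
                                          c("A", "C", "G", "T"), a), 1), ""),
                           alt = panels$tag_snps$inverted_allele))
  q_group <- stats::runif(cfg$n_pops, 0.1, 0.9)
  qmat <- matrix(rep(q_group, each = cfg$n_samples), nrow(loci),
                 cfg$n_pops * cfg$n_samples, byrow = TRUE)
  pup <- simulate_pool_pileup(loci, qmat, pops$sheet$sampleID,
                              depth_mean = cfg$depth_mean,
                              error_rate = cfg$error_rate,
                              seed = derive_seed(cfg$seed, "pools"))
  write_tsv(as.data.frame(pup), paths["pileup"])
  write_tsv(pops$truth, paths["truth_sites"])
  write_tsv(data.frame(group = paste0("pop", seq_len(cfg$n_pops)),
                       true_pool_freq = q_group), paths["truth_pools"])
  invisible(paths)
}
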