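#' Load genes and exons from a GFF3
#'
#' @param path GFF3 file.
#' @return List with `genes` (`data.frame`: gene_id, chrom, start, end),
#'   `exons` (GRanges, merged), `gene_ranges` (GRanges), `seq_lengths`
#'   (named vector from `##sequence-region` pragmas when present, otherwise
#'   the maximum annotated end per contig).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  ids <- if (!is.null(genes$ID)) as.character(genes$ID) else
    as.character(genes$Name)
  gene_df <- data.frame(gene_id = ids,
                        chrom = as.character(GenomicRanges::seqnames(genes)),
                        start = GenomicRanges::start(genes),
                        end = GenomicRanges::end(genes))
  # sequence lengths from pragmas, falling back to annotated extents
  lines <- readLines(path, n = 1000L)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr)) {
    parts <- strsplit(sr, "\\s+")
    seq_lengths <- vapply(parts, function(p) as.numeric(p[4]), 0)
    names(seq_lengths) <- vapply(parts, function(p) p[2], "")
  } else {
    ends <- tapply(GenomicRanges::end(gr),
                   as.character(GenomicRanges::seqnames(gr)), max)
    seq_lengths <- as.numeric(ends); names(seq_lengths) <- names(ends)
  }
  list(genes = gene_df,
       exons = GenomicRanges::reduce(exons),
       gene_ranges = GenomicRanges::reduce(genes),
       seq_lengths = seq_lengths)
}

#' Gene table of a GFF3
#' @param path GFF3 file.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @export
gff_genes <- function(path) read_gff3(path)$genes

#' Classify SNP positions by genomic feature
#'
#' Each position gets exactly one label with precedence exon > intron >
#' intergenic: inside any (isoform-merged) exon is exonic, else inside a
#' gene span is intronic, else intergenic. Alongside the SNP fractions the
#' genome's own composition under the same three-way partition is computed
#' from the merged feature spans over the total sequence length, so
#' ascertainment (RNA-seq variants concentrate in exons) can be read off
#' directly.
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param gff A path to a GFF3 or the result of [read_gff3()].
#' @return List of class `feature_classification`: `labels` (per SNP),
#'   `snp_fractions`, `genome_fractions` (named: exon, intron, intergenic).
#' @export
classify_snp_features <- function(chrom, pos, gff) {
  if (is.character(gff)) gff <- read_gff3(gff)
  ann_contigs <- names(gff$seq_lengths)
  if (!any(unique(chrom) %in% ann_contigs)) {
    stop("contig mismatch: SNP contig(s) ",
         paste(setdiff(unique(chrom), ann_contigs), collapse = ", "),
         " not present in annotation (",
         paste(utils::head(ann_contigs, 5), collapse = ", "), ")")
  }
  snps <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  in_exon <- IRanges::overlapsAny(snps, gff$exons)
  in_gene <- IRanges::overlapsAny(snps, gff$gene_ranges)
  labels <- ifelse(in_exon, "exon", ifelse(in_gene, "intron", "intergenic"))
  snp_fractions <- c(exon = mean(labels == "exon"),
                     intron = mean(labels == "intron"),
                     intergenic = mean(labels == "intergenic"))
  total <- sum(gff$seq_lengths)
  exon_bp <- sum(GenomicRanges::width(gff$exons))
  gene_bp <- sum(GenomicRanges::width(gff$gene_ranges))
  intron_bp <- max(gene_bp - sum(GenomicRanges::width(
    GenomicRanges::intersect(gff$gene_ranges, gff$exons))), 0)
  genome_fractions <- c(exon = exon_bp / total,
                        intron = intron_bp / total,
                        intergenic = (total - gene_bp) / total)
  structure(list(labels = labels, snp_fractions = snp_fractions,
                 genome_fractions = genome_fractions),
            class = "feature_classification")
}

# SnpEff-style ANN severity classes, most severe first
effect_class <- function(ann_strings) {
  if (!length(ann_strings)) return(NA_character_)
  effects <- vapply(strsplit(ann_strings, "|", fixed = TRUE),
                    function(f) if (length(f) >= 2) f[2] else "", "")
  if (any(grepl("stop_gained|stop_lost|start_lost", effects))) return("nonsense")
  if (any(grepl("missense", effects))) return("missense")
  if (any(grepl("synonymous", effects))) return("synonymous")
  "other"
}

#' Tally variant effect classes from ANN annotations
#'
#' Parses upstream annotator (SnpEff-style) ANN entries; each variant gets
#' one class by a most-severe-effect rule (nonsense > missense >
#' synonymous > other) across its transcript annotations. No re-annotation
#' is performed.
#'
#' @param v A `called_variants` whose sites carry `ann` strings.
#' @return List: `classes` (per annotated variant), `counts`, `fractions`
#'   over annotated variants (all-`NA` when none are annotated).
#' @export
tally_effects <- function(v) {
  has_ann <- lengths(v$sites$ann) > 0
  if (!any(has_ann)) {
    stop("no ANN annotations present; annotate the VCF (e.g. SnpEff) first")
  }
  classes <- vapply(v$sites$ann[has_ann], effect_class, "")
  lv <- c("nonsense", "missense", "synonymous", "other")
  counts <- table(factor(classes, levels = lv))
  fr <- if (length(classes)) as.numeric(counts) / length(classes)
        else rep(NA_real_, 4)
  names(fr) <- lv
  list(classes = classes, counts = counts, fractions = fr)
}

#' Missense variants within one gene, with per-group frequencies
#'
#' @param v A `called_variants` with ANN annotations.
#' @param gene_id Gene identifier as in the GFF3.
#' @param gff Path to GFF3 or result of [read_gff3()].
#' @param sheet A `sample_sheet` for the per-group alternate-allele
#'   frequencies.
#' @return `data.frame`: chrom, pos, ref, alt, aa_change, one frequency
#'   column per group. Empty when the gene has no missense variants.
#' @export
gene_missense_report <- function(v, gene_id, gff, sheet) {
  if (is.character(gff)) gff <- read_gff3(gff)
  g <- gff$genes[gff$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) {
    near <- gff$genes$gene_id[order(utils::adist(gene_id, gff$genes$gene_id))]
    stop("gene '", gene_id, "' not found in annotation; nearest ids: ",
         paste(utils::head(near, 5), collapse = ", "))
  }
  ing <- which(v$sites$chrom == g$chrom & v$sites$pos >= g$start &
               v$sites$pos <= g$end)
  cols <- c("chrom", "pos", "ref", "alt", "aa_change")
  gs <- group_samples(sheet)
  empty <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(cols) + length(gs))),
    c(cols, names(gs)))
  if (!length(ing)) return(empty)
  is_mis <- vapply(v$sites$ann[ing], function(a) {
    length(a) > 0 && effect_class(a) == "missense"
  }, TRUE)
  ing <- ing[is_mis]
  if (!length(ing)) return(empty)
  gac <- group_allele_counts(v[ing], sheet)
  bac <- biallelic_counts(gac)
  aa <- vapply(v$sites$ann[ing], function(a) {
    f <- strsplit(a[grepl("missense", a)][1], "|", fixed = TRUE)[[1]]
    if (length(f) >= 11) f[11] else ""
  }, "")
  res <- data.frame(chrom = v$sites$chrom[ing], pos = v$sites$pos[ing],
                    ref = v$sites$ref[ing],
                    alt = vapply(v$sites$alt[ing], `[`, "", 1),
                    aa_change = aa)
  for (grp in names(gs)) {
    m <- bac[[grp]]
    res[[grp]] <- ifelse(rowSums(m) > 0, m[, "alt"] / rowSums(m), NA_real_)
  }
  res
}

#' Hypergeometric enrichment of annotation terms in a gene set
#'
#' For each term annotated to at least one universe gene, tests whether the
#' selected set contains more term members than expected under sampling
#' without replacement: upper-tail p = P(X >= k) for X hypergeometric with
#' population N (universe), K annotated, n selected. P-values are BH
#' adjusted across terms.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param annotation `data.frame` with columns `gene`, `term` (gene-to-GO
#'   or gene-to-PFAM map); genes outside the universe are ignored.
#' @param universe Character vector: the gene population, typically the
#'   expressed genes.
#' @return `data.frame` (class `enrichment_result`): `term`, `N_pop`, `K`,
#'   `n_sel`, `k`, `p_value`, `p_adjusted`, sorted by p.
#' @export
hypergeometric_enrichment <- function(selected, annotation, universe) {
  selected <- unique(selected); universe <- unique(universe)
  bad <- setdiff(selected, universe)
  if (length(bad)) {
    stop("selected gene(s) absent from universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  ann <- unique(ann[c("gene", "term")])
  N <- length(universe); n <- length(selected)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    members <- ann$gene[ann$term == tm]
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, N_pop = N, K = K, n_sel = n, k = k, p_value = p)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Overlap genes with a table of selective-sweep intervals
#'
#' Half-open interval intersection (`[start, end)` on both sides): two
#' intervals overlap iff `gene_start < sweep_end` and
#' `sweep_start < gene_end`; intervals that merely touch do not overlap.
#' This kind of overlap is exploratory — colocalisation with a published
#' sweep signal is suggestive, not causal — and the output says so.
#'
#' @param genes `data.frame`: `gene_id`, `chrom`, `start`, `end`.
#' @param sweeps `data.frame`: `chrom`, `start`, `end`, `signal`, `cohort`.
#' @return `data.frame`: one row per (gene, overlapping sweep), with a
#'   `caveat` attribute on the result.
#' @export
sweep_overlap <- function(genes, sweeps) {
  rows <- list()
  if (nrow(sweeps)) {
    for (i in seq_len(nrow(genes))) {
      hit <- sweeps$chrom == genes$chrom[i] &
        genes$start[i] < sweeps$end & sweeps$start < genes$end[i]
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i], chrom = genes$chrom[i],
          gene_start = genes$start[i], gene_end = genes$end[i],
          sweeps[hit, c("start", "end", "signal", "cohort"), drop = FALSE],
          row.names = NULL)
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), chrom = character(),
               gene_start = integer(), gene_end = integer(),
               start = integer(), end = integer(),
               signal = character(), cohort = character())
  attr(res, "caveat") <-
    "Sweep-signal overlap is exploratory; colocalisation is not causation."
  res
}

#' Gene-family expression summary
#'
#' Orders the members of a gene family (e.g. all genes sharing a PFAM
#' domain: P450s, GSTs, carboxylesterases, ABC transporters, ...) by
#' average-linkage hierarchical clustering of their normalised count
#' profiles under correlation distance (1 - Pearson r), and returns the
#' panels a family heatmap needs: ordered counts, ordered fold-changes,
#' and the dendrogram.
#'
#' @param counts Numeric matrix genes x samples of normalised counts.
#' @param fold_changes Optional `data.frame` with a `gene` column plus
#'   per-contrast columns; subset and reordered to the family.
#' @param family_genes Character vector of member gene IDs (rows of
#'   `counts`).
#' @return List of class `gene_family_summary`: `order` (gene IDs, cluster
#'   order), `hclust` (`NULL` for families of < 2 members), `counts`,
#'   `fold_changes`.
#' @export
gene_family_summary <- function(counts, fold_changes = NULL, family_genes) {
  present <- intersect(family_genes, rownames(counts))
  if (!length(present)) stop("no family member present in count matrix")
  m <- counts[present, , drop = FALSE]
  if (length(present) < 2) {
    hc <- NULL
    ord <- present
  } else {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[is.na(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    ord <- present[hc$order]
  }
  fc <- NULL
  if (!is.null(fold_changes)) {
    fc <- fold_changes[match(ord, fold_changes$gene), , drop = FALSE]
  }
  structure(list(order = ord, hclust = hc, counts = m[ord, , drop = FALSE],
                 fold_changes = fc),
            class = "gene_family_summary")
}

#' Genes regulated in the same direction across comparisons
#'
#' Given differential-expression tables from two or more pairwise
#' comparisons (produced by an external DE tool), returns the genes that
#' are significant (adjusted p below `fdr`) and whose fold-change has the
#' requested sign in every comparison, plus the Venn region counts of the
#' significant sets.
#'
#' @param tables Named list of `data.frame`s with columns `gene`, `log2fc`,
#'   `padj`.
#' @param direction `"up"`, `"down"`, or `"either"` (same sign in all,
#'   whichever it is).
#' @param fdr Adjusted-p threshold (default 0.05).
#' @return List: `genes` (character), `venn` (named region counts of the
#'   significant sets, for 2 or 3 comparisons).
#' @export
shared_direction_genes <- function(tables, direction = c("up", "down", "either"),
                                   fdr = 0.05) {
  direction <- match.arg(direction)
  if (length(tables) < 2) stop("need at least 2 comparisons")
  sig_sets <- lapply(tables, function(t) t$gene[!is.na(t$padj) & t$padj < fdr])
  sig_dir <- lapply(tables, function(t) {
    sig <- !is.na(t$padj) & t$padj < fdr
    data.frame(gene = t$gene[sig], sign = sign(t$log2fc[sig]))
  })
  common <- Reduce(intersect, lapply(sig_dir, `[[`, "gene"))
  keep <- vapply(common, function(g) {
    signs <- vapply(sig_dir, function(d) d$sign[match(g, d$gene)], 0)
    switch(direction,
           up = all(signs > 0),
           down = all(signs < 0),
           either = all(signs > 0) || all(signs < 0))
  }, TRUE)
  genes <- common[keep]

  venn <- NULL
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("set", seq_along(tables))
  if (length(tables) %in% c(2, 3)) {
    un <- unique(unlist(sig_sets))
    membership <- vapply(sig_sets, function(s) un %in% s, logical(length(un)))
    membership <- matrix(membership, nrow = length(un))
    pat <- apply(membership, 1, function(b) paste(ifelse(b, "1", "0"),
                                                  collapse = ""))
    if (!length(un)) pat <- character(0)
    all_pat <- apply(expand.grid(rep(list(c("0", "1")), length(tables))),
                     1, paste, collapse = "")
    all_pat <- all_pat[all_pat != paste(rep("0", length(tables)), collapse = "")]
    venn <- stats::setNames(
      vapply(all_pat, function(p) sum(pat == p), 0L), all_pat)
    attr(venn, "sets") <- nm
  }
  list(genes = genes, venn = venn)
}
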