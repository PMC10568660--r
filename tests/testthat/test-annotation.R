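toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "##sequence-region 2L 1 1000",
    "2L\ttoy\tgene\t100\t400\t.\t+\t.\tID=geneA",
    "2L\ttoy\tmRNA\t100\t400\t.\t+\t.\tID=geneA-RA;Parent=geneA",
    "2L\ttoy\texon\t100\t200\t.\t+\t.\tID=geneA-E1;Parent=geneA-RA",
    # second isoform re-uses part of the same exon span
    "2L\ttoy\tmRNA\t100\t400\t.\t+\t.\tID=geneA-RB;Parent=geneA",
    "2L\ttoy\texon\t150\t200\t.\t+\t.\tID=geneA-E1b;Parent=geneA-RB",
    "2L\ttoy\tgene\t700\t859\t.\t+\t.\tID=geneB",
    "2L\ttoy\tmRNA\t700\t859\t.\t+\t.\tID=geneB-RA;Parent=geneB",
    "2L\ttoy\texon\t700\t859\t.\t+\t.\tID=geneB-E1;Parent=geneB-RA"),
    path)
  path
}

test_that("SNPs classify as exon/intron/intergenic with merged isoforms", {
  gff <- toy_gff()
  fc <- classify_snp_features(rep("2L", 3), c(150, 250, 500), gff)
  expect_equal(fc$labels, c("exon", "intron", "intergenic"))
  expect_equal(sum(fc$snp_fractions), 1)
  expect_equal(unname(fc$snp_fractions), rep(1 / 3, 3))
  # merged genic span: (400 - 100 + 1) + (859 - 700 + 1) = 461 of 1000
  expect_equal(unname(fc$genome_fractions["intergenic"]), 1 - 0.461)
  expect_equal(sum(fc$genome_fractions), 1)
  # genome composition is a property of the annotation, not the SNP set
  fc2 <- classify_snp_features("2L", 150, gff)
  expect_equal(fc2$genome_fractions, fc$genome_fractions)

  expect_error(classify_snp_features("chrX", 5, gff), "contig mismatch")
})

test_that("toy GFF3 from the simulator has its configured genic fraction", {
  cfg <- sim_config(genic_fraction = 0.46, n_genes = 50, seed = 7)
  panels <- simulate_panels(cfg)
  gf <- tempfile(fileext = ".gff3")
  writeLines(panels$gff_lines, gf)
  fc <- classify_snp_features(cfg$chrom, 1, gf)
  genic <- fc$genome_fractions["exon"] + fc$genome_fractions["intron"]
  expect_equal(unname(genic), 0.46, tolerance = 1e-3)
})

test_that("effect tallies follow the most-severe rule", {
  ann <- list("T|missense_variant|MODERATE|g1",
              "C|synonymous_variant|LOW|g1",
              "G|synonymous_variant|LOW|g2")
  v <- cv_build("2L", 1:3, rep("A", 3), list("T", "C", "G"), 50,
                rep(list("0/1"), 3), "s1", ann = ann)
  te <- tally_effects(v)
  expect_equal(unname(te$fractions),
               c(0, 1 / 3, 2 / 3, 0))

  # two transcripts, one missense one synonymous -> missense wins
  v2 <- cv_build("2L", 1, "A", "T", 50, list("0/1"), "s1",
                 ann = list(c("T|missense_variant|MODERATE|g1",
                              "T|synonymous_variant|LOW|g1")))
  expect_equal(unname(tally_effects(v2)$counts["missense"]), 1L)

  # nonsense outranks missense
  v3 <- cv_build("2L", 1, "A", "T", 50, list("0/1"), "s1",
                 ann = list(c("T|stop_gained|HIGH|g1",
                              "T|missense_variant|MODERATE|g1")))
  expect_equal(unname(tally_effects(v3)$counts["nonsense"]), 1L)

  v4 <- cv_build("2L", 1, "A", "T", 50, list("0/1"), "s1")
  expect_error(tally_effects(v4), "annotate")
})

test_that("gene missense report extracts rows and per-group frequencies", {
  gff <- toy_gff()
  sheet <- read_sample_sheet(write_sheet(
    data.frame(sampleID = c("s1", "s2"), treatment = c("ctl", "sel"))))
  ann <- list("T|missense_variant|MODERATE|geneA|geneA|mRNA|geneA-RA|pc|1/2|c.1A>T|p.Lys1Ter",
              "C|synonymous_variant|LOW|geneA",
              "G|synonymous_variant|LOW|geneA")
  v <- cv_build("2L", c(120, 130, 140), c("A", "A", "A"),
                list("T", "C", "G"), 50,
                rep(list(c("0/1", "1/1")), 3), c("s1", "s2"), ann = ann)
  rep_ <- gene_missense_report(v, "geneA", gff, sheet)
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$pos, 120)
  expect_equal(rep_$ctl, 0.5)
  expect_equal(rep_$sel, 1.0)
  expect_equal(rep_$aa_change, "p.Lys1Ter")

  # gene with no variants: empty table, not an error
  rep0 <- gene_missense_report(v, "geneB", gff, sheet)
  expect_equal(nrow(rep0), 0)

  expect_error(gene_missense_report(v, "geneQ", gff, sheet),
               "nearest ids.*geneA|geneB")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  universe <- paste0("g", 1:20)
  ann <- data.frame(gene = paste0("g", 1:5), term = "GO:1")
  # all five selected genes annotated: p = 1 / C(20,5)
  res <- hypergeometric_enrichment(paste0("g", 1:5), ann, universe)
  expect_equal(res$p_value, 1 / choose(20, 5))
  expect_equal(res$p_value, 6.4499e-5, tolerance = 1e-4)
  expect_equal(res$k, 5)

  # k = 2 of K = 5, n = 5: P(X >= 2) = 0.366099
  res2 <- hypergeometric_enrichment(c("g1", "g2", "g10", "g11", "g12"),
                                    ann, universe)
  expect_equal(res2$p_value, 0.366099, tolerance = 1e-5)

  # k = 0 -> p = 1
  res0 <- hypergeometric_enrichment(paste0("g", 10:14), ann, universe)
  expect_equal(res0$p_value, 1)

  # exhaustive enumeration for N <= 12
  for (case in list(c(8, 3, 4, 2), c(12, 5, 6, 3), c(10, 4, 3, 1))) {
    N <- case[1]; K <- case[2]; n <- case[3]; k <- case[4]
    uni <- paste0("u", seq_len(N))
    annx <- data.frame(gene = uni[seq_len(K)], term = "T")
    sel <- c(uni[seq_len(k)], uni[(K + 1):(K + n - k)])
    resx <- hypergeometric_enrichment(sel, annx, uni)
    expect_equal(resx$p_value, oracle_hyper_enum(N, K, n, k),
                 tolerance = 1e-12)
  }

  expect_error(hypergeometric_enrichment("gX", ann, universe), "gX")
})

test_that("sweep overlap is half-open, symmetric, and caveated", {
  genes <- data.frame(gene_id = "g1", chrom = "2L",
                      start = 10000, end = 20000)
  sweeps <- data.frame(chrom = "2L", start = 15000, end = 30000,
                       signal = "sw1", cohort = "UG")
  ov <- sweep_overlap(genes, sweeps)
  expect_equal(nrow(ov), 1)
  expect_match(attr(ov, "caveat"), "exploratory")

  # touching intervals under half-open semantics do not overlap
  sweeps2 <- data.frame(chrom = "2L", start = 20000, end = 30000,
                        signal = "sw1", cohort = "UG")
  expect_equal(nrow(sweep_overlap(genes, sweeps2)), 0)

  expect_equal(nrow(sweep_overlap(genes, sweeps[0, ])), 0)

  # symmetry: swapping query and subject finds the same intersections
  set.seed(9)
  g2 <- data.frame(gene_id = paste0("x", 1:20), chrom = "2L",
                   start = sample(1:5000, 20))
  g2$end <- g2$start + sample(100:900, 20)
  s2 <- data.frame(chrom = "2L", start = sample(1:5000, 15))
  s2$end <- s2$start + sample(100:900, 15)
  s2$signal <- paste0("y", 1:15); s2$cohort <- "c"
  fwd <- sweep_overlap(g2, s2)
  rev_ <- sweep_overlap(
    data.frame(gene_id = s2$signal, chrom = s2$chrom, start = s2$start,
               end = s2$end),
    data.frame(chrom = g2$chrom, start = g2$start, end = g2$end,
               signal = g2$gene_id, cohort = "c"))
  expect_equal(nrow(fwd), nrow(rev_))
  expect_setequal(paste(fwd$gene_id, fwd$signal),
                  paste(rev_$signal, rev_$gene_id))
})

test_that("gene families cluster by correlation distance", {
  # two identical profiles merge first; the anti-correlated gene is the
  # outgroup leaf
  counts <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
                  c = c(8, 6, 4, 2))
  fam <- gene_family_summary(counts, family_genes = c("a", "b", "c"))
  expect_equal(fam$hclust$merge[1, ], c(-1, -2))   # a,b first
  expect_true(fam$order[1] == "c" || fam$order[3] == "c")
  expect_setequal(fam$order, c("a", "b", "c"))

  one <- gene_family_summary(counts, family_genes = "a")
  expect_null(one$hclust)
  expect_equal(one$order, "a")

  fc <- data.frame(gene = c("c", "a", "b"), log2fc = 1:3)
  fam2 <- gene_family_summary(counts, fc, c("a", "b", "c"))
  expect_equal(fam2$fold_changes$gene, fam2$order)
})

test_that("shared-direction gene sets and venn counts behave", {
  t1 <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, -1, 1),
                   padj = c(0.01, 0.01, 0.2))
  t2 <- data.frame(gene = c("g1", "g2", "g4"), log2fc = c(1, 1, -2),
                   padj = c(0.04, 0.01, 0.01))
  res <- shared_direction_genes(list(A = t1, B = t2), "up")
  expect_equal(res$genes, "g1")        # up in both
  # g2 significant both but discordant: excluded even under "either"
  expect_false("g2" %in% shared_direction_genes(list(t1, t2), "either")$genes)
  expect_equal(unname(res$venn["11"]), 2L)  # g1, g2 shared-significant

  # disjoint significant sets: empty intersection, middle region 0
  t3 <- data.frame(gene = "g9", log2fc = 2, padj = 0.01)
  res2 <- shared_direction_genes(list(t1, t3), "up")
  expect_equal(length(res2$genes), 0)
  expect_equal(unname(res2$venn["11"]), 0L)

  # same table twice returns exactly its significant genes
  res3 <- shared_direction_genes(list(t1, t1), "either")
  expect_setequal(res3$genes, c("g1", "g2"))

  expect_error(shared_direction_genes(list(t1)), "at least 2")
})
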