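# Fixture builders: everything is generated in code at test time.

write_sheet <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Directly assemble a called_variants object from a compact description.
# geno: list (one element per site) of character genotypes like "0/1",
# "./.", one per sample.
cv_build <- function(chrom, pos, ref, alt, qual, geno, samples,
                     ann = NULL, ploidy = 2L) {
  n <- length(pos)
  gt <- array(NA_integer_, c(n, length(samples), ploidy))
  for (s in seq_len(n)) {
    for (j in seq_along(samples)) {
      a <- suppressWarnings(as.integer(strsplit(geno[[s]][j], "[/|]")[[1]]))
      gt[s, j, ] <- c(a, rep(NA_integer_, ploidy))[seq_len(ploidy)]
    }
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, qual = qual)
  sites$alt <- if (is.list(alt)) alt else as.list(alt)
  if (!is.null(ann)) sites$ann <- ann
  called_variants(sites, gt, samples)
}

# The 5-record toy VCF: SNP q=50 full calls; indel q=60; SNP q=20;
# SNP q=45 with one missing genotype; SNP q=30 full calls.
write_toy_vcf5 <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=2L>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "2L\t100\t.\tA\tT\t50\t.\t.\tGT\t0/1\t1/1",
    "2L\t200\t.\tAT\tA\t60\t.\t.\tGT\t0/1\t0/0",
    "2L\t300\t.\tG\tC\t20\t.\t.\tGT\t0/0\t0/1",
    "2L\t400\t.\tC\tG\t45\t.\t.\tGT\t./.\t0/1",
    "2L\t500\t.\tT\tA\t30\t.\t.\tGT\t1/1\t0/1")
  writeLines(lines, path)
  path
}

write_toy_sheet2 <- function(path = tempfile(fileext = ".tsv")) {
  write_sheet(data.frame(sampleID = c("S1", "S2"),
                         treatment = c("ctl", "sel")), path)
}

# Pileup count table rows in the collect_pileup()/simulate_pool_pileup()
# layout.
pileup_df <- function(sample, chrom, pos, A = 0L, C = 0L, G = 0L, T = 0L) {
  df <- data.frame(sample = sample, chrom = chrom, pos = pos,
                   A = A, C = C, G = G, T = T)
  df$depth <- df$A + df$C + df$G + df$T
  class(df) <- c("pileup_counts", "data.frame")
  df
}

voi_panel <- function(chrom, pos, ref, alt, name) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   name = name)
  class(df) <- c("marker_panel", "data.frame")
  attr(df, "panel_kind") <- "variants_of_interest"
  df
}

tag_panel <- function(pos, inverted_allele, chrom = "2L", inversion = "2La",
                      start_bp = min(pos), end_bp = max(pos)) {
  df <- data.frame(inversion = inversion, chrom = chrom, start_bp = start_bp,
                   end_bp = end_bp, pos = pos,
                   inverted_allele = inverted_allele)
  class(df) <- c("marker_panel", "data.frame")
  attr(df, "panel_kind") <- "tag_snps"
  df
}

aim_panel <- function(chrom, pos, alleleA, alleleB) {
  df <- data.frame(chrom = chrom, pos = pos, alleleA = alleleA,
                   alleleB = alleleB)
  class(df) <- c("marker_panel", "data.frame")
  attr(df, "panel_kind") <- "aims"
  df
}
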