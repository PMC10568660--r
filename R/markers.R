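#' Read a marker panel
#'
#' Marker panels are small tab-separated files of loci with expected alleles.
#' Three kinds are supported:
#' \describe{
#'   \item{`variants_of_interest`}{columns `chrom, pos, ref, alt, name`
#'     (e.g. insecticide-resistance SNPs such as Vgsc-995S).}
#'   \item{`tag_snps`}{columns `inversion, chrom, start_bp, end_bp, pos,
#'     inverted_allele` — karyotype-tagging SNPs lying inside inversion
#'     breakpoints.}
#'   \item{`aims`}{columns `chrom, pos, alleleA, alleleB` plus optional
#'     `panel` label — ancestry-informative markers with one diagnostic
#'     allele per species.}
#' }
#' All allele columns must contain a single base in A/C/G/T; violations are
#' reported with their line number. Panels are returned sorted by
#' (chrom, pos).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param panel_kind One of `"variants_of_interest"`, `"tag_snps"`, `"aims"`.
#' @return A `data.frame` of class `marker_panel` with attribute
#'   `panel_kind`.
#' @export
read_marker_panel <- function(path,
                              panel_kind = c("variants_of_interest",
                                             "tag_snps", "aims")) {
  panel_kind <- match.arg(panel_kind)
  if (!file.exists(path)) stop("marker file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  required <- switch(panel_kind,
    variants_of_interest = c("chrom", "pos", "ref", "alt", "name"),
    tag_snps = c("inversion", "chrom", "start_bp", "end_bp", "pos",
                 "inverted_allele"),
    aims = c("chrom", "pos", "alleleA", "alleleB"))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(panel_kind, " panel is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  allele_cols <- switch(panel_kind,
    variants_of_interest = c("ref", "alt"),
    tag_snps = "inverted_allele",
    aims = c("alleleA", "alleleB"))
  for (col in allele_cols) {
    bad <- which(!df[[col]] %in% c("A", "C", "G", "T"))
    if (length(bad)) {
      stop("malformed allele '", df[[col]][bad[1]], "' in column ", col,
           " at line ", bad[1] + 1L, " of ", path)
    }
  }
  for (col in intersect(c("pos", "start_bp", "end_bp"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  if (panel_kind == "variants_of_interest" && anyDuplicated(df$name)) {
    stop("duplicate variant-of-interest name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  if (panel_kind == "tag_snps") {
    inside <- df$pos >= df$start_bp & df$pos <= df$end_bp
    if (any(!inside)) {
      stop("tag SNP outside its inversion breakpoints at line ",
           which(!inside)[1] + 1L)
    }
  }
  if (panel_kind == "aims" && any(df$alleleA == df$alleleB)) {
    stop("AIM with identical diagnostic alleles at line ",
         which(df$alleleA == df$alleleB)[1] + 1L)
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_panel", "data.frame")
  attr(df, "panel_kind") <- panel_kind
  df
}
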