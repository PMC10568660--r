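#' Read a tab-separated sample sheet
#'
#' The sample sheet is the central description of the experiment: one row per
#' sequencing library, with at least a sample identifier and the treatment
#' group the library belongs to. Treatment groups are what the population
#' genetics treats as populations. Extra columns (strain, batch, ...) are
#' preserved untouched.
#'
#' @param path Path to a tab-separated file. The header must contain a
#'   `sampleID` column (or `sample`) and a `treatment` column (or `group`).
#' @return A `data.frame` of class `sample_sheet` with canonical columns
#'   `sampleID` and `treatment` first, all other columns preserved as
#'   character.
#' @examples
#' tf <- tempfile()
#' writeLines(c("sampleID\ttreatment", "S1\tctl", "S2\tsel"), tf)
#' sheet <- read_sample_sheet(tf)
#' group_samples(sheet)
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  names(df)[names(df) == "sample"] <- "sampleID"
  names(df)[names(df) == "group"] <- "treatment"
  for (col in c("sampleID", "treatment")) {
    if (!col %in% names(df)) {
      stop("sample sheet is missing required column '", col, "'")
    }
  }
  if (any(!nzchar(df$sampleID)) || anyNA(df$sampleID)) {
    stop("sample sheet contains empty sample identifiers")
  }
  dup <- unique(df$sampleID[duplicated(df$sampleID)])
  if (length(dup)) {
    stop("duplicate sample identifier(s) in sample sheet: ",
         paste(dup, collapse = ", "))
  }
  if (any(!nzchar(df$treatment)) || anyNA(df$treatment)) {
    stop("every sample needs a treatment group")
  }
  df <- df[c("sampleID", "treatment",
             setdiff(names(df), c("sampleID", "treatment")))]
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Group-to-sample mapping of a sample sheet
#'
#' @param sheet A `sample_sheet`.
#' @return Named list mapping each treatment group to its sample IDs.
#' @export
group_samples <- function(sheet) {
  split(sheet$sampleID, sheet$treatment)
}

#' Build an analysis configuration
#'
#' Collects every tunable of the analysis layer with the defaults used
#' throughout: QUAL >= 30, zero tolerated missingness, 20-kb nonoverlapping
#' windows, LD pruning in 500-SNP windows stepped by 250 with an r^2 cutoff
#' of 0.01, and top-5-percentile gene flagging.
#'
#' @param ploidy Haplotypes per sample. Pooled libraries use 2 x pool size.
#' @param qual_min Minimum variant QUAL retained (inclusive).
#' @param max_missing_fraction Maximum tolerated fraction of samples with a
#'   missing genotype at a site; the default 0 keeps only sites called in
#'   every sample.
#' @param window_size_bp Window span for windowed statistics.
#' @param window_step_bp Step between window starts; equal to
#'   `window_size_bp` (the default) gives nonoverlapping tiling windows.
#' @param contrasts List of 2-vectors `c(groupA, groupB)` to compare.
#' @param pbs_triples Optional list of 3-vectors `c(focal, close, outgroup)`.
#' @param ld_window_snps,ld_step_snps,ld_r2_threshold LD-pruning parameters.
#' @param fst_top_percentile Genes in the top this-many percent of per-gene
#'   F_ST are flagged.
#' @param random_seed Seed used for every stochastic step (bootstraps,
#'   down-sampling).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(ploidy = 2L,
                            qual_min = 30,
                            max_missing_fraction = 0,
                            window_size_bp = 20000L,
                            window_step_bp = window_size_bp,
                            contrasts = list(),
                            pbs_triples = list(),
                            ld_window_snps = 500L,
                            ld_step_snps = 250L,
                            ld_r2_threshold = 0.01,
                            fst_top_percentile = 5,
                            random_seed = 1L) {
  cfg <- list(ploidy = as.integer(ploidy), qual_min = qual_min,
              max_missing_fraction = max_missing_fraction,
              window_size_bp = as.integer(window_size_bp),
              window_step_bp = as.integer(window_step_bp),
              contrasts = contrasts, pbs_triples = pbs_triples,
              ld_window_snps = as.integer(ld_window_snps),
              ld_step_snps = as.integer(ld_step_snps),
              ld_r2_threshold = ld_r2_threshold,
              fst_top_percentile = fst_top_percentile,
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

CONFIG_KEYS <- c("ploidy", "qual_min", "max_missing_fraction",
                 "window_size_bp", "window_step_bp", "contrasts",
                 "pbs_triples", "ld_window_snps", "ld_step_snps",
                 "ld_r2_threshold", "fst_top_percentile", "random_seed")

validate_config <- function(cfg) {
  if (cfg$ploidy < 1) stop("ploidy must be a positive integer")
  if (cfg$window_size_bp <= 0) stop("window_size_bp must be > 0")
  if (cfg$max_missing_fraction < 0 || cfg$max_missing_fraction > 1) {
    stop("max_missing_fraction must lie in [0, 1]")
  }
  if (cfg$ld_r2_threshold < 0 || cfg$ld_r2_threshold > 1) {
    stop("ld_r2_threshold must lie in [0, 1]")
  }
  for (ct in cfg$contrasts) {
    if (length(ct) != 2) stop("each contrast must name exactly two groups")
  }
  for (tr in cfg$pbs_triples) {
    if (length(tr) != 3) stop("each PBS triple must name exactly three groups")
  }
  invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected with the list of valid keys, so typos fail loud.
#' `contrasts` may be written either as a list of two-element lists or as
#' "A_vs_B" strings.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [analysis_config()].
#' @param sheet Optional `sample_sheet`; if given, every group named in
#'   `contrasts`/`pbs_triples` must exist in it.
#' @return An `analysis_config`.
#' @export
read_config <- function(path, sheet = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), CONFIG_KEYS)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(CONFIG_KEYS, collapse = ", "))
  }
  parse_pair <- function(x, n) {
    if (is.character(x) && length(x) == 1 && grepl("_vs_", x)) {
      x <- strsplit(x, "_vs_", fixed = TRUE)[[1]]
    }
    unlist(x)
  }
  if (!is.null(raw$contrasts)) raw$contrasts <- lapply(raw$contrasts, parse_pair)
  if (!is.null(raw$pbs_triples)) raw$pbs_triples <- lapply(raw$pbs_triples, unlist)
  cfg <- do.call(analysis_config, raw)
  if (!is.null(sheet)) check_config_groups(cfg, sheet)
  cfg
}

check_config_groups <- function(cfg, sheet) {
  known <- unique(sheet$treatment)
  named <- unique(c(unlist(cfg$contrasts), unlist(cfg$pbs_triples)))
  bad <- setdiff(named, known)
  if (length(bad)) {
    stop("group(s) named in config but absent from sample sheet: ",
         paste(bad, collapse = ", "))
  }
  invisible(cfg)
}
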