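# Deterministic seed fan-out: one user-facing seed plus a component label
# yields an independent, reproducible stream per component. Derived seeds
# stay below 2^31 - 1.
derive_seed <- function(seed, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- 0
  for (x in utf8ToInt(lab)) h <- (h * 31 + x) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

seeded_rng <- function(seed, ...) {
  set.seed(derive_seed(seed, ...))
  invisible(NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] so every "adjusted p" emitted by
#' the package uses the same false-discovery-rate procedure.
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
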