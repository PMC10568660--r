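# Plots are secondary artifacts: every figure has a TSV twin, and nothing
# downstream (or in the tests) reads an image back.

#' Genome-scan plot of a windowed statistic
#' @param w A `windowed_stat` table.
#' @param path Output PDF path.
#' @param ylab Axis label.
#' @return `path`, invisibly.
#' @export
plot_genome_scan <- function(w, path, ylab = "F_ST") {
  grDevices::pdf(path, width = 9, height = 3)
  on.exit(grDevices::dev.off())
  chroms <- unique(w$chrom)
  graphics::par(mfrow = c(1, length(chroms)), mar = c(4, 4, 2, 1))
  for (ch in chroms) {
    sub <- w[w$chrom == ch, ]
    mid <- (sub$start + sub$end) / 2
    graphics::plot(mid / 1e6, sub$value, type = "p", pch = 16, cex = 0.5,
                   xlab = paste(ch, "(Mb)"), ylab = ylab, main = ch)
  }
  invisible(path)
}

#' PCA scatter plot coloured by group
#' @param pca A `pca_result`.
#' @param groups Group label per sample (same order as coordinates).
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
plot_pca <- function(pca, groups, path) {
  grDevices::pdf(path, width = 5, height = 5)
  on.exit(grDevices::dev.off())
  g <- factor(groups)
  graphics::plot(pca$coords[, 1], pca$coords[, 2], col = as.integer(g),
                 pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * pca$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * pca$explained[2]))
  graphics::legend("topright", legend = levels(g), col = seq_along(levels(g)),
                   pch = 16, bty = "n")
  invisible(path)
}

#' Allele-balance heatmap (replicates x variants of interest)
#' @param ab An `allele_balance_result`.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
plot_allele_balance <- function(ab, path) {
  ps <- ab$per_sample
  samples <- unique(ps$sample); vois <- unique(ps$name)
  m <- matrix(NA_real_, length(samples), length(vois),
              dimnames = list(samples, vois))
  m[cbind(match(ps$sample, samples), match(ps$name, vois))] <- ps$freq
  grDevices::pdf(path, width = 2 + 0.5 * length(vois),
                 height = 2 + 0.3 * length(samples))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 8, 2, 1))
  graphics::image(seq_along(vois), seq_along(samples), t(m),
                  col = grDevices::hcl.colors(50, "Reds", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", zlim = c(0, 1))
  graphics::axis(1, seq_along(vois), vois, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(samples), samples, las = 2, cex.axis = 0.7)
  invisible(path)
}
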