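# Plot rendering, separated from plot-data computation ([qq_points()],
# [forest_data()]) so tests assert on data tables rather than images. Plots
# are written as vector graphics (PDF).

#' Render the QQ plot of a scan
#'
#' Observed against expected -log10 p, with the identity (dotted) and the
#' Bonferroni threshold (dashed) reference lines.
#'
#' @param scan A `phs_scan_results`.
#' @param path Output file (`.pdf` or anything [ggplot2::ggsave()] accepts).
#' @return The path, invisibly.
#' @export
save_qq_plot <- function(scan, path) {
  pts <- qq_points(scan)
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = expected, y = observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(scan$threshold), linetype = "dashed") +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p)))) +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, g, width = 5, height = 5)
  invisible(path)
}

#' Render forest plots for below-threshold results
#'
#' One plot per estimating data type (continuous effects on the SD scale;
#' ordered and binary as odds ratios). Data types with no below-threshold
#' results are skipped with a log notice; unordered results never appear (no
#' overall estimate exists).
#'
#' @param scan A `phs_scan_results`.
#' @param dir Output directory; files are named `forest-<type>.pdf`.
#' @return Character vector of written paths, invisibly.
#' @export
save_forest_plots <- function(scan, dir) {
  fd <- forest_data(scan)
  ref <- c(continuous = 0, ordered = 1, binary = 1)
  written <- character(0)
  for (type in names(fd)) {
    tab <- fd[[type]]
    if (nrow(tab) == 0L) {
      phs_log("forest plot: no below-threshold %s results; skipped", type)
      next
    }
    tab <- tab[order(estimate)]
    tab[, varName := factor(varName, levels = varName)]
    g <- ggplot2::ggplot(tab, ggplot2::aes(x = estimate, y = varName)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_lower, xmax = ci_upper),
                              height = 0.2) +
      ggplot2::geom_vline(xintercept = ref[[type]], linetype = "dotted") +
      ggplot2::labs(x = if (type == "continuous") "Effect (SD per unit trait)"
                        else "Odds ratio per unit trait",
                    y = NULL) +
      ggplot2::theme_bw()
    path <- file.path(dir, sprintf("forest-%s.pdf", type))
    ggplot2::ggsave(path, g, width = 6, height = 1 + 0.3 * nrow(tab) + 1)
    written <- c(written, path)
  }
  invisible(written)
}
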