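#' Notched box plot panel of an indicator across BMI groups
#'
#' Base-graphics box plot with notches at `median +/- 1.58 IQR / sqrt(n)`
#' per group, as produced by [notch_interval()].
#'
#' @param x indicator values.
#' @param group BMI group factor (NW, OW, OB).
#' @param main panel title.
#' @return The list of per-group `carproc_notch` objects, invisibly.
#' @export
plot_notched_boxes <- function(x, group, main = "") {
  group <- factor(group, levels = c("NW", "OW", "OB"))
  graphics::boxplot(x ~ group, notch = TRUE, col = c("grey85", "skyblue",
                                                     "salmon"),
                    main = main, xlab = "BMI group", ylab = "percentile")
  invisible(lapply(split(x, group), notch_interval))
}

#' Density comparison panel with reference band
#'
#' Plots the two group density estimates of a [ba_density_test()] result
#' over the shaded reference band for equality; the p-value is shown in
#' red when significant at the test's level.
#'
#' @param cmp a `carproc_density_cmp` object.
#' @param labels group labels for the legend.
#' @param main panel title.
#' @return `cmp`, invisibly.
#' @export
plot_density_comparison <- function(cmp, labels = c("g1", "g2"), main = "") {
  ylim <- range(0, cmp$band_upper, cmp$density_g, cmp$density_g2)
  graphics::plot(cmp$grid, cmp$pooled, type = "n", ylim = ylim, main = main,
                 xlab = "value", ylab = "density")
  graphics::polygon(c(cmp$grid, rev(cmp$grid)),
                    c(cmp$band_lower, rev(cmp$band_upper)),
                    col = "grey88", border = NA)
  graphics::lines(cmp$grid, cmp$density_g, col = "black", lwd = 2)
  graphics::lines(cmp$grid, cmp$density_g2, col = "red", lwd = 2)
  graphics::legend("topright", legend = labels, col = c("black", "red"),
                   lwd = 2, bty = "n")
  graphics::mtext(sprintf("p = %.3f", cmp$p_value), side = 3, adj = 1,
                  col = if (cmp$significant) "red" else "black", cex = 0.8)
  invisible(cmp)
}
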