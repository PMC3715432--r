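## Figure-level graphics: box plots of d2 per group (whiskers = extreme data
## points, no outlier trimming) and radial-distribution curves / ECDFs of
## fractional radius.

#' Box plot of a metric across groups
#'
#' Whiskers span the full data range (no outlier trimming), the box spans
#' the 1st to 3rd quartile, the mid line is the median.
#'
#' @param table measurement data.frame.
#' @param metric column to plot (e.g. \code{"d2_um2"}).
#' @param groupBy grouping column (default \code{"region"}).
#' @return A ggplot object.
#' @export
plotGroupBox <- function(table, metric = "d2_um2", groupBy = "region") {
    stopIfNot(metric %in% names(table), sprintf("no column '%s'", metric))
    lab <- c(d2_um2 = "squared inter-probe distance d2 (um^2)",
             d_um = "inter-probe distance d (um)",
             frac_radius = "fractional radius")
    ggplot2::ggplot(table, ggplot2::aes(
        x = .data[[groupBy]], y = .data[[metric]])) +
        ggplot2::stat_boxplot(geom = "errorbar", coef = Inf, width = 0.3) +
        ggplot2::geom_boxplot(coef = Inf, outlier.shape = NA) +
        ggplot2::labs(x = NULL,
                      y = if (metric %in% names(lab)) lab[[metric]] else metric) +
        ggplot2::theme_classic()
}

#' Radial-distribution curves per group
#'
#' Relative-frequency polygons of fractional radius over equal-width bins
#' (0 = nuclear periphery, 1 = centre), one curve per group.
#'
#' @param table measurement data.frame with a \code{frac_radius} column.
#' @param groupBy grouping column.
#' @param bins number of bins.
#' @return A ggplot object.
#' @export
plotRadialDistribution <- function(table, groupBy = "region", bins = 10L) {
    groups <- unique(table[[groupBy]])
    curves <- do.call(rbind, lapply(groups, function(g) {
        v <- table$frac_radius[table[[groupBy]] == g]
        v <- v[v >= 0 & v <= 1]
        rd <- radialDistribution(v, bins)
        data.frame(group = g, mid = rd$mids, freq = rd$freq)
    }))
    ggplot2::ggplot(curves, ggplot2::aes(x = .data$mid, y = .data$freq,
                                         colour = .data$group)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "fractional radius (0 = periphery, 1 = centre)",
                      y = "relative frequency", colour = NULL) +
        ggplot2::theme_classic()
}
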