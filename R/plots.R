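#' Plot methods
#'
#' `autoplot()` methods render the standard figures for each result type:
#' an IP-vs-mock RPM scatter for RIP enrichment tables, a volcano plot for
#' differential results, grouped SEF box plots, a wild-type / mutant /
#' rescue expression heat map for rescue assessments, and a group bar chart
#' for relative Oil Red O reports.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ripsef-plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot geom_tile
#'   geom_col geom_errorbar scale_x_log10 scale_y_log10 labs theme_minimal
#'   geom_hline geom_vline scale_fill_gradient2
#' @export
ggplot2::autoplot

#' @rdname ripsef-plots
#' @export
autoplot.rip_tbl <- function(object, ...) {
  fc_min <- attr(object, "fc_min") %||% 4
  ggplot(object, aes(x = .data$mock_rpm + 1, y = .data$ip_rpm + 1,
                     colour = .data$bound)) +
    geom_point(size = 0.4, alpha = 0.5) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "mock IP RPM + 1", y = "IP RPM + 1", colour = "bound",
         title = paste0("IP enrichment (FC ≥ ", fc_min, ")")) +
    theme_minimal()
}

#' @rdname ripsef-plots
#' @export
autoplot.de_result <- function(object, ...) {
  dat <- filter(as_tibble(object), !is.na(.data$p_value))
  q_max <- attr(object, "q_max") %||% 0.05
  fc_min <- attr(object, "fc_min") %||% 2
  ggplot(dat, aes(x = .data$log2fc, y = -log10(pmax(.data$p_value, 1e-300)),
                  colour = .data$direction)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)), linetype = 2) +
    labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    theme_minimal()
}

#' @rdname ripsef-plots
#' @export
autoplot.sef_comparison <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$group)) +
    geom_boxplot(aes(lower = .data$q25, middle = .data$median,
                     upper = .data$q75, ymin = .data$q25, ymax = .data$q75),
                 stat = "identity", width = 0.5) +
    scale_y_log10() +
    labs(x = NULL, y = "soma enrichment factor (SEF)") +
    theme_minimal()
}

#' @rdname ripsef-plots
#' @export
autoplot.rescue_assessment <- function(object, ...) {
  dat <- object$genes |>
    mutate(order = dplyr::row_number()) |>
    tidyr::pivot_longer(c("wild_type", "mutant", "rescue"),
                        names_to = "genotype", values_to = "rpkm") |>
    mutate(genotype = factor(.data$genotype,
                             levels = c("wild_type", "mutant", "rescue")))
  ggplot(dat, aes(x = .data$genotype, y = stats::reorder(.data$gene_id, -.data$order),
                  fill = log2(.data$rpkm + 1))) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         midpoint = stats::median(log2(dat$rpkm + 1))) +
    labs(x = NULL, y = NULL, fill = "log2(RPKM+1)") +
    theme_minimal()
}

#' Group bar chart of a relative Oil Red O report
#'
#' @param report Result of [relative_oro()].
#' @return A ggplot object.
#' @export
plot_oro_groups <- function(report) {
  ggplot(report$groups, aes(x = .data$group, y = .data$mean_relative)) +
    geom_col(fill = "firebrick", width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean_relative - .data$sd_relative,
                      ymax = .data$mean_relative + .data$sd_relative),
                  width = 0.2) +
    geom_hline(yintercept = 1, linetype = 2) +
    labs(x = NULL, y = "relative Oil Red O index") +
    theme_minimal()
}
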