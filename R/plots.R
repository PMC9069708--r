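#' MA-style plot of a DEG table
#'
#' Mean expression (log10 of the age-averaged RPKM) against log2 fold
#' change, colored by classification status.
#'
#' @param object A `deg_table` from [classify_deg()].
#' @param ... Unused.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  df <- as_tibble(object)
  df <- mutate(df, mean_expr = (.data$mean_young + .data$mean_aged) / 2)
  df <- filter(df, .data$status != "not_expressed")
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mean_expr + 0.01),
                                   y = .data$log2fc,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log10 mean RPKM", y = "log2 FC (aged / young)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cochleogram survival profile
#'
#' Survival percentage against cochlear location, one line per cell
#' type.
#'
#' @param survival Output of [survival_percentage()].
#' @export
plot_survival <- function(survival) {
  ggplot2::ggplot(survival,
                  ggplot2::aes(x = .data$location_um, y = .data$percent,
                               colour = .data$cell_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = "Distance from apex (µm)", y = "Survival (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Command and current of a simulated recording segment
#'
#' @param object A `vc_recording`.
#' @param segment Which analysis segment to show (row of the segments
#'   table).
#' @param ... Unused.
#' @method autoplot vc_recording
#' @export
autoplot.vc_recording <- function(object, segment = 1, ...) {
  segs <- attr(object, "segments")
  idx <- segs$start[segment]:segs$end[segment]
  df <- tidyr::pivot_longer(as_tibble(object)[idx, ],
                            c("vcmd_mV", "current_nA"),
                            names_to = "channel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
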