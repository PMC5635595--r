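# broom-style tidiers and ggplot2 visualisations for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy sampled reconciliations into one row per gene node
#'
#' @param x A `dtl_samples` object.
#' @param ... Unused.
#' @return Tibble of modal events per gene node with support fractions.
#' @export
tidy.dtl_samples <- function(x, ...) {
  x$events |>
    group_by(.data$node) |>
    summarise(event = modal_value(.data$event),
              species = modal_value(.data$species),
              support = max(table(paste(.data$event, .data$species))) /
                dplyr::n(),
              .groups = "drop")
}

#' One-row summary of sampled reconciliations
#' @param x A `dtl_samples` object.
#' @param ... Unused.
#' @export
glance.dtl_samples <- function(x, ...) {
  tibble::tibble(cost = x$stats$cost[1L],
                 n_samples = nrow(x$stats),
                 mean_dup = mean(x$stats$n_dup),
                 mean_transfer = mean(x$stats$n_trans),
                 mean_loss = mean(x$stats$n_loss))
}

#' Tidy a retention summary
#' @param x A `retention_summary`.
#' @param ... Unused.
#' @return The per-event means tibble with test P-values attached.
#' @export
tidy.retention_summary <- function(x, ...) x$means

#' @export
glance.retention_summary <- function(x, ...) {
  tibble::tibble(
    rho_depth = x$depth_cor$rho,
    rho_p = x$depth_cor$p,
    p_spec_vs_dup = x$tests$p[x$tests$comparison == "speciation_vs_duplication"],
    p_trans_vs_dup = x$tests$p[x$tests$comparison == "transfer_vs_duplication"])
}

#' Plot event support across the transfer-cost grid
#'
#' One line per loss cost, showing a gene node's transfer-support fraction
#' against transfer cost -- the robustness profile behind transfer calls.
#'
#' @param object An `event_support` tibble.
#' @param nodes Gene node labels to show (default: nodes with any transfer
#'   support).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.event_support <- function(object, nodes = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (is.null(nodes)) {
    nodes <- unique(d$node[d$frac_transfer > 0])
  }
  d <- d |> filter(.data$node %in% nodes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$transfer, y = .data$frac_transfer,
                                  colour = factor(.data$loss))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~node) +
    ggplot2::labs(x = "transfer cost", y = "transfer support",
                  colour = "loss cost") +
    ggplot2::theme_minimal()
}

#' Plot the clade-association scan
#'
#' Corrected P per (clade, feature) on a -log10 scale, with reported
#' associations highlighted.
#'
#' @param object A `chg_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chg_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  alpha <- attr(object, "alpha") %||% 1e-4
  ggplot2::ggplot(d, ggplot2::aes(x = .data$clade,
                                  y = -log10(pmax(.data$p_corrected, 1e-300)),
                                  colour = .data$reported)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "clade", y = "-log10 corrected P") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot retention by event class
#'
#' @param object A `retention_summary`.
#' @param ... Unused.
#' @return A ggplot (boxplots of retention per event class).
#' @export
autoplot.retention_summary <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$event, y = .data$retention)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "shared-CHG fraction") +
    ggplot2::theme_minimal()
}

#' Plot junction counts along consensus coordinates
#'
#' @param counts Tibble from [junction_column_counts()].
#' @return A ggplot column chart.
#' @export
plot_junction_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$consensus, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "consensus position", y = "junctions") +
    ggplot2::theme_minimal()
}
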