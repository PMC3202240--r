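#' Plot a simulated time course
#'
#' One panel per state key, in the style of the glucose / lactate / ATP
#' kinetics figures: concentration (mM) against time (min).
#'
#' @param object An `anlsim_timecourse`.
#' @param keys State keys to draw (default: the figure-panel quartet of
#'   glucose, lactate and ATP series).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anlsim_timecourse <- function(object,
                                       keys = c("Glc@Nc", "Glc@Ac", "Lac@Nc",
                                                "Lac@Ac", "Lac@e", "ATP@Nm",
                                                "ATP@Am", "ATP@Nc", "ATP@Ac"),
                                       ...) {
  keys <- intersect(keys, names(object$data))
  long <- tidyr::pivot_longer(object$data[, c("time", keys)], -"time",
                              names_to = "key", values_to = "value")
  long$key <- factor(long$key, levels = keys)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c5aa0") +
    ggplot2::facet_wrap(~key, scales = "free_y") +
    ggplot2::labs(
      x = "time (min)", y = "concentration (mM)",
      title = sprintf("%s model, %s", object$variant, object$scenario$name)) +
    ggplot2::theme_minimal()
}

#' Plot variant comparison fold-changes
#'
#' @param object An `anlsim_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anlsim_comparison <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$scenario, y = .data$fold_change)) +
    ggplot2::geom_col(fill = "#2c5aa0") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~key) +
    ggplot2::labs(x = NULL, y = "plateau fold-change (ANLSH / classical)") +
    ggplot2::theme_minimal()
}

#' Plot an expression panel
#'
#' Reference-normalised abundances by condition, mirroring the RT-PCR-style
#' readout the regulation module is calibrated against.
#'
#' @param panel Tibble from [generate_expression_panel()].
#' @return A ggplot object.
#' @export
plot_expression_panel <- function(panel) {
  ggplot2::ggplot(panel,
                  ggplot2::aes(x = .data$gene, y = .data$abundance,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "abundance (reference-normalised)") +
    ggplot2::theme_minimal()
}

#' Plot hypoxia-vs-normoxia regulation kinetics
#'
#' mRNA and protein trajectories of one gene under two oxygen tensions,
#' from [simulate_regulation()] output.
#'
#' @param norm,hyp Long tibbles from [simulate_regulation()].
#' @param gene Gene to draw.
#' @return A ggplot object.
#' @export
plot_regulation_kinetics <- function(norm, hyp, gene = "HK") {
  dat <- dplyr::bind_rows(
    dplyr::mutate(norm, condition = "normoxia"),
    dplyr::mutate(hyp, condition = "hypoxia"))
  dat <- dat[dat$gene %in% gene &
               dat$quantity %in% c("mrna_nucleus", "protein"), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (mM)", title = gene) +
    ggplot2::theme_minimal()
}
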