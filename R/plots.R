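#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hotspot table
#'
#' Horizontal bars of mean electrostatic and van der Waals interaction
#' energy for the most favourable residues (lowest total energy first).
#'
#' @param object a `hotspot_table`
#' @param n_top residues to show
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.hotspot_table <- function(object, n_top = 10, ...) {
  tab <- utils::head(rank_hotspots(object, "total"), n_top)
  lab <- ifelse(is.na(tab$bw), as.character(tab$resid),
                paste0(tab$resid, " (", tab$bw, ")"))
  long <- tidyr::pivot_longer(
    dplyr::mutate(tab, residue = factor(lab, levels = rev(lab))),
    cols = c("elec_mean", "vdw_mean"),
    names_to = "component", values_to = "energy"
  )
  long$component <- dplyr::recode(long$component,
                                  elec_mean = "electrostatic",
                                  vdw_mean = "van der Waals")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$energy, y = .data$residue,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mean interaction energy (kcal/mol)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a 4PL fit
#'
#' Observed responses and the fitted concentration-response curve.
#'
#' @param object a `drc_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.drc_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$log10_conc) - 0.5, max(d$log10_conc) + 0.5,
            length.out = 200)
  curve <- tibble::tibble(log10_conc = xs,
                          response = predict(object,
                                             tibble::tibble(log10_conc = xs)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_conc,
                                  y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "log10 concentration (M)", y = "response") +
    ggplot2::theme_minimal()
}

#' Plot per-frame occupancy
#'
#' @param object an `occupancy_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.occupancy_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame,
                                  y = as.numeric(.data$occupied))) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("free", "occupied")) +
    ggplot2::labs(x = "frame", y = NULL,
                  title = sprintf("pocket occupancy %.1f%%", object$percent)) +
    ggplot2::theme_minimal()
}
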