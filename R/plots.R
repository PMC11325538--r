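## ggplot2 autoplot methods for the package's result objects.

#' Plot per-window free energies of an MBAR fit
#'
#' @param object An `abfe_mbar` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abfe_mbar <- function(object, ...) {
  df <- tidy.abfe_mbar(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$f_kcal)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "window", y = "free energy (kcal/mol)",
                  title = "MBAR per-window free energies") +
    ggplot2::theme_minimal()
}

#' Plot the component ledger of an assembled cycle
#'
#' Bar chart of the letter-coded components (site -> bulk direction) with
#' block uncertainties, annotated with the assembled binding free energy.
#'
#' @param object An `abfe_cycle` from [assemble()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abfe_cycle <- function(object, ...) {
  df <- object$components
  df$letter <- factor(df$letter, levels = df$letter)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$letter, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$uncertainty,
                   ymax = .data$value + .data$uncertainty),
      width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "component", y = "free energy (kcal/mol)",
      title = sprintf("%s cycle: dG_bind = %.1f (%.1f) kcal/mol",
                      object$scheme, round_half_away(object$dg_bind, 1),
                      round_half_away(object$uncertainty, 1))) +
    ggplot2::theme_minimal()
}

#' Plot planned simulation time per component
#'
#' @param object An `abfe_plan` from [plan_protocol()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abfe_plan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$time_ns)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "component", y = "planned time (ns)",
                  title = sprintf("protocol total: %.1f ns",
                                  sum(df$time_ns))) +
    ggplot2::theme_minimal()
}
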