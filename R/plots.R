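# ggplot2 views of the main result types.

#' @export
autoplot.scan_table <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$ddG)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::labs(x = expression(Delta * Delta * G ~ "(kcal/mol)"),
                  y = "motifs",
                  title = "Relative binding energies across the motif space")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @export
autoplot.frequency_matrix <- function(object, ...) {
  df <- tidy(object)
  ic <- information_profile(object)
  df <- left_join(df, ic, by = "position")
  df$height <- df$p * df$bits
  df <- df |> group_by(.data$position) |>
    arrange(.data$height, .by_group = TRUE) |>
    mutate(ytop = cumsum(.data$height),
           ymid = .data$ytop - .data$height / 2) |>
    ungroup() |> filter(.data$height > 1e-3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$base,
                                    size = .data$height,
                                    colour = .data$base)) +
    ggplot2::scale_size_continuous(range = c(2, 10), guide = "none") +
    ggplot2::scale_colour_manual(values = c(
      A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839"),
      guide = "none") +
    ggplot2::scale_x_continuous(breaks = unique(df$position)) +
    ggplot2::labs(x = "motif position", y = "information (bits)",
                  title = "Energy-weighted sequence logo") +
    ggplot2::ylim(0, 2)
}

#' @export
autoplot.thermogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$injection, y = .data$heat)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "injection", y = "heat (ucal)",
                  title = "Integrated injection heats")
}

#' @export
autoplot.binding_fit <- function(object, ...) {
  df <- object$fitted
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$injection)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat)) +
    ggplot2::labs(x = "injection", y = "heat (ucal)",
                  title = "One-site fit")
  if (object$converged) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                colour = "red")
  }
  p
}

#' @export
autoplot.icrm_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue",
                  title = "Distance-gated correlation matrix")
}
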