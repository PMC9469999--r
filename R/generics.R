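# Re-exported generics so tidy()/glance()/autoplot() work without attaching
# their home packages.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL

#' Plot a label map
#'
#' Raster display of a tissue label map (outside/remote/lesion/MVO),
#' optionally over the intensity image.
#'
#' @param labelmap An `lge_label_map`.
#' @return A ggplot object.
#' @export
plot_label_map <- function(labelmap) {
  l <- labelmap$labels
  df <- tibble::tibble(
    row = rep(seq_len(nrow(l)), times = ncol(l)),
    col = rep(seq_len(ncol(l)), each = nrow(l)),
    class = factor(as.vector(l), levels = 0:3,
                   labels = names(lge_labels())))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(outside = "black", remote = "grey40",
                                          lesion = "magenta", mvo = "yellow")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = labelmap$method) +
    ggplot2::theme_void()
}
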