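#' Plot a mid-plane slice of a scalar field
#'
#' Heatmap of the field on an axis-aligned plane through the grid (default
#' the central z-plane). Potential maps are usually shown saturated at
#' +/-5 kT/e and isopotential renderings at +/-1.5 kT/e; ESI maps are often
#' displayed on 0.5-0.7-0.9 (perturbation families) or -0.10-0.15-0.40
#' (homologue families) colour scales — set `limits` accordingly.
#'
#' @param object a `scalar_field`.
#' @param slice_axis axis normal to the slice (`"z"`, `"y"`, `"x"`).
#' @param index node index of the slice (default: middle).
#' @param limits optional colour limits, e.g. `c(-5, 5)` for potentials.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scalar_field <- function(object, slice_axis = "z", index = NULL,
                                  limits = NULL, ...) {
  g <- object$spec
  ax <- grid_axes(g)
  a <- match(slice_axis, c("x", "y", "z"))
  if (is.null(index)) index <- (g$points[a] + 1L) %/% 2L
  sl <- switch(a,
               object$values[index, , ],
               object$values[, index, ],
               object$values[, , index])
  keep <- setdiff(1:3, a)
  df <- expand.grid(h = ax[[keep[1]]], v = ax[[keep[2]]])
  df$value <- as.vector(sl)
  if (!is.null(limits)) df$value <- pmin(pmax(df$value, limits[1]), limits[2])
  lab <- c("x (A)", "y (A)", "z (A)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  midpoint = if (is.null(limits)) 0 else mean(limits),
                                  limits = limits, name = object$unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[keep[1]], y = lab[keep[2]],
                  title = sprintf("%s slice, %s = %.2f A", object$unit,
                                  slice_axis, ax[[a]][index])) +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity matrix
#'
#' @param object a `similarity_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Per-residue profile of a projected field
#'
#' @param object an `atom_projection`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.atom_projection <- function(object, ...) {
  df <- object$residues
  df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "residue", y = object$unit) +
    ggplot2::theme_minimal()
}

#' @export
plot.esimap_hclust <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}
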