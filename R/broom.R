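#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory
#'
#' @param x A [trajectory()].
#' @param ... Unused.
#' @return A plain tibble with one row per frame (`frame`, `x`, `y`) plus
#'   per-frame displacement `step` in pixels (NA on the first frame).
#' @export
tidy.trajectory <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(step = c(NA_real_,
                           sqrt(diff(.data$x)^2 + diff(.data$y)^2)))
}

#' Summarize a trajectory in one row
#'
#' @param x A [trajectory()].
#' @param ... Unused.
#' @return A one-row tibble: frame span, number of frames, total path
#'   length (px) and mean speed (px/frame).
#' @export
glance.trajectory <- function(x, ...) {
  steps <- if (nrow(x) > 1L) sqrt(diff(x$x)^2 + diff(x$y)^2) else numeric(0)
  tibble::tibble(
    n_frames = nrow(x),
    first_frame = if (nrow(x)) min(x$frame) else NA_integer_,
    last_frame = if (nrow(x)) max(x$frame) else NA_integer_,
    path_length = sum(steps),
    mean_speed = if (length(steps)) mean(steps) else 0
  )
}

#' Tidy a click set
#'
#' @param x A [click_set()].
#' @param ... Unused.
#' @return A tibble with one row per click and a per-frame click index.
#' @export
tidy.click_set <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$frame) |>
    dplyr::mutate(click = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Tidy a symbol geometry into vertices
#'
#' @param x A [make_symbol()] / [place_symbol()] geometry.
#' @param circle_segments Number of segments used to outline circles.
#' @param ... Unused.
#' @return A tibble with columns `primitive`, `kind`, `fill`, `x`, `y`.
#' @export
tidy.symbol_geometry <- function(x, circle_segments = 64L, ...) {
  dplyr::bind_rows(lapply(seq_along(x$primitives), function(i) {
    p <- x$primitives[[i]]
    if (p$kind == "circle") {
      th <- seq(0, 2 * pi, length.out = circle_segments + 1L)
      tibble::tibble(primitive = i, kind = p$kind, fill = p$fill,
                     x = p$cx + p$r * cos(th), y = p$cy + p$r * sin(th))
    } else {
      tibble::tibble(primitive = i, kind = p$kind, fill = p$fill,
                     x = p$x, y = p$y)
    }
  }))
}

#' Plot a trajectory
#'
#' Path plus per-frame anchors, drawn in screen orientation (y axis
#' reversed so the origin sits at the top left, as in the movie).
#'
#' @param object A [trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(color = "brown") +
    ggplot2::geom_point(ggplot2::aes(color = .data$frame), size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "frame")
}

#' Plot a click set
#'
#' @param object A [click_set()].
#' @param ... Unused.
#' @return A ggplot object in screen orientation.
#' @export
autoplot.click_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 21, color = "goldenrod", size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$frame), labeller = "label_both") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a symbol geometry
#'
#' Previews a glyph the way the option panel preview does: filled
#' primitives as polygons, strokes as paths, screen orientation.
#'
#' @param object A [make_symbol()] / [place_symbol()] geometry.
#' @param color Fill/stroke color used in the preview.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symbol_geometry <- function(object, color = "red", ...) {
  df <- tidy.symbol_geometry(object)
  filled <- df[df$fill, , drop = FALSE]
  open <- df[!df$fill, , drop = FALSE]
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$x, y = .data$y,
                                              group = .data$primitive))
  if (nrow(filled)) p <- p + ggplot2::geom_polygon(data = filled, fill = color)
  if (nrow(open)) p <- p + ggplot2::geom_path(data = open, color = color)
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' @importFrom rlang .data
NULL
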