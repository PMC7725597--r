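#' Available symbol styles and colors
#'
#' Five glyph families are supported: `DELTA` (solid triangular head),
#' `THICK` (solid open chevron band), `THIN` (two stroked line segments),
#' `CIRCLE` (a circle centered on the anchor) and `POINTY` (a barbed,
#' concave-backed head). Colors come from a fixed named palette mapped to
#' exact RGB bytes.
#'
#' @return `symbol_styles()`: character vector of the five style names.
#' @export
symbol_styles <- function() c("DELTA", "THICK", "THIN", "CIRCLE", "POINTY")

.palette <- list(
  red     = c(255L,   0L,   0L),
  green   = c(  0L, 255L,   0L),
  blue    = c(  0L,   0L, 255L),
  yellow  = c(255L, 255L,   0L),
  magenta = c(255L,   0L, 255L),
  cyan    = c(  0L, 255L, 255L),
  white   = c(255L, 255L, 255L),
  black   = c(  0L,   0L,   0L),
  orange  = c(255L, 165L,   0L),
  brown   = c(165L,  42L,  42L)
)

#' @rdname symbol_styles
#' @param color A palette color name; omit to list all names.
#' @return `annot_color()`: length-3 integer RGB vector for `color`;
#'   with no argument, the vector of available color names.
#' @export
annot_color <- function(color) {
  if (missing(color)) return(names(.palette))
  rgb <- .palette[[match.arg(color, names(.palette))]]
  rgb
}

#' Specify a graphical symbol
#'
#' Captures the full parameterization of one symbol: its style, head
#' length, overall length, stroke thickness, fill state, color, and how it
#' is positioned relative to the trajectory anchor (rotation angle and x/y
#' offset). The proportion constants the styles share (head apex
#' half-angle, barb depth as a fraction of head length) default to values
#' matched by eye to the classic arrow glyphs and can be overridden.
#'
#' @param style One of [symbol_styles()].
#' @param head_length Head extent in pixels, > 0. For `CIRCLE` this is the
#'   circle radius.
#' @param length Total symbol extent (shaft + head) in pixels, >= 0. When
#'   `length <= head_length` the shaft collapses and only the head is drawn
#'   (arrowhead mode); ignored by `CIRCLE`.
#' @param thickness Shaft/stroke width in pixels, > 0.
#' @param filled Fill closed primitives (`TRUE`) or stroke their outlines.
#' @param color Palette color name, see [annot_color()].
#' @param angle Rotation in degrees about the anchor. A positive angle
#'   turns the symbol counterclockwise in conventional math axes, which is
#'   clockwise on screen where y increases downward.
#' @param dx,dy Offset of the symbol tip from the anchor, in pixels.
#' @param half_angle_deg Head apex half-angle in degrees.
#' @param barb_fraction For `POINTY`: how far the back of the head is
#'   pulled toward the tip, as a fraction of `head_length`.
#' @return A `symbol_spec` object.
#' @export
#' @examples
#' symbol_spec("DELTA", head_length = 12, length = 40, thickness = 4,
#'             color = "red", angle = 45)
symbol_spec <- function(style, head_length = 10, length = 30, thickness = 3,
                        filled = TRUE, color = "red", angle = 0,
                        dx = 0, dy = 0,
                        half_angle_deg = 30, barb_fraction = 1 / 3) {
  if (!is.character(style) || length(style) != 1L || !style %in% symbol_styles()) {
    stop("unknown symbol style ", deparse(substitute(style)),
         "; must be one of: ", paste(symbol_styles(), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(head_length > 0, length >= 0, thickness > 0,
            is.logical(filled), length(filled) == 1L,
            is.finite(angle), is.finite(dx), is.finite(dy),
            half_angle_deg > 0, half_angle_deg < 90,
            barb_fraction >= 0, barb_fraction < 1)
  rgb <- annot_color(color)
  structure(
    list(style = style, head_length = head_length, length = length,
         thickness = thickness, filled = filled,
         color = match.arg(color, names(.palette)), rgb = rgb,
         angle = angle, dx = dx, dy = dy,
         half_angle_deg = half_angle_deg, barb_fraction = barb_fraction),
    class = "symbol_spec"
  )
}

#' @export
print.symbol_spec <- function(x, ...) {
  cat(sprintf(
    "<symbol_spec> %s  head %g px, length %g px, thickness %g px, %s, %s\n",
    x$style, x$head_length, x$length, x$thickness,
    if (x$filled) "filled" else "outlined", x$color))
  cat(sprintf("  angle %g deg, offset (%g, %g) px\n", x$angle, x$dx, x$dy))
  invisible(x)
}

poly_prim <- function(x, y, fill, stroke) {
  list(kind = "polygon", x = x, y = y, fill = fill, stroke = stroke)
}
line_prim <- function(x, y, stroke) {
  list(kind = "polyline", x = x, y = y, fill = FALSE, stroke = stroke)
}
circ_prim <- function(cx, cy, r, fill, stroke) {
  list(kind = "circle", cx = cx, cy = cy, r = r, fill = fill, stroke = stroke)
}

new_symbol_geometry <- function(primitives) {
  structure(list(primitives = primitives, anchor = c(0, 0)),
            class = "symbol_geometry")
}

#' Build a symbol's geometry
#'
#' Constructs the glyph in local coordinates: the tip (the pointing end)
#' sits at the origin and the shaft extends toward +x, so the symbol
#' points in the -x direction. The geometry is a list of polygon, polyline
#' and circle primitives; identical specs yield identical geometry.
#'
#' @param spec A [symbol_spec()].
#' @return A `symbol_geometry` with the tip anchored at the local origin.
#' @export
make_symbol <- function(spec) {
  stopifnot(inherits(spec, "symbol_spec"))
  hl <- spec$head_length
  t2 <- spec$thickness / 2
  w <- hl * tan(spec$half_angle_deg * pi / 180)
  shaft_needed <- spec$style != "CIRCLE" && spec$length > hl
  prims <- switch(
    spec$style,
    DELTA = {
      p <- list(poly_prim(c(0, hl, hl), c(0, w, -w), spec$filled, spec$thickness))
      if (shaft_needed) {
        p <- c(p, list(poly_prim(c(hl, spec$length, spec$length, hl),
                                 c(-t2, -t2, t2, t2),
                                 spec$filled, spec$thickness)))
      }
      p
    },
    THICK = {
      # solid chevron band: outer edge is the V through the tip, inner edge
      # the V offset inward (toward +x) by the full thickness
      alpha <- atan2(w, hl)
      n_up <- c(-sin(alpha), cos(alpha))    # outward normal of upper arm
      n_dn <- c(-sin(alpha), -cos(alpha))
      t <- spec$thickness
      band <- poly_prim(
        x = c(hl, 0, hl, hl - t * n_dn[1], t / sin(alpha), hl - t * n_up[1]),
        y = c(w, 0, -w, -w - t * n_dn[2], 0, w - t * n_up[2]),
        fill = TRUE, stroke = spec$thickness)
      p <- list(band)
      if (shaft_needed) {
        p <- c(p, list(poly_prim(c(hl, spec$length, spec$length, hl),
                                 c(-t2, -t2, t2, t2),
                                 spec$filled, spec$thickness)))
      }
      p
    },
    THIN = {
      p <- list(line_prim(c(hl, 0, hl), c(w, 0, -w), spec$thickness))
      if (shaft_needed) {
        p <- c(p, list(line_prim(c(hl, spec$length), c(0, 0), spec$thickness)))
      }
      p
    },
    POINTY = {
      notch <- hl - hl * spec$barb_fraction
      p <- list(poly_prim(c(0, hl, notch, hl), c(0, w, 0, -w),
                          spec$filled, spec$thickness))
      if (shaft_needed) {
        p <- c(p, list(poly_prim(c(notch, spec$length, spec$length, notch),
                                 c(-t2, -t2, t2, t2),
                                 spec$filled, spec$thickness)))
      }
      p
    },
    CIRCLE = list(circ_prim(0, 0, hl, spec$filled, spec$thickness))
  )
  new_symbol_geometry(prims)
}

#' Place a symbol at a trajectory anchor
#'
#' Rigidly maps the local geometry onto screen coordinates: every vertex v
#' becomes `R(angle) v + (x + dx, y + dy)`, rotating about the tip so the
#' symbol pivots around the point it points at, then translating so the
#' tip lands exactly at `(x + dx, y + dy)`. A positive angle rotates
#' counterclockwise in math axes, i.e. clockwise as seen on screen with y
#' increasing downward.
#'
#' @param geom A [make_symbol()] geometry.
#' @param anchor Length-2 numeric `(x, y)` anchor in pixels.
#' @param angle Rotation in degrees.
#' @param dx,dy Additional offset in pixels.
#' @return The placed `symbol_geometry` in screen coordinates.
#' @export
place_symbol <- function(geom, anchor, angle = 0, dx = 0, dy = 0) {
  stopifnot(inherits(geom, "symbol_geometry"),
            length(anchor) == 2L, all(is.finite(anchor)),
            is.finite(angle), is.finite(dx), is.finite(dy))
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  tx <- anchor[1] + dx; ty <- anchor[2] + dy
  # screen coords have y down; counterclockwise-in-math rotation is
  # [c, s; -s, c] acting on (x, y_screen)
  map <- function(px, py) {
    list(x = co * px + si * py + tx, y = -si * px + co * py + ty)
  }
  prims <- lapply(geom$primitives, function(p) {
    if (p$kind == "circle") {
      ctr <- map(p$cx, p$cy)
      p$cx <- ctr$x; p$cy <- ctr$y
    } else {
      v <- map(p$x, p$y)
      p$x <- v$x; p$y <- v$y
    }
    p
  })
  out <- new_symbol_geometry(prims)
  out$anchor <- c(tx, ty)
  out
}

#' @export
print.symbol_geometry <- function(x, ...) {
  kinds <- vapply(x$primitives, `[[`, character(1), "kind")
  cat(sprintf("<symbol_geometry> %d primitive(s): %s; anchor (%g, %g)\n",
              length(kinds), paste(kinds, collapse = ", "),
              x$anchor[1], x$anchor[2]))
  invisible(x)
}

# all vertices of a geometry as an n x 2 matrix (circle centers included)
geometry_vertices <- function(geom) {
  do.call(rbind, lapply(geom$primitives, function(p) {
    if (p$kind == "circle") cbind(p$cx, p$cy) else cbind(p$x, p$y)
  }))
}

# axis-aligned bounding box (xmin, ymin, xmax, ymax) incl. stroke dilation
geometry_bbox <- function(geom) {
  boxes <- lapply(geom$primitives, function(p) {
    pad <- if (p$fill && p$kind != "circle") 0 else p$stroke / 2
    if (p$kind == "circle") {
      pad <- if (p$fill) 0 else p$stroke / 2
      c(p$cx - p$r - pad, p$cy - p$r - pad, p$cx + p$r + pad, p$cy + p$r + pad)
    } else {
      c(min(p$x) - pad, min(p$y) - pad, max(p$x) + pad, max(p$y) + pad)
    }
  })
  m <- do.call(rbind, boxes)
  c(min(m[, 1]), min(m[, 2]), max(m[, 3]), max(m[, 4]))
}
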