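MARKER_RADIUS <- 4
MARKER_STROKE <- 1

#' Create an empty overlay
#'
#' An overlay holds the renderable items of each frame — yellow click
#' markers, brown interpolated-trajectory markers, and placed symbols —
#' separate from the pixel data. Nothing touches movie pixels until
#' [rasterize()] or [flatten()] is called.
#'
#' @return An `overlay` object with no items.
#' @export
overlay <- function() {
  new_overlay(tibble::tibble(
    frame = integer(), role = character(), color = character(), geom = list()
  ))
}

new_overlay <- function(items) structure(list(items = items), class = "overlay")

#' @export
print.overlay <- function(x, ...) {
  n <- nrow(x$items)
  cat(sprintf("<overlay> %d item(s) on %d frame(s)\n",
              n, length(unique(x$items$frame))))
  if (n > 0) print(table(x$items$role))
  invisible(x)
}

marker_geom <- function(x, y) {
  new_symbol_geometry(list(circ_prim(x, y, MARKER_RADIUS, fill = FALSE,
                                     stroke = MARKER_STROKE)))
}

append_items <- function(ov, frame, role, color, geoms) {
  new <- tibble::tibble(frame = as.integer(frame), role = role,
                        color = color, geom = geoms)
  new_overlay(dplyr::bind_rows(ov$items, new))
}

#' Add yellow click markers
#'
#' One yellow circle per raw click, on the click's frame — the working aid
#' that shows where the user has labeled.
#'
#' @param ov An [overlay()].
#' @param clicks A [click_set()].
#' @return The overlay with the markers appended.
#' @export
add_click_markers <- function(ov, clicks) {
  stopifnot(inherits(ov, "overlay"), inherits(clicks, "click_set"))
  if (nrow(clicks) == 0L) return(ov)
  geoms <- Map(marker_geom, clicks$x, clicks$y)
  append_items(ov, clicks$frame, "click_marker", "yellow", geoms)
}

#' Add brown trajectory markers
#'
#' One brown circle per trajectory entry. Re-adding trajectory markers
#' first discards the previous ones, so the overlay always shows only the
#' newest interpolation result.
#'
#' @param ov An [overlay()].
#' @param traj A [trajectory()].
#' @return The overlay with trajectory markers replaced.
#' @export
add_trajectory_markers <- function(ov, traj) {
  stopifnot(inherits(ov, "overlay"), inherits(traj, "trajectory"))
  kept <- new_overlay(ov$items[ov$items$role != "traj_marker", , drop = FALSE])
  if (nrow(traj) == 0L) return(kept)
  geoms <- Map(marker_geom, traj$x, traj$y)
  append_items(kept, traj$frame, "traj_marker", "brown", geoms)
}

#' Draw a symbol along a trajectory
#'
#' Places one copy of the symbol on every trajectory frame, the tip landing
#' at the trajectory position shifted by the spec's dx/dy, rotated by its
#' angle. Drawing twice without [remove_symbols()] stacks a second set of
#' symbols, mirroring the remove-then-redraw workflow.
#'
#' @param ov An [overlay()].
#' @param traj A non-empty [trajectory()].
#' @param spec A [symbol_spec()].
#' @return The overlay with one placed symbol per trajectory frame.
#' @export
draw_symbols <- function(ov, traj, spec) {
  stopifnot(inherits(ov, "overlay"), inherits(traj, "trajectory"),
            inherits(spec, "symbol_spec"))
  if (nrow(traj) == 0L) stop("cannot draw symbols along an empty trajectory",
                             call. = FALSE)
  base <- make_symbol(spec)
  geoms <- Map(function(x, y) place_symbol(base, c(x, y), spec$angle,
                                           spec$dx, spec$dy),
               traj$x, traj$y)
  append_items(ov, traj$frame, "symbol", spec$color, geoms)
}

#' Remove all drawn symbols
#'
#' Clears every placed symbol from every frame while leaving click and
#' trajectory markers untouched — the step before re-drawing with new
#' parameters.
#'
#' @param ov An [overlay()].
#' @return The overlay without symbol items.
#' @export
remove_symbols <- function(ov) {
  stopifnot(inherits(ov, "overlay"))
  new_overlay(ov$items[ov$items$role != "symbol", , drop = FALSE])
}

check_overlay_frames <- function(ov, movie) {
  bad <- setdiff(unique(ov$items$frame), seq_len(movie$n_frames))
  if (length(bad) > 0L) {
    stop("overlay has items on frame(s) ", paste(sort(bad), collapse = ", "),
         " but the movie has only ", movie$n_frames, " frame(s)", call. = FALSE)
  }
}

#' Paint an overlay onto a copy of a movie
#'
#' Returns a new movie with every overlay item rasterized into its frame's
#' pixels, in item insertion order (later items overpaint earlier ones).
#' Filled primitives use integer scanline fill, outlines and lines are
#' stroked at their thickness, and everything is clipped to the frame
#' bounds; the source movie is left untouched.
#'
#' @param ov An [overlay()]; items on frames outside the movie are an error.
#' @param movie A [movie()].
#' @param roles Which item roles to paint (default: all).
#' @return A new, annotated [movie()].
#' @export
rasterize <- function(ov, movie, roles = c("click_marker", "traj_marker", "symbol")) {
  stopifnot(inherits(ov, "overlay"), inherits(movie, "movie"))
  check_overlay_frames(ov, movie)
  items <- ov$items[ov$items$role %in% roles, , drop = FALSE]
  frames <- movie$frames
  for (i in seq_len(nrow(items))) {
    f <- items$frame[i]
    frames[[f]] <- paint_geometry(frames[[f]], items$geom[[i]],
                                  annot_color(items$color[i]))
  }
  out <- movie
  out$frames <- frames
  out
}

#' Permanently burn the overlay into the movie
#'
#' The destructive step before saving: paints the overlay's symbols into
#' the pixel data and returns the annotated movie together with an emptied
#' overlay. Markers are working aids and are excluded by default; set
#' `include_markers = TRUE` to burn them in as well.
#'
#' @param movie A [movie()].
#' @param ov An [overlay()].
#' @param include_markers Also paint click/trajectory markers.
#' @return A list with elements `movie` (annotated) and `overlay` (empty).
#' @export
flatten <- function(movie, ov, include_markers = FALSE) {
  roles <- if (include_markers) c("click_marker", "traj_marker", "symbol")
           else "symbol"
  list(movie = rasterize(ov, movie, roles = roles), overlay = overlay())
}
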