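#' Create an empty click set
#'
#' A click set collects raw landmark clicks, several per frame if need be,
#' before they are fused into a trajectory. It is an ordinary tibble with
#' columns `frame` (1-based frame number), `x` and `y` (pixel coordinates,
#' x rightward, y downward, origin at the top-left corner of the frame),
#' so it composes with dplyr verbs; row order records click order.
#'
#' @return A `click_set` tibble with zero rows.
#' @seealso [add_click()], [frame_median()], [interpolate()]
#' @export
#' @examples
#' click_set() |> add_click(3, 10, 20)
click_set <- function() {
  new_click_set(tibble::tibble(frame = integer(), x = double(), y = double()))
}

new_click_set <- function(df) {
  structure(df, class = c("click_set", class(tibble::tibble())))
}

#' Record one or more clicks on a frame
#'
#' Appends clicks to a click set. Clicking several times at the right
#' position is the intended way to override an earlier miss-click: the
#' per-frame median used by [interpolate()] ignores outvoted outliers.
#'
#' @param clicks A [click_set()] tibble.
#' @param frame Frame number(s), 1-based.
#' @param x,y Pixel coordinates, non-negative. Vectors are recycled against
#'   `frame` by ordinary rules.
#' @return The click set with the new clicks appended.
#' @export
add_click <- function(clicks, frame, x, y) {
  stopifnot(inherits(clicks, "click_set"))
  if (length(frame) == 0L) return(clicks)
  if (any(!is.finite(frame)) || any(frame < 1) || any(frame != floor(frame))) {
    stop("`frame` must be a whole number >= 1", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    stop("click coordinates must be finite and non-negative", call. = FALSE)
  }
  new <- tibble::tibble(frame = as.integer(frame), x = as.double(x), y = as.double(y))
  new_click_set(dplyr::bind_rows(tibble::as_tibble(clicks), new))
}

#' Discard all recorded clicks
#'
#' @param clicks A [click_set()].
#' @return An empty click set.
#' @export
remove_points <- function(clicks) {
  stopifnot(inherits(clicks, "click_set"))
  click_set()
}

#' Component-wise median of clicked positions
#'
#' Fuses the clicks of one frame into a single position: the median of the
#' x values paired with the median of the y values. With an even number of
#' clicks each component is the mean of its two middle values. Because the
#' median ignores outliers, k miss-clicks are overridden by k + 1 clicks at
#' the right position.
#'
#' @param points A data frame with columns `x` and `y` (at least one row).
#' @return A named numeric vector `c(x = , y = )`.
#' @export
#' @examples
#' frame_median(data.frame(x = c(50, 10, 10), y = c(50, 10, 10)))
frame_median <- function(points) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    stop("`points` must be a data frame with columns `x` and `y`", call. = FALSE)
  }
  if (nrow(points) == 0L) stop("cannot take the median of zero points", call. = FALSE)
  c(x = stats::median(points$x), y = stats::median(points$y))
}

#' Construct a trajectory from per-frame positions
#'
#' A trajectory is the dense (or, when loaded from a sparse file, keyframe)
#' sequence of anchor positions, one row per frame: a tibble with columns
#' `frame`, `x`, `y`, sorted by frame.
#'
#' @param frame Integer frame numbers, 1-based, strictly increasing after
#'   sorting (duplicates are an error).
#' @param x,y Pixel coordinates.
#' @return A `trajectory` tibble.
#' @export
trajectory <- function(frame = integer(), x = double(), y = double()) {
  stopifnot(length(frame) == length(x), length(frame) == length(y))
  if (anyDuplicated(frame)) stop("duplicate frame numbers in trajectory", call. = FALSE)
  ord <- order(frame)
  new_trajectory(tibble::tibble(
    frame = as.integer(frame[ord]), x = as.double(x[ord]), y = as.double(y[ord])
  ))
}

new_trajectory <- function(df) {
  structure(df, class = c("trajectory", class(tibble::tibble())))
}

# piecewise-linear evaluation through keyframes, one row per integer frame
# from the first to the last keyframe; weights computed explicitly so the
# keyframe positions are reproduced with zero error.
interpolate_keyframes <- function(key) {
  key <- key[order(key$frame), , drop = FALSE]
  frames <- seq.int(key$frame[1L], key$frame[nrow(key)])
  if (nrow(key) == 1L) {
    return(trajectory(frames, key$x, key$y))
  }
  seg <- findInterval(frames, key$frame, rightmost.closed = TRUE)
  fa <- key$frame[seg]; fb <- key$frame[seg + 1L]
  w <- (frames - fa) / (fb - fa)
  x <- key$x[seg] * (1 - w) + key$x[seg + 1L] * w
  y <- key$y[seg] * (1 - w) + key$y[seg + 1L] * w
  at_key <- frames %in% key$frame
  x[at_key] <- key$x[match(frames[at_key], key$frame)]
  y[at_key] <- key$y[match(frames[at_key], key$frame)]
  trajectory(frames, x, y)
}

#' Interpolate a dense trajectory from clicks
#'
#' First fuses each labeled frame's clicks into one keyframe position by
#' [frame_median()], then fills every frame between the first and the last
#' labeled frame by piecewise-linear interpolation through all keyframes.
#' No extrapolation happens beyond either end; a single labeled frame
#' yields a one-row trajectory. A `trajectory` may also be passed, in which
#' case its rows are treated as keyframes (re-interpolating an already
#' dense trajectory is the identity).
#'
#' @param clicks A [click_set()] with at least one click, or a
#'   [trajectory()] whose rows act as keyframes.
#' @return A [trajectory()] covering every frame from the first to the last
#'   labeled frame.
#' @export
#' @examples
#' click_set() |>
#'   add_click(1, 0, 0) |>
#'   add_click(3, 2, 2) |>
#'   interpolate()
interpolate <- function(clicks) {
  if (inherits(clicks, "trajectory")) {
    if (nrow(clicks) == 0L) stop("cannot interpolate an empty trajectory", call. = FALSE)
    return(interpolate_keyframes(clicks))
  }
  stopifnot(inherits(clicks, "click_set"))
  if (nrow(clicks) == 0L) stop("cannot interpolate an empty click set", call. = FALSE)
  key <- clicks |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      x = stats::median(.data$x), y = stats::median(.data$y), .groups = "drop"
    )
  interpolate_keyframes(key)
}

# shortest decimal representation that parses back to the same double;
# integers get a trailing ".0" to match the trajectory file dialect.
format_coord <- function(v) {
  vapply(v, function(val) {
    s <- NULL
    for (d in 1:17) {
      s <- format(val, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == val) break
    }
    if (!grepl(".", s, fixed = TRUE)) s <- paste0(s, ".0")
    s
  }, character(1))
}

#' Write a trajectory as plain text
#'
#' One line per frame in ascending frame order, in the interchange format
#' `"x-position, y-position, frame number,"` (fields separated by a comma
#' and a space, with a trailing comma). Coordinates are printed as the
#' shortest decimal that parses back to the stored double, so a save/load
#' round trip is exact; `strict_integer = TRUE` rounds coordinates to
#' integers for byte-parity with producers that write integer positions.
#'
#' @param traj A non-empty [trajectory()].
#' @param path Output file path.
#' @param strict_integer Round coordinates to whole pixels before writing.
#' @return `path`, invisibly.
#' @export
save_trajectory <- function(traj, path, strict_integer = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) == 0L) stop("cannot save an empty trajectory", call. = FALSE)
  x <- traj$x; y <- traj$y
  if (strict_integer) { x <- round(x); y <- round(y) }
  lines <- paste0(format_coord(x), ", ", format_coord(y), ", ", traj$frame, ",")
  con <- file(path, open = "wb")  # binary so line endings are stable across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trajectory text file
#'
#' Parses the plain-text interchange format written by [save_trajectory()]
#' (and by the original annotation tool): one record per line, `x, y,
#' frame,` with an optional trailing comma and arbitrary surrounding
#' whitespace; blank lines are ignored. Integer and fractional coordinates
#' both parse. Loading replaces whatever points the caller held before —
#' the returned object is a fresh trajectory, never merged state.
#'
#' @param path Path to the text file.
#' @return A [trajectory()] sorted by frame. Frames need not be contiguous:
#'   a sparse file is a set of keyframes ready for [interpolate()].
#' @export
load_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  raw_lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw_lines)))
  if (length(keep) == 0L) stop("trajectory file is empty: ", path, call. = FALSE)
  parse_one <- function(line, lineno) {
    fields <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) != 3L) {
      stop(sprintf("line %d of '%s': expected 'x, y, frame,' but got: %s",
                   lineno, path, trimws(line)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("line %d of '%s': non-numeric field in: %s",
                   lineno, path, trimws(line)), call. = FALSE)
    }
    if (vals[3] < 1 || vals[3] != floor(vals[3])) {
      stop(sprintf("line %d of '%s': frame number must be a whole number >= 1",
                   lineno, path), call. = FALSE)
    }
    vals
  }
  parsed <- t(vapply(seq_along(keep),
                     function(i) parse_one(raw_lines[keep[i]], keep[i]),
                     numeric(3)))
  frames <- as.integer(parsed[, 3])
  if (anyDuplicated(frames)) {
    stop("duplicate frame number(s) in '", path, "': ",
         paste(unique(frames[duplicated(frames)]), collapse = ", "), call. = FALSE)
  }
  trajectory(frames, parsed[, 1], parsed[, 2])
}
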