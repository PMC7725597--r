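#' Describe a synthetic moving target
#'
#' Defines the ground truth for a synthetic test movie: a bright disc that
#' follows a piecewise-constant-velocity path through the given waypoints —
#' the motion model under which linear interpolation of clicks is exact. A
#' single waypoint gives a stationary spot (velocity constantly zero).
#'
#' @param waypoints A data frame with columns `frame`, `x`, `y`; frames
#'   strictly increasing.
#' @param spot_radius Disc radius in pixels.
#' @param spot_intensity Disc gray value, 0..255.
#' @param background_noise_sigma Standard deviation of the Gaussian
#'   background noise, in intensity units (0 = clean background).
#' @param seed Integer seed; all randomness in [generate_movie()] flows
#'   from it, with no global RNG state left behind.
#' @return A `motion_spec` object.
#' @export
motion_spec <- function(waypoints, spot_radius = 5, spot_intensity = 255,
                        background_noise_sigma = 0, seed = 1L) {
  stopifnot(is.data.frame(waypoints),
            all(c("frame", "x", "y") %in% names(waypoints)),
            nrow(waypoints) >= 1L)
  if (is.unsorted(waypoints$frame, strictly = TRUE)) {
    stop("waypoint frames must be strictly increasing", call. = FALSE)
  }
  stopifnot(spot_radius > 0, spot_intensity >= 0, spot_intensity <= 255,
            background_noise_sigma >= 0)
  structure(
    list(waypoints = tibble::as_tibble(waypoints[c("frame", "x", "y")]),
         spot_radius = spot_radius, spot_intensity = spot_intensity,
         background_noise_sigma = background_noise_sigma,
         seed = as.integer(seed)),
    class = "motion_spec"
  )
}

#' Generate a synthetic movie with known ground truth
#'
#' Renders the moving disc described by a [motion_spec()] onto a noisy
#' background and returns both the movie and the exact ground-truth
#' trajectory (the piecewise-linear interpolation of the waypoints), so
#' every downstream stage can be checked against truth. The same spec and
#' seed always produce byte-identical movies.
#'
#' @param spec A [motion_spec()]; waypoint frames must lie in
#'   `1..n_frames` and the spot must fit inside the frame.
#' @param n_frames,height,width Movie dimensions.
#' @return A list with elements `movie` (a [movie()]) and `truth`
#'   (a [trajectory()] covering the waypoint span).
#' @export
generate_movie <- function(spec, n_frames, height, width) {
  stopifnot(inherits(spec, "motion_spec"), n_frames >= 1,
            height >= 1, width >= 1)
  wp <- spec$waypoints
  if (min(wp$frame) < 1 || max(wp$frame) > n_frames) {
    stop("waypoint frames must lie within 1..n_frames", call. = FALSE)
  }
  truth <- interpolate_keyframes(wp)
  if (any(truth$x - spec$spot_radius < 0) || any(truth$x + spec$spot_radius > width) ||
      any(truth$y - spec$spot_radius < 0) || any(truth$y + spec$spot_radius > height)) {
    stop("spot does not fit inside the frame along the whole path", call. = FALSE)
  }
  spot_rgb <- rep(as.integer(round(spec$spot_intensity)), 3L)
  frames <- withr::with_seed(spec$seed, {
    lapply(seq_len(n_frames), function(f) {
      bg <- if (spec$background_noise_sigma > 0) {
        pmin(255, pmax(0, round(stats::rnorm(height * width,
                                             sd = spec$background_noise_sigma))))
      } else {
        rep(0L, height * width)
      }
      fr <- array(as.integer(bg), dim = c(height, width, 1L))
      fr <- array(rep(fr, 3L), dim = c(height, width, 3L))
      storage.mode(fr) <- "integer"
      hit <- which(truth$frame == f)
      if (length(hit) == 1L) {
        fr <- paint_primitive(
          fr, circ_prim(truth$x[hit], truth$y[hit], spec$spot_radius,
                        fill = TRUE, stroke = 1),
          spot_rgb)
      }
      fr
    })
  })
  list(movie = movie(frames, source = "synthetic"), truth = truth)
}

#' Simulate user clicks on a known trajectory
#'
#' Emulates the labeling step: on each labeled frame one click is placed at
#' the true position plus independent Gaussian jitter per axis; with the
#' given probability a far-off miss-click is added too, followed by
#' `miss_click_extra` corrective clicks at the true position — the
#' override recipe in which k miss-clicks are outvoted by k + 1 correct
#' clicks under the median.
#'
#' @param truth A [trajectory()] with the ground-truth positions.
#' @param labeled_frames Frames to click on; must all appear in `truth`.
#' @param jitter_sigma Per-axis click jitter SD in pixels.
#' @param miss_click_rate Probability of a miss-click on a labeled frame.
#' @param miss_click_extra Corrective clicks added alongside a miss-click.
#' @param seed Integer seed; identical seeds give identical click sets.
#' @param miss_distance Minimum distance of a miss-click from the true
#'   position, in pixels, so it is an unambiguous outlier.
#' @return A [click_set()].
#' @export
generate_clicks <- function(truth, labeled_frames, jitter_sigma = 0,
                            miss_click_rate = 0, miss_click_extra = 2,
                            seed = 1L, miss_distance = 50) {
  stopifnot(inherits(truth, "trajectory"),
            jitter_sigma >= 0, miss_click_rate >= 0, miss_click_rate <= 1,
            miss_click_extra >= 0, miss_distance > 0)
  missing_frames <- setdiff(labeled_frames, truth$frame)
  if (length(missing_frames) > 0L) {
    stop("labeled frame(s) absent from truth: ",
         paste(missing_frames, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    clicks <- click_set()
    for (f in labeled_frames) {
      i <- match(f, truth$frame)
      tx <- truth$x[i]; ty <- truth$y[i]
      cx <- max(0, tx + stats::rnorm(1, sd = jitter_sigma))
      cy <- max(0, ty + stats::rnorm(1, sd = jitter_sigma))
      clicks <- add_click(clicks, f, cx, cy)
      if (stats::runif(1) < miss_click_rate) {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- miss_distance * stats::runif(1, 1, 2)
        ox <- d * cos(ang); oy <- d * sin(ang)
        # reflect offsets that would leave the image so the miss-click stays
        # a valid click while keeping its distance from the truth
        if (tx + ox < 0) ox <- -ox
        if (ty + oy < 0) oy <- -oy
        clicks <- add_click(clicks, f, tx + ox, ty + oy)
        for (k in seq_len(miss_click_extra)) clicks <- add_click(clicks, f, tx, ty)
      }
    }
    clicks
  })
}
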