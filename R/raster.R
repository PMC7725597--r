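# Integer rasterization of overlay primitives into 8-bit RGB frames.
#
# Coordinate convention: continuous coordinates are 0-based with x rightward
# and y downward, origin at the top-left pixel's corner. The pixel stored at
# array position [row r, col c] (1-based) covers x in [c-1, c], y in [r-1, r]
# and has its center at (c - 0.5, r - 0.5). A pixel is painted iff its center
# lies inside a filled primitive, or within stroke/2 of a stroked path. No
# antialiasing: output is byte-identical across runs and platforms.

set_pixels <- function(frame, rows, cols, rgb) {
  if (length(rows) == 0L) return(frame)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  keep <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
  rows <- rows[keep]; cols <- cols[keep]
  if (length(rows) == 0L) return(frame)
  for (k in 1:3) frame[cbind(rows, cols, k)] <- rgb[k]
  frame
}

# even-odd scanline fill of a closed polygon given by vertex vectors
fill_polygon_pixels <- function(xs, ys, h, w) {
  n <- length(xs)
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  r_min <- max(1L, as.integer(ceiling(min(ys) + 0.5)))
  r_max <- min(h, as.integer(floor(max(ys) + 0.5)))
  if (r_min > r_max) return(list(rows = integer(), cols = integer()))
  out_r <- vector("list", r_max - r_min + 1L)
  out_c <- vector("list", r_max - r_min + 1L)
  for (r in r_min:r_max) {
    yc <- r - 0.5
    # half-open rule: an edge contributes iff one endpoint is <= yc and the
    # other is > yc, so vertices on a scanline are counted exactly once
    hit <- (ys <= yc & y2 > yc) | (y2 <= yc & ys > yc)
    if (!any(hit)) next
    cx <- xs[hit] + (yc - ys[hit]) * (x2[hit] - xs[hit]) / (y2[hit] - ys[hit])
    cx <- sort(cx)
    cols <- integer(0)
    for (i in seq(1L, length(cx) - 1L, by = 2L)) {
      c_lo <- max(1L, as.integer(ceiling(cx[i] + 0.5)))
      c_hi <- min(w, as.integer(floor(cx[i + 1L] + 0.5)))
      if (c_lo <= c_hi) cols <- c(cols, c_lo:c_hi)
    }
    idx <- r - r_min + 1L
    out_c[[idx]] <- cols
    out_r[[idx]] <- rep.int(r, length(cols))
  }
  list(rows = unlist(out_r), cols = unlist(out_c))
}

# pixels whose centers are within width/2 of segment (x1,y1)-(x2,y2)
stroke_segment_pixels <- function(x1, y1, x2, y2, width, h, w) {
  half <- width / 2
  r_min <- max(1L, as.integer(ceiling(min(y1, y2) - half + 0.5)))
  r_max <- min(h, as.integer(floor(max(y1, y2) + half + 0.5)))
  c_min <- max(1L, as.integer(ceiling(min(x1, x2) - half + 0.5)))
  c_max <- min(w, as.integer(floor(max(x1, x2) + half + 0.5)))
  if (r_min > r_max || c_min > c_max) return(list(rows = integer(), cols = integer()))
  rr <- r_min:r_max; cc <- c_min:c_max
  px <- rep(cc - 0.5, times = length(rr))
  py <- rep(rr - 0.5, each = length(cc))
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d2 <- (px - x1)^2 + (py - y1)^2
  } else {
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
  }
  hit <- d2 <= half * half
  list(rows = as.integer(py[hit] + 0.5), cols = as.integer(px[hit] + 0.5))
}

circle_pixels <- function(cx, cy, r, fill, width, h, w) {
  pad <- if (fill) 0 else width / 2
  r_min <- max(1L, as.integer(ceiling(cy - r - pad + 0.5)))
  r_max <- min(h, as.integer(floor(cy + r + pad + 0.5)))
  c_min <- max(1L, as.integer(ceiling(cx - r - pad + 0.5)))
  c_max <- min(w, as.integer(floor(cx + r + pad + 0.5)))
  if (r_min > r_max || c_min > c_max) return(list(rows = integer(), cols = integer()))
  rr <- r_min:r_max; cc <- c_min:c_max
  px <- rep(cc - 0.5, times = length(rr))
  py <- rep(rr - 0.5, each = length(cc))
  d <- sqrt((px - cx)^2 + (py - cy)^2)
  hit <- if (fill) d <= r else abs(d - r) <= width / 2
  list(rows = as.integer(py[hit] + 0.5), cols = as.integer(px[hit] + 0.5))
}

paint_primitive <- function(frame, prim, rgb) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  px <- switch(
    prim$kind,
    circle = circle_pixels(prim$cx, prim$cy, prim$r, prim$fill, prim$stroke, h, w),
    polygon = if (prim$fill) {
      fill_polygon_pixels(prim$x, prim$y, h, w)
    } else {
      n <- length(prim$x)
      xs2 <- c(prim$x[-1], prim$x[1]); ys2 <- c(prim$y[-1], prim$y[1])
      acc_r <- list(); acc_c <- list()
      for (i in seq_len(n)) {
        s <- stroke_segment_pixels(prim$x[i], prim$y[i], xs2[i], ys2[i],
                                   prim$stroke, h, w)
        acc_r[[i]] <- s$rows; acc_c[[i]] <- s$cols
      }
      list(rows = unlist(acc_r), cols = unlist(acc_c))
    },
    polyline = {
      n <- length(prim$x)
      acc_r <- list(); acc_c <- list()
      for (i in seq_len(n - 1L)) {
        s <- stroke_segment_pixels(prim$x[i], prim$y[i],
                                   prim$x[i + 1L], prim$y[i + 1L],
                                   prim$stroke, h, w)
        acc_r[[i]] <- s$rows; acc_c[[i]] <- s$cols
      }
      list(rows = unlist(acc_r), cols = unlist(acc_c))
    },
    stop("unknown primitive kind: ", prim$kind)
  )
  set_pixels(frame, px$rows, px$cols, rgb)
}

paint_geometry <- function(frame, geom, rgb) {
  for (prim in geom$primitives) frame <- paint_primitive(frame, prim, rgb)
  frame
}
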