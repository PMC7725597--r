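#' Construct a movie from frames
#'
#' A movie is an ordered stack of same-sized 8-bit RGB frames. Frames are
#' stored as `height x width x 3` integer arrays with values in 0..255 and
#' are indexed 1-based and contiguously (1..n_frames), matching ImageJ
#' frame numbering.
#'
#' @param frames A list of `H x W x 3` numeric arrays (values 0..255), or
#'   `H x W` matrices which are promoted to RGB by channel replication.
#' @param source Provenance label, a file path or `"in-memory"`.
#' @return A `movie` object with fields `frames`, `height`, `width`,
#'   `n_frames`, `source`.
#' @export
movie <- function(frames, source = "in-memory") {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("a movie needs at least one frame", call. = FALSE)
  }
  frames <- lapply(frames, promote_frame)
  dims <- vapply(frames, dim, integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same height x width", call. = FALSE)
  }
  structure(
    list(frames = frames, height = dims[1, 1], width = dims[2, 1],
         n_frames = length(frames), source = source),
    class = "movie"
  )
}

# normalize one frame to an H x W x 3 integer array in 0..255
promote_frame <- function(fr) {
  if (is.matrix(fr)) fr <- array(rep(fr, 3L), dim = c(dim(fr), 3L))
  if (!is.array(fr) || length(dim(fr)) != 3L) {
    stop("each frame must be an H x W matrix or H x W x 3 array", call. = FALSE)
  }
  if (dim(fr)[3] == 1L) fr <- array(rep(fr, 3L), dim = c(dim(fr)[1:2], 3L))
  if (dim(fr)[3] != 3L) {
    stop("frames must have 1 or 3 channels; convert to an RGB stack first",
         call. = FALSE)
  }
  if (any(!is.finite(fr)) || min(fr) < 0 || max(fr) > 255) {
    stop("pixel values must lie in 0..255", call. = FALSE)
  }
  storage.mode(fr) <- "integer"
  fr
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("<movie> %d frame(s), %d x %d px, 8-bit RGB (source: %s)\n",
              x$n_frames, x$width, x$height, x$source))
  invisible(x)
}

# natural numeric order of file names: digit runs compare as numbers, so
# t2 sorts before t10 and zero-padding does not matter
natural_order <- function(names) {
  base <- tools::file_path_sans_ext(basename(names))
  parts <- lapply(base, function(s) {
    regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
  })
  width <- max(lengths(parts))
  keys <- vapply(parts, function(p) {
    padded <- vapply(p, function(tok) {
      if (grepl("^[0-9]+$", tok)) sprintf("%020d", as.numeric(tok)) else tok
    }, character(1))
    paste0(paste(padded, collapse = ""), strrep(" ", width))
  }, character(1))
  order(keys, names)
}

read_tiff_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(pg) {
    bits <- attr(pg, "bits.per.sample")
    if (!is.null(bits) && any(bits > 8L)) {
      stop("only 8-bit samples are supported; convert to an 8-bit RGB stack first",
           call. = FALSE)
    }
    d <- dim(pg)
    # readTIFF normalizes samples to [0, 1]; map back to 0..255 bytes and
    # drop the file metadata attributes so frames compare by pixels alone
    pg <- array(as.integer(round(pg * 255)), dim = d)
    if (length(d) == 3L && d[3] == 4L) {
      if (all(pg[, , 4] == 255L)) pg <- pg[, , 1:3, drop = FALSE]
      else stop("RGBA input with non-trivial alpha; convert to an RGB stack first",
                call. = FALSE)
    }
    if (length(d) == 3L && d[3] > 4L) {
      stop("multi-channel input (", d[3],
           " channels); convert to an RGB stack first", call. = FALSE)
    }
    pg
  })
}

#' Load a movie from disk
#'
#' Accepts either a multipage TIFF stack (each page becomes one frame, in
#' page order) or a folder of single-frame `.tif`/`.tiff` files named in
#' increasing order, e.g. `t0001.tif, t0002.tif, t0003.tif`. Folder
#' contents are ordered by natural numeric sort of their names, so `t2`
#' precedes `t10` regardless of zero-padding. Grayscale input is promoted
#' to RGB by channel replication; genuinely multi-channel or >8-bit input
#' is rejected with a prompt to convert to an RGB stack first. Frames are
#' re-indexed 1..n.
#'
#' @param path Path to a `.tif`/`.tiff` file or to a directory containing
#'   at least one such file.
#' @return A [movie()].
#' @export
load_movie <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) {
      stop("directory contains no .tif/.tiff files: ", path, call. = FALSE)
    }
    files <- files[natural_order(files)]
    frames <- unlist(lapply(files, read_tiff_frames), recursive = FALSE)
  } else {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      stop("expected a .tif/.tiff file or a directory: ", path, call. = FALSE)
    }
    frames <- read_tiff_frames(path)
  }
  movie(frames, source = path)
}

#' Save a movie as a multipage TIFF
#'
#' Writes one uncompressed 8-bit RGB page per frame; reloading the file
#' with [load_movie()] reproduces the pixel data bit-exactly.
#'
#' @param movie A [movie()].
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
save_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie"))
  imgs <- lapply(movie$frames, function(fr) {
    a <- fr / 255
    storage.mode(a) <- "double"
    a
  })
  ok <- tiff::writeTIFF(imgs, path, bits.per.sample = 8L, compression = "none")
  if (ok != movie$n_frames) stop("failed to write all frames to ", path, call. = FALSE)
  invisible(path)
}
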