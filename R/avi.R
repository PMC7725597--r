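# Minimal uncompressed AVI (RIFF) writer: one BI_RGB 24-bit DIB video
# stream, bottom-up BGR rows padded to 4 bytes, plus an idx1 index so
# stock players can seek. Only container-level behavior (frame count,
# frame rate/duration) is contractual; AVI is not the bit-exact path —
# use save_movie_tiff() for lossless round trips.

u32 <- function(...) writeBin(as.integer(c(...)), raw(), size = 4L, endian = "little")
u16 <- function(...) writeBin(as.integer(c(...)), raw(), size = 2L, endian = "little")
fourcc <- function(s) charToRaw(s)

riff_chunk <- function(id, data) {
  out <- c(fourcc(id), u32(length(data)), data)
  if (length(data) %% 2L == 1L) out <- c(out, as.raw(0L))
  out
}
riff_list <- function(type, content) {
  c(fourcc("LIST"), u32(4L + length(content)), fourcc(type), content)
}

# one frame as a bottom-up, 4-byte-aligned BGR pixel block
frame_to_dib <- function(fr, stride) {
  h <- dim(fr)[1]; w <- dim(fr)[2]
  block <- matrix(as.raw(0L), nrow = stride, ncol = h)
  flipped <- fr[h:1, , , drop = FALSE]          # bottom row first
  cols <- seq_len(w)
  block[(cols - 1L) * 3L + 1L, ] <- as.raw(t(flipped[, , 3]))  # B
  block[(cols - 1L) * 3L + 2L, ] <- as.raw(t(flipped[, , 2]))  # G
  block[(cols - 1L) * 3L + 3L, ] <- as.raw(t(flipped[, , 1]))  # R
  as.vector(block)
}

#' Save a movie as an uncompressed AVI
#'
#' Writes one 24-bit uncompressed video frame per movie frame at the given
#' frame rate, so an n-frame movie at `fps` plays for `n / fps` seconds.
#' The frame count and frame rate are preserved exactly; pixel fidelity
#' holds for this writer but is not contractual for AVI in general — use
#' [save_movie_tiff()] when bit-exact round trips matter.
#'
#' @param movie A [movie()].
#' @param path Destination `.avi` path.
#' @param fps Playback rate in frames per second, > 0.
#' @return `path`, invisibly.
#' @export
save_movie_avi <- function(movie, path, fps = 10) {
  stopifnot(inherits(movie, "movie"))
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single number > 0", call. = FALSE)
  }
  h <- movie$height; w <- movie$width; n <- movie$n_frames
  stride <- ((3L * w + 3L) %/% 4L) * 4L
  dib_size <- stride * h
  scale <- 1000L
  rate <- as.integer(round(fps * 1000))

  avih <- riff_chunk("avih", c(
    u32(round(1e6 * scale / rate)),        # microseconds per frame
    u32(min(2^31 - 1, dib_size * ceiling(fps))),  # max bytes per second
    u32(0L),                               # padding granularity
    u32(16L),                              # AVIF_HASINDEX
    u32(n), u32(0L), u32(1L),              # total frames, initial, streams
    u32(dib_size),                         # suggested buffer size
    u32(w), u32(h),
    u32(0L, 0L, 0L, 0L)                    # reserved
  ))
  strh <- riff_chunk("strh", c(
    fourcc("vids"), fourcc("DIB "),
    u32(0L), u16(0L), u16(0L), u32(0L),    # flags, priority, language, initial
    u32(scale), u32(rate),
    u32(0L), u32(n),                       # start, length (frames)
    u32(dib_size), u32(-1L), u32(0L),      # buffer, quality, sample size
    u16(0L, 0L, w, h)                      # rcFrame
  ))
  strf <- riff_chunk("strf", c(
    u32(40L), u32(w), u32(h),              # BITMAPINFOHEADER, bottom-up
    u16(1L), u16(24L),
    u32(0L),                               # BI_RGB
    u32(dib_size), u32(0L, 0L, 0L, 0L)
  ))
  hdrl <- riff_list("hdrl", c(avih, riff_list("strl", c(strh, strf))))

  movi_chunks <- lapply(movie$frames, function(fr) {
    riff_chunk("00db", frame_to_dib(fr, stride))
  })
  movi <- riff_list("movi", do.call(c, movi_chunks))

  chunk_len <- 8L + dib_size
  offsets <- 4L + (seq_len(n) - 1L) * chunk_len
  idx_entries <- do.call(c, lapply(seq_len(n), function(i) {
    c(fourcc("00db"), u32(16L), u32(offsets[i]), u32(dib_size))
  }))
  idx1 <- riff_chunk("idx1", idx_entries)

  body <- c(fourcc("AVI "), hdrl, movi, idx1)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write AVI to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}
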