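# Independent oracles and small fixture builders shared across the suite.

# sort-and-middle median, written independently of stats::median
oracle_median <- function(points) {
  mid <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) %/% 2L] else (v[n %/% 2L] + v[n %/% 2L + 1L]) / 2
  }
  c(x = mid(points$x), y = mid(points$y))
}

# piecewise-linear evaluation via stats::approx (independent of the
# package's explicit blend-weight implementation)
oracle_interp <- function(key_frame, key_x, key_y, at) {
  ord <- order(key_frame)
  list(
    x = stats::approx(key_frame[ord], key_x[ord], xout = at)$y,
    y = stats::approx(key_frame[ord], key_y[ord], xout = at)$y
  )
}

rand_frames <- function(n, h, w) {
  lapply(seq_len(n), function(i) {
    array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  })
}

rand_trajectory <- function(max_len = 40) {
  start <- sample(1:50, 1)
  n <- sample(1:max_len, 1)
  trajectory(seq.int(start, start + n - 1L),
             x = round(runif(n, 0, 500), sample(0:6, 1)),
             y = round(runif(n, 0, 500), sample(0:6, 1)))
}

# page count by an independent TIFF reader (python tifffile)
tiff_pages_python <- function(path) {
  out <- system2("python",
                 c("-c",
                   shQuote("import tifffile,sys; print(len(tifffile.TiffFile(sys.argv[1]).pages))"),
                   shQuote(path)),
                 stdout = TRUE, stderr = FALSE)
  as.integer(out[length(out)])
}

# independent RIFF/AVI container scan: counts video data chunks and reads
# the stream header's rate/scale/length fields directly from the bytes
scan_avi <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  u32at <- function(off) sum(as.numeric(bytes[off + 1:4]) * 256^(0:3))
  stopifnot(rawToChar(bytes[1:4]) == "RIFF", rawToChar(bytes[9:12]) == "AVI ")
  env <- new.env()
  env$frames <- 0L
  env$strh <- NA_integer_
  walk <- function(start, end) {
    pos <- start
    while (pos + 8 <= end) {
      id <- rawToChar(bytes[pos + 1:4])
      size <- u32at(pos + 4)
      if (id == "LIST") {
        walk(pos + 12, pos + 8 + size)
      } else {
        if (grepl("^..d[bc]$", id)) env$frames <- env$frames + 1L
        if (id == "strh") env$strh <- pos + 8
      }
      pos <- pos + 8 + size + (size %% 2)
    }
  }
  walk(12, 8 + u32at(4))
  list(frames = env$frames,
       fps = u32at(env$strh + 24) / u32at(env$strh + 20),
       declared_length = u32at(env$strh + 32))
}
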