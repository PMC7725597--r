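blank_movie <- function(n = 1L, h = 40L, w = 40L) {
  movie(lapply(seq_len(n), function(i) array(0L, dim = c(h, w, 3))))
}

# inject one raw geometry as a symbol item (test-only access to internals)
inject_item <- function(ov, frame, geom, color = "red") {
  annotrack:::append_items(ov, frame, "symbol", color, list(geom))
}

rect_geom <- function(x0, y0, x1, y1) {
  annotrack:::new_symbol_geometry(list(
    annotrack:::poly_prim(c(x0, x1, x1, x0), c(y0, y0, y1, y1),
                          fill = TRUE, stroke = 1)))
}

changed_mask <- function(a, b) {
  apply(a != b, c(1, 2), any)
}

test_that("click markers appear one per click on the click's frame", {
  cs <- click_set() |> add_click(2, 10, 10)
  ov <- overlay() |> add_click_markers(cs)
  expect_equal(nrow(ov$items), 1L)
  expect_equal(ov$items$frame, 2L)
  expect_equal(ov$items$color, "yellow")

  cs <- cs |> add_click(2, 11, 10) |> add_click(2, 12, 10)
  ov <- overlay() |> add_click_markers(cs)
  expect_equal(nrow(ov$items), 3L)

  expect_identical(add_click_markers(overlay(), click_set())$items,
                   overlay()$items)
})

test_that("trajectory markers cover each entry and replace older ones", {
  tr <- trajectory(3:7, x = seq(10, 30, 5), y = rep(20, 5))
  ov <- overlay() |> add_trajectory_markers(tr)
  expect_equal(sort(ov$items$frame), 3:7)
  expect_true(all(ov$items$color == "brown"))

  # re-interpolation: only the newest trajectory remains visible
  tr2 <- trajectory(3:5, x = c(1, 2, 3), y = c(1, 2, 3))
  ov2 <- add_trajectory_markers(ov, tr2)
  expect_equal(sum(ov2$items$role == "traj_marker"), 3L)

  expect_identical(add_trajectory_markers(overlay(), trajectory())$items,
                   overlay()$items)
})

test_that("symbols are drawn once per trajectory frame and stack on redraw", {
  spec <- symbol_spec("DELTA", head_length = 6, length = 15, thickness = 2)
  tr1 <- trajectory(4L, 20, 20)
  ov <- overlay() |> draw_symbols(tr1, spec)
  expect_equal(ov$items$frame, 4L)

  tr <- trajectory(2:6, x = seq(5, 25, 5), y = rep(15, 5))
  ov <- overlay() |> draw_symbols(tr, spec)
  expect_equal(sort(ov$items$frame), 2:6)

  ov2 <- draw_symbols(ov, tr, spec)
  expect_equal(nrow(ov2$items), 2L * nrow(ov$items))

  expect_error(draw_symbols(overlay(), trajectory(), spec), "empty")
})

test_that("remove_symbols strips symbols but keeps markers, and redraw matches", {
  tr <- trajectory(1:3, x = c(10, 15, 20), y = c(10, 10, 10))
  cs <- click_set() |> add_click(1, 10, 10) |> add_click(3, 20, 10)
  spec <- symbol_spec("POINTY", head_length = 5, length = 12, thickness = 2)
  ov <- overlay() |> add_click_markers(cs) |>
    add_trajectory_markers(tr) |> draw_symbols(tr, spec)
  stripped <- remove_symbols(ov)
  expect_setequal(unique(stripped$items$role), c("click_marker", "traj_marker"))
  expect_identical(remove_symbols(stripped)$items, stripped$items)

  # draw -> remove -> draw equals a single draw, item for item
  again <- draw_symbols(stripped, tr, spec)
  expect_identical(again$items, ov$items)
})

test_that("rasterizing an empty overlay copies the movie pixel-identically", {
  m <- blank_movie(2)
  out <- rasterize(overlay(), m)
  expect_identical(out$frames, m$frames)
})

test_that("a filled axis-aligned 10x4 rectangle paints exactly 40 pixels", {
  m <- blank_movie()
  ov <- inject_item(overlay(), 1L, rect_geom(5, 8, 15, 12))
  out <- rasterize(ov, m)
  changed <- changed_mask(out$frames[[1]], m$frames[[1]])
  expect_equal(sum(changed), 40L)
  # pixel-center convention: rows 9..12, cols 6..15 (1-based)
  expect_true(all(changed[9:12, 6:15]))
  # painted in the spec color
  expect_true(all(out$frames[[1]][, , 1][changed] == 255L))
  expect_true(all(out$frames[[1]][, , 2][changed] == 0L))
})

test_that("off-frame geometry is clipped, matching an enlarged-canvas oracle", {
  withr::local_seed(31)
  for (i in 1:10) {
    h <- 24L; w <- 24L; pad <- 30L
    geom <- rect_geom(runif(1, -15, 20), runif(1, -15, 20),
                      runif(1, 10, 45), runif(1, 10, 45))
    small <- rasterize(inject_item(overlay(), 1L, geom), blank_movie(1, h, w))
    # oracle: paint on a larger canvas with the geometry shifted by the pad,
    # then crop the corresponding window
    shifted <- geom
    shifted$primitives[[1]]$x <- shifted$primitives[[1]]$x + pad
    shifted$primitives[[1]]$y <- shifted$primitives[[1]]$y + pad
    big <- rasterize(inject_item(overlay(), 1L, shifted),
                     blank_movie(1, h + 2L * pad, w + 2L * pad))
    crop <- big$frames[[1]][pad + seq_len(h), pad + seq_len(w), , drop = FALSE]
    expect_identical(small$frames[[1]], crop)
  }
})

test_that("items on frames beyond the movie are an error", {
  ov <- inject_item(overlay(), 5L, rect_geom(1, 1, 3, 3))
  expect_error(rasterize(ov, blank_movie(2)), "frame")
})

test_that("rasterization never mutates the input and is byte-deterministic", {
  withr::local_seed(32)
  m <- movie(rand_frames(2, 32, 32))
  before <- m$frames
  tr <- trajectory(1:2, x = c(10, 20), y = c(12, 18))
  ov <- overlay() |> draw_symbols(tr, symbol_spec("THICK", head_length = 7,
                                                  length = 18, thickness = 3,
                                                  color = "cyan", angle = 30))
  a <- rasterize(ov, m)
  b <- rasterize(ov, m)
  expect_identical(m$frames, before)
  expect_identical(a$frames, b$frames)
  expect_identical(serialize(a$frames, NULL), serialize(b$frames, NULL))
})

test_that("changed pixels stay inside the dilated item bounding boxes", {
  withr::local_seed(33)
  m <- blank_movie(1, 48, 48)
  for (i in 1:10) {
    style <- sample(symbol_styles(), 1)
    spec <- symbol_spec(style, head_length = runif(1, 4, 10),
                        length = runif(1, 0, 24), thickness = runif(1, 1, 4),
                        filled = sample(c(TRUE, FALSE), 1),
                        angle = runif(1, 0, 360))
    tr <- trajectory(1L, runif(1, 10, 38), runif(1, 10, 38))
    ov <- overlay() |> draw_symbols(tr, spec)
    out <- rasterize(ov, m)
    changed <- which(changed_mask(out$frames[[1]], m$frames[[1]]), arr.ind = TRUE)
    if (nrow(changed) == 0L) next
    bb <- annotrack:::geometry_bbox(ov$items$geom[[1]])
    centers_x <- changed[, 2] - 0.5
    centers_y <- changed[, 1] - 0.5
    expect_true(all(centers_x >= bb[1] - 0.5 & centers_x <= bb[3] + 0.5))
    expect_true(all(centers_y >= bb[2] - 0.5 & centers_y <= bb[4] + 0.5))
  }
})

test_that("flatten burns symbols only by default and empties the overlay", {
  m <- blank_movie()
  tr <- trajectory(1L, 20, 20)
  ov <- overlay() |>
    add_trajectory_markers(tr) |>
    draw_symbols(tr, symbol_spec("DELTA", head_length = 6, length = 14,
                                 thickness = 2, color = "red"))
  flat <- flatten(m, ov)
  expect_equal(nrow(flat$overlay$items), 0L)
  expect_identical(flat$movie$frames,
                   rasterize(ov, m, roles = "symbol")$frames)
  # no brown marker pixels in the default flatten
  fr <- flat$movie$frames[[1]]
  brown <- fr[, , 1] == 165L & fr[, , 2] == 42L & fr[, , 3] == 42L
  expect_false(any(brown))

  withmk <- flatten(m, ov, include_markers = TRUE)
  expect_identical(withmk$movie$frames, rasterize(ov, m)$frames)

  # empty overlay: identity; flatten twice: second pass is identity
  flat0 <- flatten(m, overlay())
  expect_identical(flat0$movie$frames, m$frames)
  again <- flatten(flat$movie, flat$overlay)
  expect_identical(again$movie$frames, flat$movie$frames)
})

test_that("multi-pass annotation equals painting both item sets in order", {
  m <- blank_movie(1, 40, 40)
  specA <- symbol_spec("DELTA", head_length = 6, length = 16, thickness = 2,
                       color = "red")
  specB <- symbol_spec("CIRCLE", head_length = 5, thickness = 2,
                       color = "green", filled = FALSE)
  trA <- trajectory(1L, 12, 12)
  trB <- trajectory(1L, 25, 25)

  pass1 <- flatten(m, overlay() |> draw_symbols(trA, specA))
  pass2 <- flatten(pass1$movie, overlay() |> draw_symbols(trB, specB))

  both <- overlay() |> draw_symbols(trA, specA) |> draw_symbols(trB, specB)
  direct <- rasterize(both, m, roles = "symbol")
  expect_identical(pass2$movie$frames, direct$frames)
})
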