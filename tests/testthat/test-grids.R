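test_that("grid geometry: centers and point location follow the half-open box rule", {
  sp <- grid_spec(west = -91, north = 40, dx = 0.25, dy = 0.5,
                  nrows = 4, ncols = 6)
  expect_equal(x_centers(sp)[1], -91 + 0.125)
  expect_equal(y_centers(sp)[4], 40 - 3.5 * 0.5)

  # west/north edges belong to the pixel, east/south edges to the neighbor
  loc <- locate_points(sp, c(-91, -91 + 0.25, -91 + 6 * 0.25),
                       c(40, 40, 40))
  expect_equal(loc$col, c(1L, 2L, NA))
  loc <- locate_points(sp, rep(-90.9, 3), c(40, 40 - 0.5, 40 - 2))
  expect_equal(loc$row, c(1L, 2L, NA))

  expect_error(grid_spec(0, 0, dx = -1, nrows = 2, ncols = 2), "positive")
  expect_error(grid_spec(0, 0, dx = 1, nrows = 0, ncols = 2), "positive")
})

test_that("locate_points agrees with a brute-force point-in-box search", {
  set.seed(401)
  sp <- grid_spec(west = -100 + runif(1), north = 35 + runif(1),
                  dx = 0.07, dy = 0.11, nrows = 9, ncols = 13)
  x <- runif(300, sp$west - 0.2, sp$west + sp$ncols * sp$dx + 0.2)
  y <- runif(300, sp$north - sp$nrows * sp$dy - 0.2, sp$north + 0.2)
  loc <- locate_points(sp, x, y)
  for (i in seq_along(x)) {
    hit <- NULL
    for (r in seq_len(sp$nrows)) for (c in seq_len(sp$ncols)) {
      if (x[i] >= sp$west + (c - 1) * sp$dx && x[i] < sp$west + c * sp$dx &&
          y[i] > sp$north - r * sp$dy && y[i] <= sp$north - (r - 1) * sp$dy)
        hit <- c(r, c)
    }
    if (is.null(hit)) {
      expect_false(loc$inside[i])
    } else {
      expect_equal(c(loc$row[i], loc$col[i]), hit)
    }
  }
})

test_that("cell map: exact 12x nesting gives 144 members per cell", {
  coarse <- grid_spec(west = -90.5, north = 39, dx = 0.125,
                      nrows = 3, ncols = 2)
  fine <- refine_grid(coarse, 12)
  cm <- build_cell_map(fine, coarse)
  expect_true(all(lengths(cm$members) == 144L))
  expect_false(anyNA(cm$owner))
})

test_that("cell map: membership partitions the assigned pixels and matches brute force", {
  set.seed(402)
  for (trial in 1:3) {
    fine <- grid_spec(west = -90.5 + runif(1, -0.1, 0.1),
                      north = 39 + runif(1, -0.1, 0.1),
                      dx = 0.013, dy = 0.017, nrows = 20, ncols = 24)
    coarse <- grid_spec(west = -90.45, north = 38.97, dx = 0.1, dy = 0.08,
                        nrows = 3, ncols = 3)
    cm <- build_cell_map(fine, coarse)
    # partition: every assigned pixel appears in exactly one member list
    all_members <- unlist(cm$members)
    expect_equal(sort(all_members), which(!is.na(cm$owner)))
    expect_false(anyDuplicated(all_members) > 0)
    # brute force containment of each fine center
    loc <- locate_points(coarse,
                         rep(x_centers(fine), each = fine$nrows),
                         rep(y_centers(fine), times = fine$ncols))
    want <- ifelse(loc$inside, (loc$col - 1L) * coarse$nrows + loc$row,
                   NA_integer_)
    expect_equal(as.integer(cm$owner), as.integer(want))
  }
})

test_that("cell map with zero overlap warns and is empty", {
  fine <- grid_spec(west = 0, north = 0, dx = 0.01, nrows = 5, ncols = 5)
  coarse <- grid_spec(west = 50, north = 50, dx = 1, nrows = 2, ncols = 2)
  expect_warning(cm <- build_cell_map(fine, coarse), "overlap")
  expect_true(all(is.na(cm$owner)))
  expect_true(all(lengths(cm$members) == 0L))
})

test_that("point extraction is containment-based and flags the bad cases", {
  sp <- grid_spec(west = 0, north = 2, dx = 1, nrows = 2, ncols = 2)
  vals <- matrix(c(11, 21, 12, 22), 2, 2)  # [r,c]: 11 12 / 21 22
  vals[2, 2] <- NA
  f <- field2d(sp, vals)
  pts <- data.frame(
    station_id = c("center", "edge_x", "edge_y", "invalid", "outside"),
    lon = c(0.5, 1.0, 0.2, 1.5, 9),
    lat = c(1.5, 1.5, 1.0, 0.5, 9))
  got <- extract_at_points(f, pts)
  expect_equal(got$value[1], 11)         # pixel center
  expect_equal(got$value[2], 12)         # shared x edge -> right pixel
  expect_equal(got$value[3], 21)         # shared y edge -> pixel below
  expect_equal(got$flag, c("ok", "ok", "ok", "invalid_pixel",
                           "outside_domain"))
  expect_true(all(is.na(got$value[4:5])))
  # idempotent and order-independent
  sh <- sample(nrow(pts))
  expect_equal(extract_at_points(f, pts[sh, ])$value, got$value[sh])
})

test_that("random station extraction equals brute-force box search", {
  set.seed(403)
  sp <- grid_spec(west = -90.5, north = 39, dx = 0.04, dy = 0.03,
                  nrows = 15, ncols = 18)
  f <- random_field(sp)
  pts <- data.frame(lon = runif(100, sp$west, sp$west + sp$ncols * sp$dx),
                    lat = runif(100, sp$north - sp$nrows * sp$dy, sp$north))
  got <- extract_at_points(f, pts)
  for (i in 1:100) {
    r <- which(pts$lat[i] > sp$north - seq_len(sp$nrows) * sp$dy &
                 pts$lat[i] <= sp$north - (seq_len(sp$nrows) - 1) * sp$dy)
    c <- which(pts$lon[i] >= sp$west + (seq_len(sp$ncols) - 1) * sp$dx &
                 pts$lon[i] < sp$west + seq_len(sp$ncols) * sp$dx)
    expect_equal(got$value[i], f$values[r, c])
  }
})
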