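skel_world <- function(nest = 3L, ncells = 2L, seed = 500) {
  set.seed(seed)
  coarse <- grid_spec(west = -90.5, north = 39, dx = 0.125,
                      nrows = ncells, ncols = ncells)
  fine <- refine_grid(coarse, nest)
  cmap <- build_cell_map(fine, coarse)
  m <- matrix(rnorm(fine$nrows * fine$ncols, 32, 4), fine$nrows, fine$ncols)
  list(coarse = coarse, fine = fine, cmap = cmap,
       dep = departures_from_matrix(m, cmap),
       tl = random_field(coarse, mean = 28, sd = 2))
}

test_that("standardization divides by the owning cell's sigma", {
  w <- skel_world()
  dep <- standardize(w$dep, w$cmap)
  sig <- dep$cell_sigma[w$cmap$owner]
  expect_equal(dep$z, matrix(dep$d / sig, w$fine$nrows, w$fine$ncols))
  # per cell: mean 0, population sd 1
  for (cell in seq_along(w$cmap$members)) {
    zz <- dep$z[w$cmap$members[[cell]]]
    expect_equal(mean(zz), 0)
    expect_equal(sqrt(mean((zz - mean(zz))^2)), 1)
  }
  # degenerate sigma: uniform composite gives z = 0
  uni <- departures_from_matrix(matrix(5, w$fine$nrows, w$fine$ncols),
                                w$cmap)
  expect_true(all(standardize(uni, w$cmap)$z == 0))
})

test_that("constant-ratio downscaling is t_l + R*d with the single owning cell", {
  coarse <- grid_spec(west = 0, north = 1, dx = 1, nrows = 1, ncols = 1)
  fine <- refine_grid(coarse, 2)
  cmap <- build_cell_map(fine, coarse)
  dep <- departures_from_matrix(matrix(c(28, 30, 30, 32), 2, 2), cmap)
  tl <- field2d(coarse, matrix(30))
  ds <- downscale_constant_ratio(tl, dep, downscale_config(0.5), cmap)
  expect_equal(ds$t_dis$values, matrix(30 + 0.5 * c(-2, 0, 0, 2), 2, 2))
  # direct single-pixel reading: t_l 30, d 2, R 0.5 -> 31
  expect_equal(ds$t_dis$values[2, 2], 30 + 0.5 * 2)
})

test_that("zero departures and zero R both reduce to nearest-cell upsampling", {
  w <- skel_world()
  up <- matrix(w$tl$values[w$cmap$owner], w$fine$nrows, w$fine$ncols)
  zero_dep <- departures_from_matrix(
    matrix(7, w$fine$nrows, w$fine$ncols), w$cmap)
  ds0 <- downscale_constant_ratio(w$tl, zero_dep, downscale_config(0.5),
                                  w$cmap)
  expect_equal(ds0$t_dis$values, up)
  dsR0 <- downscale_constant_ratio(w$tl, w$dep, downscale_config(0),
                                   w$cmap)
  expect_equal(dsR0$t_dis$values, up)
})

test_that("downscaling is linear in R and strictly monotone in d for R > 0", {
  w <- skel_world(seed = 501)
  d1 <- downscale_constant_ratio(w$tl, w$dep, downscale_config(1), w$cmap)
  d03 <- downscale_constant_ratio(w$tl, w$dep, downscale_config(0.3), w$cmap)
  up <- matrix(w$tl$values[w$cmap$owner], w$fine$nrows, w$fine$ncols)
  expect_equal(d03$t_dis$values - up, 0.3 * (d1$t_dis$values - up))

  bumped <- w$dep; bumped$d <- w$dep$d + 0.01
  ds <- downscale_constant_ratio(w$tl, w$dep, downscale_config(0.5), w$cmap)
  dsb <- downscale_constant_ratio(w$tl, bumped, downscale_config(0.5), w$cmap)
  expect_true(all(dsb$t_dis$values > ds$t_dis$values))
})

test_that("coarse-cell means of the downscaled field reproduce t_l exactly", {
  w <- skel_world(nest = 5L, ncells = 3L, seed = 502)
  ds <- downscale_constant_ratio(w$tl, w$dep, downscale_config(0.5), w$cmap)
  for (cell in seq_along(w$cmap$members)) {
    mem <- w$cmap$members[[cell]]
    expect_equal(mean(ds$t_dis$values[mem]), w$tl$values[cell],
                 tolerance = 1e-12)
  }
})

test_that("an invalid coarse cell yields invalid fine pixels, not extrapolation", {
  w <- skel_world()
  tl <- w$tl
  tl$values[1, 1] <- NA; tl$valid[1, 1] <- FALSE
  tl <- field2d(w$coarse, tl$values, tl$valid)
  ds <- downscale_constant_ratio(tl, w$dep, downscale_config(0.5), w$cmap)
  dead <- w$cmap$members[[1]]
  expect_true(all(!ds$t_dis$valid[dead]))
  expect_true(all(ds$t_dis$valid[-dead]))
})

test_that("sigma-ratio form t_l + z*sigma_l reproduces the direct ratio form", {
  w <- skel_world(nest = 4L, ncells = 3L, seed = 503)
  dep <- standardize(w$dep, w$cmap)
  st <- neighborhood_stats(w$tl, window = 3L)
  ds <- downscale_sigma_ratio(st, dep, w$cmap)
  # Eq-1-after-Eq-2 path, assembled by hand
  zl <- dep$z * matrix(st$sigma_l[w$cmap$owner],
                       w$fine$nrows, w$fine$ncols)
  up <- matrix(w$tl$values[w$cmap$owner], w$fine$nrows, w$fine$ncols)
  expect_lt(max(abs(ds$t_dis$values - (up + zl))), 1e-9)
  # spot value: t_l 28, z * sigma_l = 2.5 -> 30.5
  one <- grid_spec(west = 0, north = 1, dx = 1, nrows = 1, ncols = 1)
  fine1 <- refine_grid(one, 2)
  cm1 <- build_cell_map(fine1, one)
  dep1 <- standardize(departures_from_matrix(
    matrix(c(30, 34, 30, 34), 2, 2), cm1), cm1)
  expect_equal(dep1$z[2, 2], 1)
  st1 <- neighborhood_stats(field2d(one, matrix(28)), window = 1L)
  st1$sigma_l[] <- 2.5
  ds1 <- downscale_sigma_ratio(st1, dep1, cm1)
  expect_equal(ds1$t_dis$values[2, 2], 28 + 1 * 2.5)
})

test_that("with sigma_l == sigma_h the sigma-ratio mode equals constant R = 1", {
  w <- skel_world(nest = 4L, seed = 504)
  st <- neighborhood_stats(w$tl, window = 1L)
  st$sigma_l <- w$dep$cell_sigma
  ds_sig <- downscale_sigma_ratio(st, w$dep, w$cmap)
  ds_r1 <- downscale_constant_ratio(w$tl, w$dep, downscale_config(1), w$cmap)
  expect_equal(ds_sig$t_dis$values, ds_r1$t_dis$values)
})

test_that("neighborhood stats use the population sd over the clipped window", {
  tl <- field2d(grid_spec(west = 0, north = 3, dx = 1, nrows = 3, ncols = 3),
                matrix(1:9, 3, 3))
  st <- neighborhood_stats(tl, window = 3L)
  v <- 1:9
  expect_equal(st$sigma_l[2, 2], sqrt(mean((v - mean(v))^2)))
  corner <- c(1, 2, 4, 5)
  expect_equal(st$sigma_l[1, 1], sqrt(mean((corner - mean(corner))^2)))
  expect_true(all(neighborhood_stats(tl, 1L)$sigma_l == 0))
  expect_error(neighborhood_stats(tl, 2L), "odd")
})

test_that("the sigma-ratio diagnostic recovers a constructed coupling and degenerates safely", {
  coarse <- grid_spec(west = -90.5, north = 39, dx = 0.125,
                      nrows = 8, ncols = 8)
  fine <- refine_grid(coarse, 12)
  cmap <- build_cell_map(fine, coarse)
  xs <- matrix(rep(seq(0, 2 * pi, length.out = fine$ncols),
                   each = fine$nrows), fine$nrows, fine$ncols)
  f <- 30 + 5 * sin(xs) + 4 * cos(t(xs))
  stk <- scene_stack(fine, list(list(label = "smooth", values = f,
                                     valid = matrix(TRUE, fine$nrows,
                                                    fine$ncols))))
  comp <- robust_composite(stk)
  bm <- vapply(cmap$members, function(mem) mean(f[mem]), numeric(1))
  tl <- field2d(coarse, matrix(20 + 0.5 * bm, coarse$nrows, coarse$ncols))
  est <- estimate_sigma_ratio(list(tl), comp, cmap, window = 5L)
  expect_lt(abs(est$global - 0.5), 0.05)
  # spatially uniform coarse field: sigma_l = 0 everywhere, ratio 0
  flat <- field2d(coarse, matrix(25, coarse$nrows, coarse$ncols))
  est0 <- estimate_sigma_ratio(list(flat), comp, cmap, window = 5L)
  expect_equal(est0$global, 0)
  expect_true(all(est0$ratio_map[is.finite(est0$ratio_map)] == 0))
})
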