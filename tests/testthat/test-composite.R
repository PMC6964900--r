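test_that("scaled-integer LST scenes decode to degC with fill masked", {
  got <- ingest_scene(matrix(c(15000, 0, 15500, 14000), 2, 2))
  expect_equal(got$values[1, 1], 26.85)          # 300 K
  expect_false(got$valid[2, 1])                  # raw 0 is fill
  expect_true(is.na(got$values[2, 1]))
  expect_warning(bad <- ingest_scene(matrix(c(-5, 15000), 1, 2)),
                 "negative Kelvin")
  expect_false(bad$valid[1, 1])

  # inverse-scaling round trip of random valid temperatures
  set.seed(407)
  tc <- runif(50, -20, 60)
  raw <- round((tc + 273.15) / 0.02)
  back <- ingest_scene(matrix(raw, 5, 10))
  expect_lt(max(abs(back$values - matrix(tc, 5, 10))), 0.01)
})

stack_of <- function(values_list, valid_list = NULL) {
  sp <- grid_spec(west = 0, north = 1, dx = 1, nrows = 1, ncols = 1)
  scene_stack(sp, lapply(seq_along(values_list), function(i)
    list(label = as.character(i), values = matrix(values_list[[i]]),
         valid = matrix(if (is.null(valid_list)) is.finite(values_list[[i]])
                        else valid_list[[i]]))))
}

test_that("upper-half compositing follows the ceil(n/2) rule", {
  expect_equal(robust_composite(stack_of(list(10, 20, 30, 40)))$t_h$values[1],
               35)                                # mean of {30, 40}
  expect_equal(robust_composite(
    stack_of(list(10, 20, 30, 40, 50)))$t_h$values[1], 40)  # top 3 of 5
  got <- robust_composite(stack_of(list(NA, NA, 26.85, 36.85)))
  expect_equal(got$t_h$values[1], 36.85)          # fills excluded, top 1 of 2
  expect_equal(got$n_valid[1], 2L)
  all_fill <- robust_composite(stack_of(list(NA, NA)))
  expect_false(all_fill$t_h$valid[1])
  expect_error(robust_composite(stack_of(list())), "empty")
})

test_that("compositing is scene-order invariant and below-median insensitive", {
  set.seed(408)
  sp <- grid_spec(west = 0, north = 1, dx = 0.1, nrows = 6, ncols = 6)
  vals <- replicate(9, matrix(rnorm(36, 30, 4), 6, 6), simplify = FALSE)
  mk <- function(vv) scene_stack(sp, lapply(vv, function(v)
    list(label = "", values = v, valid = matrix(TRUE, 6, 6))))
  base <- robust_composite(mk(vals))
  expect_equal(robust_composite(mk(rev(vals)))$t_h$values, base$t_h$values)

  # a cold outlier below every pixel's median never moves the composite
  cold <- matrix(apply(simplify2array(vals), c(1, 2), min) - 10, 6, 6)
  expect_equal(robust_composite(mk(c(vals, list(cold))))$t_h$values,
               base$t_h$values)
})

one_cell_world <- function() {
  coarse <- grid_spec(west = 0, north = 2, dx = 2, nrows = 1, ncols = 1)
  fine <- refine_grid(coarse, 2)
  build_cell_map(fine, coarse)
}

test_that("departures recenter each cell to zero mean", {
  cmap <- one_cell_world()
  dep <- departures_from_matrix(matrix(c(1, 2, 3, 4), 2, 2), cmap)
  expect_equal(dep$cell_mean[1, 1], 2.5)
  expect_equal(dep$d, matrix(c(1, 2, 3, 4), 2, 2) - 2.5)
  expect_true(all(dep$qc == "ok"))

  uni <- departures_from_matrix(matrix(7, 2, 2), cmap)
  expect_equal(uni$d, matrix(0, 2, 2))
  expect_equal(uni$cell_sigma[1, 1], 0)
})

test_that("multi-cell departures match brute force and honor the pixel threshold", {
  set.seed(409)
  coarse <- grid_spec(west = -90.5, north = 39, dx = 0.125,
                      nrows = 3, ncols = 3)
  fine <- refine_grid(coarse, 4)
  cmap <- build_cell_map(fine, coarse)
  m <- matrix(rnorm(144, 30, 5), 12, 12)
  m[sample(144, 30)] <- NA          # dropouts
  m[cmap$members[[5]][seq_len(14)]] <- NA   # cell 5: only 2 valid left
  dep <- departures_from_matrix(m, cmap)
  for (cell in seq_along(cmap$members)) {
    mem <- cmap$members[[cell]]
    v <- m[mem][is.finite(m[mem])]
    if (length(v) < 3) {
      expect_true(all(dep$qc[mem] %in% "fallback_zero"))
      expect_true(all(dep$d[mem] == 0))
      expect_true(is.na(dep$cell_mean[cell]))
    } else {
      ok <- mem[is.finite(m[mem])]
      expect_equal(dep$cell_mean[cell], mean(v))
      expect_equal(dep$cell_sigma[cell], sqrt(mean((v - mean(v))^2)))
      expect_equal(dep$d[ok], m[ok] - mean(v))
      expect_equal(mean(dep$d[ok]), 0)
      expect_true(all(dep$qc[ok] == "ok"))
    }
  }
})

test_that("departures are translation invariant and reject mismatched grids", {
  set.seed(410)
  coarse <- grid_spec(west = 0, north = 1, dx = 0.5, nrows = 2, ncols = 2)
  fine <- refine_grid(coarse, 3)
  cmap <- build_cell_map(fine, coarse)
  m <- matrix(rnorm(36, 28, 3), 6, 6)
  d1 <- departures_from_matrix(m, cmap)
  d2 <- departures_from_matrix(m + 4.2, cmap)
  expect_equal(d2$d, d1$d)

  other <- refine_grid(coarse, 2)
  stk <- scene_stack(other, list(list(label = "", values = matrix(1, 4, 4),
                                      valid = matrix(TRUE, 4, 4))))
  expect_error(compute_departures(robust_composite(stk), cmap),
               "does not match")
})

test_that("pixels outside the coarse domain are flagged unassigned", {
  coarse <- grid_spec(west = 0, north = 1, dx = 1, nrows = 1, ncols = 1)
  fine <- grid_spec(west = 0, north = 1, dx = 0.5, nrows = 2, ncols = 4)
  expect_warning(cmap <- build_cell_map(fine, coarse), NA)
  dep <- departures_from_matrix(matrix(rnorm(8, 20), 2, 4), cmap,
                                min_valid_pixels = 1L)
  expect_true(all(dep$qc[, 3:4] == "unassigned"))
  expect_true(all(dep$d[, 3:4] == 0))
})
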