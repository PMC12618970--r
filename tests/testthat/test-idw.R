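test_that("inverse-distance weights normalize and handle zeros", {
  expect_equal(idw_weights(c(1, 1), power = 2), c(0.5, 0.5))
  expect_equal(idw_weights(c(1, 2), power = 2), c(0.8, 0.2))
  expect_equal(idw_weights(c(0, 5), power = 2), c(1, 0))
  expect_equal(idw_weights(c(0, 0, 5), power = 1), c(0.5, 0.5, 0))
  set.seed(11)
  for (i in 1:20) {
    d <- stats::runif(sample(1:30, 1), 0.01, 10)
    expect_equal(sum(idw_weights(d, power = stats::runif(1, 0, 4))), 1,
                 tolerance = 1e-12)
  }
  expect_error(idw_weights(numeric(0), 2), "non-empty")
  expect_error(idw_weights(c(-1, 2), 2), ">= 0")
})

test_that("point predictions match hand and brute-force evaluations", {
  pts <- tibble::tibble(x = c(0, 1, 0), y = c(0, 0, 2), value = c(10, 20, 30))
  # distances to (0,1): 1, sqrt(2), 1 -> (10*1 + 20*0.5 + 30*1)/2.5 = 20
  expect_equal(idw_predict(pts, 0, 1, idw_config(power = 2)), 20)
  expect_equal(idw_predict(pts, 0, 1, idw_config(power = 2)),
               brute_force_idw(pts, 0, 1, 2))
  # exactness at a data point
  expect_equal(idw_predict(pts, 1, 0, idw_config()), 20)
  # symmetry: equidistant from two values
  two <- tibble::tibble(x = c(-1, 1), y = 0, value = c(10, 20))
  expect_equal(idw_predict(two, 0, 0, idw_config()), 15)
  # agreement with the naive full formula on random configurations
  set.seed(22)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    p <- tibble::tibble(x = stats::runif(n), y = stats::runif(n),
                        value = stats::runif(n, -5, 50))
    a <- stats::runif(1, 0.5, 4)
    tx <- stats::runif(1); ty <- stats::runif(1)
    expect_equal(
      idw_predict(p, tx, ty, idw_config(power = a, max_neighbors = n)),
      brute_force_idw(p, tx, ty, a), tolerance = 1e-12)
  }
})

test_that("predictions are convex combinations of the neighbours used", {
  set.seed(33)
  p <- tibble::tibble(x = stats::runif(40), y = stats::runif(40),
                      value = stats::runif(40, 0, 100))
  cfg <- idw_config(power = 2, max_neighbors = 40)
  tx <- stats::runif(30); ty <- stats::runif(30)
  pred <- idw_predict(p, tx, ty, cfg)
  expect_true(all(pred >= min(p$value) - 1e-12))
  expect_true(all(pred <= max(p$value) + 1e-12))
})

test_that("power limits: 0 gives the neighbour mean, large converges to nearest", {
  set.seed(44)
  p <- tibble::tibble(x = stats::runif(20), y = stats::runif(20),
                      value = stats::runif(20, 0, 10))
  d <- sqrt((p$x - 0.5)^2 + (p$y - 0.5)^2)
  m <- 6
  nearest_m <- order(d)[seq_len(m)]
  expect_equal(idw_predict(p, 0.5, 0.5, idw_config(power = 0, max_neighbors = m)),
               mean(p$value[nearest_m]))
  expect_equal(idw_predict(p, 0.5, 0.5, idw_config(power = 60, max_neighbors = m)),
               p$value[which.min(d)], tolerance = 1e-6)
})

test_that("distance ties at the neighbour cap are all included", {
  # four points equidistant from the origin; cap of 2 must keep all four
  p <- tibble::tibble(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1),
                      value = c(1, 2, 3, 4))
  expect_equal(idw_predict(p, 0, 0, idw_config(power = 2, max_neighbors = 2)),
               mean(p$value))
  # and the result is order-independent
  expect_equal(idw_predict(p[c(3, 1, 4, 2), ], 0, 0,
                           idw_config(power = 2, max_neighbors = 2)),
               mean(p$value))
})

test_that("coincident points and cutoffs behave as documented", {
  p <- tibble::tibble(x = c(0, 0, 1), y = c(0, 0, 0), value = c(10, 30, 99))
  expect_warning(got <- idw_predict(p, 0, 0, idw_config()), "coincident")
  expect_equal(got, 20)  # mean of the coincident values
  # no point within the cutoff -> no-data, not an error
  far <- tibble::tibble(x = 10, y = 10, value = 5)
  expect_true(is.na(idw_predict(far, 0, 0, idw_config(cutoff = 1))))
  expect_error(idw_predict(far[0, ], 0, 0, idw_config()), "non-empty")
})

test_that("haversine metric reproduces great-circle distance weighting", {
  p <- tibble::tibble(x = c(85.75, 85.90), y = c(20.25, 20.40), value = c(0, 100))
  tx <- 85.80; ty <- 20.30
  d <- geosphere::distHaversine(cbind(tx, ty), cbind(p$x, p$y))
  w <- d^-2 / sum(d^-2)
  expect_equal(idw_predict(p, tx, ty, idw_config(metric = "haversine")),
               sum(w * p$value), tolerance = 1e-12)
})

test_that("gridded surfaces agree cell-by-cell with direct prediction", {
  pts <- tibble::tibble(x = c(0, 1, 0), y = c(0, 0, 2), value = c(10, 20, 30))
  cfg <- idw_config(power = 2)
  surf <- idw_grid(pts, bbox = c(0, 0, 2, 2), ncols = 2, nrows = 2, cfg)
  expect_s3_class(surf, "idw_surface")
  # cell centres: x in {0.5, 1.5}, y in {1.5, 0.5}; row 1 is the top row
  expect_equal(surf$values[1, 1], idw_predict(pts, 0.5, 1.5, cfg))
  expect_equal(surf$values[1, 2], idw_predict(pts, 1.5, 1.5, cfg))
  expect_equal(surf$values[2, 1], idw_predict(pts, 0.5, 0.5, cfg))
  expect_equal(surf$values[2, 2], idw_predict(pts, 1.5, 0.5, cfg))
  # determinism and the single-point constant field
  expect_identical(surf, idw_grid(pts, c(0, 0, 2, 2), 2, 2, cfg))
  one <- tibble::tibble(x = 0.3, y = 0.7, value = 42)
  s1 <- idw_grid(one, c(0, 0, 1, 1), 3, 4, cfg)
  expect_true(all(s1$values == 42))
})

test_that("ESRI ASCII grids round-trip through write_asc/read_asc", {
  set.seed(55)
  pts <- tibble::tibble(x = stats::runif(10), y = stats::runif(10),
                        value = stats::runif(10, 0, 9))
  surf <- idw_grid(pts, c(0, 0, 1, 1), 5, 5, idw_config(cutoff = 0.4))
  f <- withr::local_tempfile(fileext = ".asc")
  write_asc(surf, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols 5$")
  expect_match(hdr[6], "^NODATA_value")
  back <- read_asc(f)
  expect_equal(back$values, surf$values, tolerance = 1e-9)
  expect_equal(back$bbox, surf$bbox, tolerance = 1e-9)
  # non-square cells are not representable
  rect <- idw_grid(pts, c(0, 0, 2, 1), 3, 3, idw_config())
  expect_error(write_asc(rect, f), "square")
})
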