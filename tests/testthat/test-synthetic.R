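test_that("builtin zone profiles carry the study design and statistics", {
  p <- zone_profiles()
  expect_setequal(unique(p$zone), c("north", "south_west", "south_east"))
  expect_equal(nrow(p), 30L)  # 3 zones x 10 parameters

  design <- unique(p[, c("zone", "n_wards", "samples_per_ward")])
  expect_equal(sum(design$n_wards * design$samples_per_ward), 335L)
  expect_equal(design$n_wards[design$zone == "south_east"], 25L)

  se_hard <- p[p$zone == "south_east" & p$parameter == "hardness", ]
  expect_equal(se_hard$mean, 186.09)
  expect_equal(se_hard$sd, 40.78)
  expect_equal(se_hard$minimum, 98.40)
  expect_equal(se_hard$maximum, 268.96)

  n_ph <- p[p$zone == "north" & p$parameter == "ph", ]
  expect_equal(n_ph$minimum, 5.56)
  expect_equal(n_ph$maximum, 8.61)

  expect_true(all(p$minimum <= p$mean & p$mean <= p$maximum))
  expect_true(all(p$sd >= 0))
})

test_that("truncated-normal moments match numerical integration", {
  cases <- list(
    c(186.09, 40.78, 98.40, 268.96),  # south-east hardness
    c(7.66, 0.70, 5.56, 8.61),        # north pH
    c(2.39, 1.00, 0.55, 4.60),        # south-east BOD
    c(0, 1, -1, 3)
  )
  for (cs in cases) {
    mom <- truncnorm_moments(cs[1], cs[2], cs[3], cs[4])
    Z <- stats::pnorm(cs[4], cs[1], cs[2]) - stats::pnorm(cs[3], cs[1], cs[2])
    m_num <- stats::integrate(function(x) x * stats::dnorm(x, cs[1], cs[2]) / Z,
                              cs[3], cs[4], rel.tol = 1e-10)$value
    v_num <- stats::integrate(function(x) (x - m_num)^2 * stats::dnorm(x, cs[1], cs[2]) / Z,
                              cs[3], cs[4], rel.tol = 1e-10)$value
    expect_equal(mom$mean, m_num, tolerance = 1e-8)
    expect_equal(mom$sd, sqrt(v_num), tolerance = 1e-8)
  }
})

test_that("truncated-normal draws respect bounds and their target mean", {
  set.seed(9)
  x <- rtruncnorm(50000, 186.09, 40.78, 98.40, 268.96)
  expect_true(all(x >= 98.40 & x <= 268.96))
  m_true <- truncnorm_moments(186.09, 40.78, 98.40, 268.96)$mean
  expect_lt(abs(mean(x) - m_true) / m_true, 0.02)
  # degenerate cases
  expect_equal(rtruncnorm(5, 3, 1, 2, 2), rep(2, 5))
  expect_message(y <- rtruncnorm(5, 10, 0, 0, 4), "sd = 0")
  expect_equal(y, rep(4, 5))  # clamped mean
})

test_that("generation is seed-deterministic with the exact design counts", {
  a <- generate_samples(seed = 123)
  b <- generate_samples(seed = 123)
  expect_identical(a, b)
  expect_equal(nrow(a), 335L)
  expect_equal(sort(table(a$zone), decreasing = TRUE)[["south_east"]], 125L)
  expect_equal(length(unique(a$ward)), 67L)
  expect_true(all(table(a$ward) == 5L))
  c2 <- generate_samples(seed = 124)
  expect_false(identical(a, c2))
})

test_that("every generated value lies within its profile bounds and the bbox", {
  p <- zone_profiles()
  s <- generate_samples(seed = 5)
  for (i in seq_len(nrow(p))) {
    v <- s[s$zone == p$zone[i], ][[p$parameter[i]]]
    expect_true(all(v >= p$minimum[i] & v <= p$maximum[i]))
  }
  bb <- study_bbox()
  expect_true(all(s$x >= bb["xmin"] & s$x <= bb["xmax"]))
  expect_true(all(s$y >= bb["ymin"] & s$y <= bb["ymax"]))
})

test_that("samples of a ward cluster around a shared centroid", {
  s <- generate_samples(seed = 6, jitter_sd = 0.003)
  spread <- tapply(s$x, s$ward, function(v) max(v) - min(v))
  # within-ward spread is bounded by a few jitter SDs, far below the bbox width
  expect_true(all(spread < 10 * 0.003))
})

test_that("exceedance calibration hits exact counts while honouring bounds", {
  std <- is10500_standards()
  set.seed(77)
  # upper-only limit
  spec <- std[std$parameter == "ec", ]
  v <- rtruncnorm(125, 342.97, 73.69, 173.16, 581.47)
  cal <- calibrate_exceedance(v, spec, n_exceed = 90,
                              lower = 173.16, upper = 581.47)
  expect_equal(sum(exceeds_limit(cal, spec)), 90)
  expect_true(all(cal >= 173.16 & cal <= 581.47))
  expect_equal(order(cal), order(v))  # rank-preserving

  # range limit: non-exceeders must stay inside the two-sided band
  spec_do <- std[std$parameter == "do", ]
  vd <- rtruncnorm(125, 7.43, 0.49, 5.91, 8.20)
  cald <- calibrate_exceedance(vd, spec_do, n_exceed = 19,
                               lower = 5.91, upper = 8.20)
  expect_equal(sum(exceeds_limit(cald, spec_do)), 19)
  expect_true(all(cald >= 5.91 & cald <= 8.20))

  # low-side calibration
  call <- calibrate_exceedance(vd, spec_do, n_exceed = 19,
                               lower = 5.91, upper = 8.20, side = "low")
  expect_equal(sum(exceeds_limit(call, spec_do)), 19)
  expect_equal(sum(call < 6.5), 19)

  # extreme counts
  expect_equal(sum(exceeds_limit(
    calibrate_exceedance(v, spec, 0, 173.16, 581.47), spec)), 0)
  expect_equal(sum(exceeds_limit(
    calibrate_exceedance(v, spec, 125, 173.16, 581.47), spec)), 125)
  expect_error(calibrate_exceedance(v, spec, 126, 173.16, 581.47), "0\\.\\.125")
})

test_that("calibration hooks into generation per zone and parameter", {
  s <- generate_samples(seed = 31,
                        calibrate = list(south_east = list(ec = 90, ph = 8)))
  std <- is10500_standards()
  se <- s[s$zone == "south_east", ]
  expect_equal(sum(exceeds_limit(se$ec, std, "ec")), 90)
  expect_equal(sum(exceeds_limit(se$ph, std, "ph")), 8)
  # other zones untouched by the calibration request: still within bounds
  p <- zone_profiles()
  nb <- p[p$zone == "north" & p$parameter == "ec", ]
  expect_true(all(s$ec[s$zone == "north"] >= nb$minimum &
                  s$ec[s$zone == "north"] <= nb$maximum))
})
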