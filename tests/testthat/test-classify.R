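y_grid <- seq(0.5, 199.5, by = 1)
t_grid <- seq(0, 400, by = 1)

test_that("synthetic wave fields carry their design spectra", {
  tw <- generate_synthetic_field("tw", y_grid, t_grid, A = 2, q = 0.5,
                                 w = 0.3, offset = 7)
  expect_equal(mean(tw), 7, tolerance = 1e-3)
  expect_equal(max(tw), 9, tolerance = 1e-2)
  un <- generate_synthetic_field("uniform", y_grid, t_grid, offset = 4)
  expect_true(all(un == 4))
  # lateral average of a zero-mean wave equals the offset
  sw <- generate_synthetic_field("sw", y_grid, t_grid, A = 2, q = 0.5,
                                 w = 0.3, offset = 7)
  expect_lt(max(abs(colMeans(sw) - 7)), 0.05)
  expect_error(generate_synthetic_field("tw", y_grid, t_grid, q = 4),
               "Nyquist")
  # chaos surrogate has the requested RMS amplitude around the offset
  ch <- generate_synthetic_field("chaos", y_grid, t_grid, A = 1.5, q = 0.5,
                                 w = 0.3, offset = 7, seed = 2)
  expect_equal(sqrt(mean((ch - 7)^2)), 1.5, tolerance = 1e-6)
})

test_that("classifier identifies pure and noisy wave types", {
  tw <- generate_synthetic_field("tw", y_grid, t_grid, q = 0.5, w = 0.3,
                                 offset = 5)
  cl <- classify_field(tw)
  expect_equal(as.character(cl$class), "TW")
  expect_equal(abs(cl$directionality), 1, tolerance = 1e-6)
  expect_equal(cl$q_peak, 0.5, tolerance = 0.05)
  expect_equal(cl$w_peak, 0.3, tolerance = 0.02)

  sw <- generate_synthetic_field("sw", y_grid, t_grid, q = 0.5, w = 0.3,
                                 offset = 5)
  cl2 <- classify_field(sw)
  expect_equal(as.character(cl2$class), "SW")
  expect_lt(abs(cl2$directionality), 0.05)

  # robust to moderate measurement noise
  twn <- generate_synthetic_field("tw", y_grid, t_grid, q = 0.5, w = 0.3,
                                  offset = 5, noise = 0.2, seed = 8)
  expect_equal(as.character(classify_field(twn)$class), "TW")
  swn <- generate_synthetic_field("sw", y_grid, t_grid, q = 0.5, w = 0.3,
                                  offset = 5, noise = 0.15, seed = 8)
  expect_equal(as.character(classify_field(swn)$class), "SW")
})

test_that("band-limited surrogate turbulence is classified as chaos", {
  for (s in 1:3) {
    ch <- generate_synthetic_field("chaos", y_grid, t_grid, q = 0.5,
                                   w = 0.3, offset = 5, seed = s)
    cl <- classify_field(ch)
    expect_equal(as.character(cl$class), "CHAOS")
    expect_gt(cl$entropy, 0.45)
  }
})

test_that("degenerate inputs are flagged", {
  un <- generate_synthetic_field("uniform", y_grid, t_grid, offset = 5)
  expect_equal(as.character(classify_field(un)$class), "NONE")
  short_t <- seq(0, 30, by = 1)
  tw <- generate_synthetic_field("tw", y_grid, short_t, q = 0.5, w = 0.3,
                                 offset = 5)
  expect_error(classify_field(tw), "too short")
})
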