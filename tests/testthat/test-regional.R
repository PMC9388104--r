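test_that("averaging operators are exact on constants and linear in z", {
  w <- wedge_geometry(L = 100, H0 = 4, H1 = 40)
  x <- seq(0, 100, length.out = 41)
  y <- seq(0, 100, length.out = 31)
  zeta <- seq(0, 1, length.out = 21)
  const2 <- matrix(3.7, length(x), length(y))
  expect_equal(average_membrane(const2, x, y), 3.7)
  expect_equal(average_y(const2, x, y), rep(3.7, length(x)))
  const3 <- array(3.7, c(length(x), length(y), length(zeta)))
  expect_equal(average_bulk(const3, x, y, zeta, w), 3.7)
  expect_equal(average_yz(const3, x, y, zeta, w), rep(3.7, length(x)))

  # field = z on the wedge: <z>_V = int H^2/2 dx / int H dx
  H <- w$H(x)
  zfield <- array(0, c(length(x), length(y), length(zeta)))
  for (k in seq_along(zeta)) zfield[, , k] <- H %o% rep(1, length(y)) * zeta[k]
  got <- average_bulk(zfield, x, y, zeta, w)
  # closed form for affine H on [0, L]
  want <- (diff(range(x)) / 6 * (w$H0^2 + w$H0 * w$H1 + w$H1^2)) /
    (diff(range(x)) * (w$H0 + w$H1) / 2)
  expect_equal(got, want, tolerance = 1e-3)

  # Fubini: the bulk average is the H-weighted x-average of slice averages
  prof <- average_yz(zfield, x, y, zeta, w)
  wts <- H * c(diff(x) / 2, 0) + H * c(0, diff(x) / 2)
  expect_equal(sum(wts * prof) / sum(wts), got, tolerance = 1e-12)
})

test_that("instantaneous totals reduce to the slice totals at an HSS", {
  p <- p_canon
  w <- wedge_geometry(L = 100, H0 = 10, H1 = 10)
  x <- seq(5, 95, length.out = 7)
  b <- solve_hss(10, 665, 410, p)[1, ]
  md <- matrix(b$md, 7, 5)
  mde <- matrix(b$mde, 7, 5)
  cD0 <- matrix(b$cD0, 7, 5)
  cE0 <- matrix(b$cE0, 7, 5)
  tot <- instantaneous_totals(md, mde, cD0, cE0, x, w)
  expect_equal(unique(as.vector(tot$nD)), 665, tolerance = 1e-10)
  expect_equal(unique(as.vector(tot$nE)), 410, tolerance = 1e-10)
  # with nothing on the membrane the totals are the contact concentrations
  tot0 <- instantaneous_totals(md * 0, mde * 0, cD0, cE0, x, w)
  expect_equal(tot0$nD, cD0)
  expect_equal(tot0$nE, cE0)
})

test_that("slice-averaged instantaneous totals wash out wave structure", {
  p <- p_canon
  w <- wedge_geometry(L = 200, H0 = 8, H1 = 8)
  x <- c(50, 150)
  ny <- 256
  y <- seq(0.5, 199.5, length.out = ny)
  q <- 2 * pi * 12 / 200    # 12 wavelengths across the slice
  b <- solve_hss(8, 665, 410, p)[1, ]
  wave <- function(A, ph) A * sin(q * y + ph)
  md <- matrix(rep(b$md * (1 + 0.4 * sin(q * y)), each = 2), 2, ny)
  mde <- matrix(rep(b$mde * (1 + 0.3 * sin(q * y + 1)), each = 2), 2, ny)
  cD0 <- matrix(rep(b$cD0 * (1 + 0.2 * sin(q * y + 2)), each = 2), 2, ny)
  cE0 <- matrix(rep(b$cE0 * (1 + 0.2 * sin(q * y + 2.5)), each = 2), 2, ny)
  tot <- instantaneous_totals(md, mde, cD0, cE0, x, w)
  nD_bar <- average_y(tot$nD, x, y)
  nE_bar <- average_y(tot$nE, x, y)
  # averaging over many wavelengths recovers the slice totals within 2%
  expect_lt(max(abs(nD_bar / 665 - 1)), 0.02)
  expect_lt(max(abs(nE_bar / 410 - 1)), 0.02)
})

test_that("the commensurability classifier maps ratios to pattern types", {
  expect_equal(as.character(classify_ratio(1.5)), "CHAOS")
  expect_equal(as.character(classify_ratio(2.05)), "SW")
  expect_equal(as.character(classify_ratio(3.2)), "TW")
  expect_equal(as.character(classify_ratio(NA_real_)), "STABLE")
  # monotone: class index never decreases with the ratio
  lv <- c("CHAOS", "SW", "TW")
  idx <- vapply(seq(1.05, 6, by = 0.05), function(r) {
    match(as.character(classify_ratio(r)), lv)
  }, integer(1))
  expect_true(all(diff(idx) >= 0))
  # configurable SW/TW boundary
  expect_equal(as.character(classify_ratio(2.7, list(r_chaos = 2, r_TW = 3))),
               "SW")
})

test_that("regional kymographs handle trivial density fields", {
  p <- p_canon
  w <- default_wedge()
  x <- seq(50, 450, length.out = 5)
  tt <- c(0, 100, 200)
  z <- matrix(0, 5, 3)
  rk0 <- regional_kymograph(z, z + 300, x, tt, w, p)
  expect_true(all(rk0$class == "STABLE"))
  expect_true(all(is.na(attr(rk0, "x_crit")$x_crit)))

  # time-constant densities give a time-constant kymograph
  nD <- matrix(665, 5, 3)
  nE <- matrix(410, 5, 3)
  rk <- regional_kymograph(nD, nE, x, tt, w, p,
                           q_grid = default_q_grid(q_min = 5e-3, q_max = 3,
                                                   n = 30))
  byx <- split(rk$class, rk$x)
  expect_true(all(vapply(byx, function(v) length(unique(v)) == 1,
                         logical(1))))
  xc <- attr(rk, "x_crit")$x_crit
  expect_true(all(abs(xc - xc[1]) < 1e-9 | (is.na(xc) & is.na(xc[1]))))
})

test_that("crossing extraction interpolates and picks the primary front", {
  x <- seq(0, 100, by = 10)
  ratio <- c(1, 1.2, 1.5, 1.8, 2.2, 2.6, 3, 3.2, 3.4, 3.5, 3.6)
  cr <- ratio_crossings(x, ratio, level = 2)
  expect_equal(length(cr$all), 1)
  expect_equal(cr$primary, 35, tolerance = 0.01)
  # wiggly profile: several crossings, primary separates the big regions
  r2 <- c(1, 1.1, 2.3, 1.9, 1.2, 1.4, 2.4, 2.8, 3, 3.3, 3.4)
  cr2 <- ratio_crossings(x, r2, level = 2)
  expect_gt(length(cr2$all), 1)
  expect_gt(cr2$primary, 40)
  expect_lt(cr2$primary, 70)
})
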