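test_that("steady membrane flux has the right limits and BVP behaviour", {
  p <- p_canon
  expect_equal(steady_flux_phi(0, 7, p), 0)
  # deep-bulk saturation at sqrt(Dc lam) per unit contact concentration
  expect_equal(steady_flux_phi(1, 1e4, p), sqrt(360), tolerance = 1e-12)
  expect_lt(abs(sqrt(360) - 18.974), 1e-3)
  # monotone in H
  H <- c(1, 2, 5, 10, 30)
  expect_true(all(diff(steady_flux_phi(1, H, p)) > 0))
  expect_error(steady_flux_phi(1, -2, p), "positive")
})

test_that("steady flux matches the independent two-point BVP oracle", {
  p <- p_canon
  for (H in c(1, 2.5, 5, 10, 20, 50, 100)) {
    expect_equal(steady_flux_phi(1, H, p), gamma_bvp(H, p),
                 tolerance = 1e-8)
  }
})

test_that("residual vanishes at the analytic corner states", {
  p <- p_canon
  noD <- list(H = 7, nD = 0, nE = 300, md = 0, mde = 0,
              cD0 = 0, cDD0 = 0, cE0 = 300)
  expect_equal(max(abs(hss_residual(noD, p))), 0)
  # without MinE there is no detachment pathway: all MinD on the membrane
  noE <- list(H = 7, nD = 400, nE = 0, md = 2800, mde = 0,
              cD0 = 0, cDD0 = 0, cE0 = 0)
  expect_equal(max(abs(hss_residual(noE, p))), 0)
  # perturbing a converged state must break the balance
  s <- solve_hss(20, 665, 410, p)[1, ]
  s$md <- s$md * 1.01
  expect_gt(max(abs(hss_residual(s, p))), 1e-3)
})

test_that("solve_hss returns corner branches and satisfies mass closure", {
  p <- p_canon
  c1 <- solve_hss(11, 0, 250, p)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$cE0, 250)
  expect_equal(c1$md + c1$mde + c1$cD0 + c1$cDD0, 0)
  c2 <- solve_hss(11, 250, 0, p)
  expect_equal(c2$md, 250 * 11)

  set.seed(3)
  for (i in 1:12) {
    H <- runif(1, 2, 60)
    nD <- runif(1, 50, 1500)
    nE <- runif(1, 30, 1200)
    bs <- solve_hss(H, nD, nE, p)
    for (k in seq_len(nrow(bs))) {
      b <- bs[k, ]
      expect_lt(b$residual, 1e-10 * p$kde * (1 + p$nE_bar))
      # conserved totals reconstruct the inputs
      expect_equal(b$cD0 + (b$md + b$mde) / H, nD, tolerance = 1e-10)
      expect_equal(b$cE0 + b$mde / H, nE, tolerance = 1e-10)
    }
  }
})

test_that("canonical slice steady states agree with the BVP oracle", {
  p <- p_canon
  for (H in c(5, 20, 50)) {
    b <- solve_hss(H, 665, 410, p)
    expect_equal(nrow(b), 1)
    cap <- md_cap_of(H, 665, 410, p)
    o <- hss_oracle(H, 665, 410, p, c(cap * 1e-6, cap * (1 - 1e-12)))
    expect_equal(b$md, o$md, tolerance = 1e-8)
    expect_equal(b$mde, o$mde, tolerance = 1e-8)
    expect_equal(b$cD0, o$cD0, tolerance = 1e-8)
    expect_equal(b$cDD0, o$cDD0, tolerance = 1e-8)
    expect_equal(b$cE0, o$cE0, tolerance = 1e-8)
  }
})

test_that("implied vertical profile solves the stationary bulk problem", {
  p <- p_canon
  b <- solve_hss(12, 665, 410, p)[1, ]
  kz <- sqrt(p$lam / p$Dc)
  z <- seq(0, 12, length.out = 400)
  prof <- b$cDD0 * cosh(kz * (z - 12)) / cosh(kz * 12)
  # second derivative on the dense grid vs lam/Dc * c
  h <- z[2] - z[1]
  d2 <- (prof[-c(1, 2)] - 2 * prof[-c(1, 400)] + prof[-c(399, 400)]) / h^2
  resid <- p$Dc * d2 - p$lam * prof[-c(1, 400)]
  expect_lt(max(abs(resid)) / (p$lam * b$cDD0), 1e-4)
  # boundary conditions: the analytic profile has zero slope at the top and
  # carries the steady flux at the membrane
  dprof <- b$cDD0 * kz * sinh(kz * (z - 12)) / cosh(kz * 12)
  expect_equal(dprof[400], 0)
  expect_equal(-p$Dc * dprof[1], b$phi, tolerance = 1e-10)
})

test_that("multistable slices expose three branches ordered by cD0", {
  p <- p_canon
  bs <- solve_hss(5, 1600, 1400, p)
  expect_equal(nrow(bs), 3)
  expect_true(all(diff(bs$cD0) > 0))
  expect_equal(bs$branch_id, 1:3)
  hinted <- solve_hss(5, 1600, 1400, p, init_hint = list(md = bs$md[3],
                                                         mde = bs$mde[3]))
  expect_equal(which(hinted$nearest_hint), 3L)
})

test_that("branch continuation tracks folds against a finer scan", {
  p <- p_canon
  path <- tibble::tibble(H = 5, nD = seq(800, 2400, length.out = 33),
                         nE = 1400)
  ct <- hss_continuation(path, p)
  expect_equal(length(ct$sets), 33)
  counts <- vapply(ct$sets, nrow, integer(1))
  expect_true(any(counts == 3))
  expect_gt(nrow(ct$folds), 0)
  # each fold bracket is confirmed by a 10x finer branch-count scan
  for (k in seq_len(nrow(ct$folds))) {
    i0 <- ct$folds$i_before[k]; i1 <- ct$folds$i_after[k]
    fine <- seq(path$nD[i0], path$nD[i1], length.out = 11)
    fine_counts <- vapply(fine, function(nd) nrow(solve_hss(5, nd, 1400, p)),
                          integer(1))
    expect_equal(fine_counts[1], ct$folds$count_before[k])
    expect_equal(fine_counts[11], ct$folds$count_after[k])
    expect_true(any(diff(fine_counts) != 0))
  }
  # a constant path must keep constant branches and report no folds
  const <- hss_continuation(tibble::tibble(H = 5, nD = 900, nE = 410), p)
  expect_equal(nrow(const$folds), 0)
})
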