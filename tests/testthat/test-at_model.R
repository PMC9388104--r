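test_that("closed-form growth rates match the real 2x2 linearization", {
  set.seed(21)
  worst <- 0
  for (i in 1:10000) {
    pp <- at_params(gamma = runif(1, 0.1, 5), omega = runif(1, 0.5, 4),
                    b = runif(1, 0.2, 3), rho0 = runif(1, 0, 1))
    q <- runif(1, 0, 3)
    rho <- runif(1, 0, 1.5)
    s <- at_sigma(q, rho, pp)
    ev <- eigen(at_linear_matrix(q, rho, pp), only.values = TRUE)$values
    d <- max(Mod(sort(as.complex(s[1, ])) - sort(as.complex(ev))))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-10)
})

test_that("undriven dynamics are unconditionally stable", {
  pp <- at_params(gamma = 0)
  q <- seq(0, 3, by = 0.1)
  s <- at_sigma(q, pp$rho0, pp)
  expect_true(all(Re(s[, "sigma_plus"]) < 0))
  expect_equal(Re(s[, "sigma_plus"]), -(1 + pp$rho0 + q^2))
})

test_that("critical drive matches numerical bisection and self-consistency", {
  p <- at_params()
  expect_true(attr(gamma_c(p), "short_wavelength"))
  max_growth <- function(g) {
    pp <- at_params(gamma = g)
    -stats::optimize(function(q) -Re(at_sigma(q, pp$rho0, pp)[1, 1]),
                     c(0, 2.5), tol = 1e-12)$objective
  }
  gc_num <- stats::uniroot(max_growth, c(2, 3.5), tol = 1e-9)$root
  expect_lt(abs(gc_num - as.numeric(gamma_c(p))), 1e-6)
  # rho_c inverts gamma_c: at gamma = gamma_c the critical density is rho0
  pc <- at_params(gamma = as.numeric(gamma_c(p)))
  expect_equal(rho_c(pc), p$rho0, tolerance = 1e-12)
  # a drive barely above threshold puts rho_c barely above rho0
  p1 <- at_params(gamma_rel = 1.001)
  expect_gt(rho_c(p1), p1$rho0)
  expect_lt(rho_c(p1) - p1$rho0, 0.01)
  # short-wavelength onset condition
  expect_gt(p$b * p$omega - 1 - p$rho0, 0)
  p_long <- at_params(omega = 0.8, b = 1, rho0 = 0.3)
  expect_false(attr(gamma_c(p_long), "short_wavelength"))
})

test_that("the zero state is invariant and subthreshold noise decays", {
  p <- at_params()
  st0 <- simulate_at(p, T = 10, dt = 0.1, seed = 1, init_amp = 0)
  expect_equal(max(Mod(st0$psi)), 0)
  expect_equal(unique(as.vector(st0$rho)), p$rho0)

  psub <- at_params(gamma_rel = 0.9)
  st <- simulate_at(psub, T = 60, dt = 0.1, seed = 2, init_amp = 1e-3)
  expect_lt(max(Mod(st$psi)), 1e-4)
  # mean density conserved to round-off
  expect_lt(abs(mean(st$rho) - p$rho0), 1e-12)
})

test_that("stability maps mark low coarse density as unstable", {
  p <- at_params()
  rc <- rho_c(p)
  lo <- matrix(p$rho0, 64, 32)          # rho0 < rho_c at this drive
  sm <- regional_stability_map(lo, p = p, filter_sd = 5)
  expect_true(all(sm$unstable))
  hi <- matrix(rc + 0.05, 64, 32)
  sm2 <- regional_stability_map(hi, p = p, filter_sd = 5)
  expect_false(any(sm2$unstable))
  # the filter is mass-preserving: mean of the filtered field is unchanged
  set.seed(4)
  rnd <- matrix(runif(64 * 32, 0.2, 0.4), 64, 32)
  sm3 <- regional_stability_map(rnd, p = p, filter_sd = 5)
  expect_equal(mean(sm3$rho_bar), mean(rnd), tolerance = 1e-12)
})
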