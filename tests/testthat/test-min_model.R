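test_that("reaction fluxes match direct mass-action evaluation", {
  p <- p_canon
  z <- reaction_rates(cDT = 0, cE = 0, md = 0, mde = 0, p = p)
  expect_identical(unlist(z), c(rDon = 0, rEon = 0, rDEoff = 0))

  r1 <- reaction_rates(cDT = 1, cE = 1, md = 0, mde = 0, p = p)
  expect_equal(r1$rDon, 0.065)
  expect_equal(r1$rEon, 0)
  expect_equal(r1$rDEoff, 0)

  r2 <- reaction_rates(cDT = 1, cE = 1, md = 1, mde = 1, p = p)
  expect_equal(r2$rDon, 0.163)
  expect_equal(r2$rEon, 0.126)
  expect_equal(r2$rDEoff, 0.34)

  expect_error(reaction_rates(cDT = -1, cE = 1, md = 1, mde = 1, p = p),
               "non-negative")
})

test_that("membrane reactive rates and boundary fluxes are consistent", {
  p <- p_canon
  m <- membrane_rhs_reactions(cDT = 1, cE = 1, md = 1, mde = 1, p = p)
  expect_equal(m$md, 0.037)
  expect_equal(m$mde, -0.214)

  f <- boundary_fluxes(cDT = 1, cE = 1, md = 1, mde = 1, p = p)
  expect_equal(f$cD, 0.177)
  expect_equal(f$cDD, 0.34)
  expect_equal(f$cE, 0.214)

  z <- boundary_fluxes(cDT = 0, cE = 0, md = 0, mde = 0, p = p)
  expect_identical(unlist(z), c(cD = 0, cDD = 0, cE = 0))
})

test_that("interface bookkeeping sums to zero for arbitrary states", {
  p <- p_canon
  set.seed(42)
  for (i in 1:25) {
    st <- list(cDT = runif(1, 0, 700), cE = runif(1, 0, 500),
               md = runif(1, 0, 4000), mde = runif(1, 0, 9000))
    m <- do.call(membrane_rhs_reactions, c(st, list(p = p)))
    f <- do.call(boundary_fluxes, c(st, list(p = p)))
    r <- do.call(reaction_rates, c(st, list(p = p)))
    scale <- max(abs(unlist(r)), 1)
    # total membrane-bound MinD change + MinD flux into the bulk = 0
    expect_lt(abs(m$md + m$mde + f$cD) / scale, 1e-14)
    # same bookkeeping for MinE (carried by the complex only)
    expect_lt(abs(m$mde + f$cE) / scale, 1e-14)
  }
})

test_that("analytic interface Jacobians match finite differences", {
  p <- p_canon
  set.seed(7)
  for (i in 1:5) {
    s <- list(cD0 = runif(1, 10, 600), cDD0 = runif(1, 1, 100),
              cE0 = runif(1, 1, 400), md = runif(1, 1, 3000),
              mde = runif(1, 1, 8000))
    ja <- do.call(linearized_interface, c(s, list(p = p)))
    jn <- do.call(fd_interface_jacobians, c(s, list(p = p)))
    for (nm in names(ja)) {
      expect_equal(unname(ja[[nm]]), unname(jn[[nm]]), tolerance = 1e-6)
    }
  }
})

test_that("parameter and geometry constructors validate inputs", {
  expect_error(min_params(60, 0.013, -1, 0.098, 0.126, 0.34, 6, 665, 410),
               "positive")
  expect_error(wedge_geometry(L = 500, H0 = 50, H1 = 5))
  w <- wedge_geometry(L = 500, H0 = 5, H1 = 50)
  expect_equal(w$H(c(0, 250, 500)), c(5, 27.5, 50))
  expect_equal(w$area, 250000)
  expect_equal(w$volume, 500^2 * 27.5)
})

test_that("cytosol variable conversions invert each other", {
  tr <- contact_to_transformed(cDD = 3, cDT = 4, cE = 5)
  expect_equal(tr$cD, 7)
  back <- do.call(transformed_to_contact, tr)
  expect_equal(back, list(cDD = 3, cDT = 4, cE = 5))
})
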