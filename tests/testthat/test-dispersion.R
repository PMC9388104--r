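test_that("vertical decay rates follow the closed forms", {
  p <- p_canon
  k <- vertical_decay_rates(0, 0, p)
  expect_equal(k$kD, 0 + 0i)
  expect_equal(k$kDD, complex(real = sqrt(0.1)), tolerance = 1e-12)
  expect_equal(k$kE, k$kD)
  # real positive growth gives real positive rates
  k2 <- vertical_decay_rates(0.5, 0.3, p)
  expect_true(Im(k2$kD) == 0 && Re(k2$kD) > 0)
  # neutral diffusive mode: sigma = -Dc q^2 makes kD vanish
  k3 <- vertical_decay_rates(-p$Dc * 0.25, 0.5, p)
  expect_equal(Mod(k3$kD), 0, tolerance = 1e-12)
})

test_that("characteristic matrix matches finite-difference Jacobians", {
  p <- p_canon
  hss <- solve_hss(20, 665, 410, p)[1, ]
  jn <- fd_interface_jacobians(hss$cD0, hss$cDD0, hss$cE0, hss$md, hss$mde, p)
  set.seed(11)
  for (i in 1:6) {
    sig <- complex(real = runif(1, -1, 1), imaginary = runif(1, -1, 1))
    q <- runif(1, 0.01, 1.5)
    Ma <- characteristic_matrix(sig, q, hss, p)
    Mn <- characteristic_matrix(sig, q, hss, p, jac = jn)
    expect_lt(max(Mod(Ma - Mn)) / max(Mod(Ma)), 1e-6)
    # evenness in q (only q^2 enters)
    expect_equal(Ma, characteristic_matrix(sig, -q, hss, p), tolerance = 1e-12)
  }
})

test_that("mass conservation forces a double root at the origin", {
  p <- p_canon
  for (H in c(5, 20, 45)) {
    hss <- solve_hss(H, 665, 410, p)[1, ]
    M <- characteristic_matrix(0, 0, hss, p)
    sv <- svd(M)$d
    # exactly two singular values vanish: two conserved masses
    expect_lt(sv[5] / sv[1], 1e-12)
    expect_lt(sv[4] / sv[1], 1e-12)
    expect_gt(sv[3] / sv[1], 1e-8)
    ev <- operator_eigenvalues(0, hss, p, n_nodes = 48)
    # exactly two neutral modes in the operator spectrum as well
    expect_equal(sum(Mod(ev) < 1e-8), 2)
    expect_equal(sum(Mod(ev) < 1e-3), 2)
  }
})

test_that("leading root agrees with the collocation operator", {
  p <- p_canon
  hss <- solve_hss(35, 665, 410, p)[1, ]
  prev <- NULL
  for (q in c(0.05, 0.3, 0.8, 1.5)) {
    ls <- leading_sigma(q, hss, p, seeds = prev)
    prev <- ls$roots[seq_len(min(3, length(ls$roots)))]
    ev <- operator_eigenvalues(q, hss, p, n_nodes = 110)[1]
    ev <- if (Im(ev) < 0) Conj(ev) else ev
    s <- if (Im(ls$sigma) < 0) Conj(ls$sigma) else ls$sigma
    expect_lt(Mod(s - ev) / Mod(ev), 1e-6)
  }
})

test_that("large wavenumbers are diffusively damped", {
  p <- p_canon
  hss <- solve_hss(20, 665, 410, p)[1, ]
  s1 <- leading_sigma(4, hss, p)$sigma
  s2 <- leading_sigma(8, hss, p)$sigma
  expect_lt(Re(s2), Re(s1))
  expect_lt(Re(s1), 0)
})

test_that("the dead membrane state has no unstable band", {
  p <- p_canon
  dead <- solve_hss(20, 665, 0, p)[1, ]
  for (q in c(0.05, 0.3, 1)) {
    ev <- operator_eigenvalues(q, dead, p, n_nodes = 60)
    expect_lt(max(Re(ev)), 1e-10)
  }
})

test_that("dispersion curves extract band structure and mode ratio", {
  p <- p_canon
  hss <- solve_hss(30, 665, 410, p)[1, ]
  dc <- dispersion_curve(hss, p, q_grid = default_q_grid(q_min = 5e-3,
                                                         q_max = 3, n = 45))
  g <- glance(dc)
  expect_true(g$unstable)
  expect_true(g$oscillatory)
  expect_gt(g$q_star, 0.4)
  expect_lt(g$q_star, 1)
  expect_gt(g$ratio, 1)
  # the leading growth rate at the refined maximum beats every grid point
  expect_gte(g$re_sigma_star, max(dc$re_sigma) - 1e-10)
  # the band edge has zero growth and decay just beyond it
  s_edge <- leading_sigma(g$q_max, hss, p)$sigma
  expect_lt(abs(Re(s_edge)), 1e-5)
  s_beyond <- leading_sigma(g$q_max * 1.05, hss, p)$sigma
  expect_lt(Re(s_beyond), 0)

  # a laterally stable slice is flagged as such
  stab <- solve_hss(10, 665, 410, p)[1, ]
  dc2 <- dispersion_curve(stab, p, q_grid = default_q_grid(q_min = 5e-3,
                                                           q_max = 2, n = 25))
  expect_false(glance(dc2)$unstable)
  expect_true(is.na(glance(dc2)$ratio))
})
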