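p_ref <- kinetic_params()

test_that("hydrolysis rate honours its Michaelis-Menten identities", {
  n <- 16
  E <- seq(0, 1e-8, length.out = n)
  # no substrate -> no flux
  expect_equal(hydrolysis_rate(rep(0, n), E, p_ref), rep(0, n))
  # half-saturation: S = K_S gives exactly k_cat*E/2
  S <- rep(p_ref$K_S, n)
  expect_equal(hydrolysis_rate(S, E, p_ref), p_ref$k_cat * E / 2)
  # enzyme-free spontaneous (acid) hydrolysis
  ps <- kinetic_params(k_spont = 3e-7)
  S <- seq(0, 0.03, length.out = n)
  expect_equal(hydrolysis_rate(S, rep(0, n), ps), 3e-7 * S)
  # upper bound v <= k_cat*E + k_spont*S
  set.seed(11)
  S <- runif(n, 0, 0.05); E <- runif(n, 0, 1e-7)
  v <- hydrolysis_rate(S, E, ps)
  expect_true(all(v <= ps$k_cat * E + ps$k_spont * S + 1e-30))
  expect_error(hydrolysis_rate(S[1:3], E, p_ref), "share one grid")
  expect_error(hydrolysis_rate(-S, E, p_ref), "non-negative")
})

test_that("hexose uptake saturates and halves at half-saturation", {
  n <- 8
  N <- rep(1e6, n)
  expect_equal(hexose_uptake_rate(rep(0, n), N, p_ref), rep(0, n))
  # saturation limit within 0.01%
  H_big <- rep(1e6 * max(p_ref$K_hi, p_ref$K_lo), n)
  u_sat <- 1e6 * 1e3 * (p_ref$V_hi + p_ref$V_lo)
  expect_rel(hexose_uptake_rate(H_big, N, p_ref), rep(u_sat, n), 1e-4)
  # single-transporter half-saturation
  p1 <- kinetic_params(V_lo = 0)
  expect_equal(hexose_uptake_rate(rep(p1$K_hi, n), N, p1),
               rep(1e6 * 1e3 * p1$V_hi / 2, n))
  expect_error(hexose_uptake_rate(c(NaN, rep(0, n - 1)), N, p_ref),
               "finite")
})

test_that("Monod growth rate is bounded and halves at K_H", {
  expect_equal(specific_growth_rate(0, p_ref), 0)
  expect_equal(specific_growth_rate(p_ref$K_H, p_ref), p_ref$mu_max / 2)
  mu_inf <- specific_growth_rate(1e4 * p_ref$K_H, p_ref)
  expect_lt(mu_inf, p_ref$mu_max)
  expect_rel(mu_inf, 0.27, 1e-3)
})

test_that("invertase production scales with cells and decays with delta_E", {
  n <- 6
  expect_equal(invertase_production_rate(rep(0, n), 1.8e-24, p_ref),
               rep(0, n))
  # dark lawn accumulation at the leaky rate
  N <- rep(2e6, n)
  expect_equal(invertase_production_rate(N, p_ref$alpha_cheat, p_ref),
               rep(2e6 * 1e3 * 1.5e-25, n))
  # pure decay
  pd <- kinetic_params(delta_E = 1e-5)
  E <- runif(n)
  expect_equal(invertase_production_rate(rep(0, n), 0, pd, E = E),
               -1e-5 * E)
  expect_error(invertase_production_rate(N, c(1, 2), p_ref), "aligned")
})

test_that("local_rhs conserves hexose equivalents and matches hand math", {
  g <- tiny_grid()
  zero <- sim_state(g)
  d0 <- local_rhs(zero, 0, p_ref)
  expect_true(all(unlist(d0) == 0))

  # derived check: fresh sucrose + enzyme, hexose initially rises at
  # 2*phi*k_cat*E*S/(K_S+S); hand-evaluated with independent arithmetic
  pp <- kinetic_params(phi_leak = 0.8)
  S0 <- 29.2e-3; E0 <- 4e-10
  st <- sim_state(g, S = S0, E = E0, N = 1e6)
  d <- local_rhs(st, 0, pp)
  v_hand <- 1000 * 4e-10 * 29.2e-3 / (26e-3 + 29.2e-3)   # mol/L/s
  expect_rel(d$dH[1], 2 * 0.8 * v_hand * 3600, 1e-12)
  expect_rel(d$dS[1], -v_hand * 3600, 1e-12)

  # conservation 2 dS + dH + dU = 0 for random states, any phi
  set.seed(42)
  for (phi in c(0, 0.3, 1)) {
    pr <- kinetic_params(phi_leak = phi, k_spont = 1e-7)
    st <- sim_state(g, S = runif(8, 0, 0.03), H = runif(8, 0, 0.01),
                    E = runif(8, 0, 1e-8), N = runif(8, 0, 1e9),
                    U = runif(8, 0, 0.01))
    d <- local_rhs(st, 1e-24, pr)
    resid <- abs(2 * d$dS + d$dH + d$dU)
    scale <- pmax(abs(d$dS), abs(d$dH), abs(d$dU), 1e-300)
    expect_lt(max(resid / scale), 1e-12)
  }
})

test_that("rates are monotone and homogeneous in density", {
  set.seed(7)
  S <- sort(runif(10, 0, 0.05)); E <- sort(runif(10, 0, 1e-8))
  H <- sort(runif(10, 0, 0.01)); N <- sort(runif(10, 1e5, 1e9))
  expect_true(all(diff(hydrolysis_rate(S, rep(1e-9, 10), p_ref)) >= 0))
  expect_true(all(diff(hydrolysis_rate(rep(0.01, 10), E, p_ref)) >= 0))
  expect_true(all(diff(hexose_uptake_rate(H, rep(1e7, 10), p_ref)) >= 0))
  expect_true(all(diff(hexose_uptake_rate(rep(1e-3, 10), N, p_ref)) >= 0))
  expect_true(all(diff(specific_growth_rate(H, p_ref)) >= 0))
  # doubling N doubles uptake and production at fixed concentrations
  expect_equal(hexose_uptake_rate(rep(1e-3, 10), 2 * N, p_ref),
               2 * hexose_uptake_rate(rep(1e-3, 10), N, p_ref))
  expect_equal(invertase_production_rate(2 * N, 1e-24, p_ref),
               2 * invertase_production_rate(N, 1e-24, p_ref))
})

test_that("sim_state validates shapes and signs", {
  g <- tiny_grid()
  expect_error(sim_state(g, S = rep(1, 3)), "mismatch")
  expect_error(sim_state(g, N = -1), "non-negative")
  st <- initial_state(g)
  expect_equal(st$S[1], 10 / 342.30)
  expect_equal(st$N[1], 1e6)
})
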