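test_that("grid construction enforces its invariants", {
  expect_error(rd_grid(10, 0.3), "integer multiple")
  expect_error(rd_grid(1, 0.5), "at least 4")
  expect_error(rd_grid(-5), "positive")
  g <- rd_grid(c(10, 5), 0.5, c("noflux", "periodic"))
  expect_equal(g$n, c(20L, 10L))
  expect_equal(grid_coords(g, 2)[1], 0.25)
})

test_that("laplacian matches stencil identities and conserves mass", {
  g <- rd_grid(10, 0.5)
  expect_equal(laplacian(rep(3.2, g$n[1]), g), rep(0, g$n[1]))
  # f(x) = x^2 -> f'' = 2 on the interior
  x <- grid_coords(g)
  lap <- laplacian(x^2, g)
  expect_rel(lap[3:(g$n[1] - 2)], rep(2, g$n[1] - 4), 1e-10)
  # no-flux: domain sum is exactly zero (discrete divergence theorem)
  set.seed(5)
  f <- runif(g$n[1])
  expect_lt(abs(sum(laplacian(f, g))), 1e-12 * max(abs(f)) / g$spacing^2)
  gp <- rd_grid(10, 0.5, "periodic")
  expect_lt(abs(sum(laplacian(f, gp))) /
              (max(abs(f)) / g$spacing^2), 1e-10)
  # 2D five-point stencil on a paraboloid
  g2 <- rd_grid(c(5, 5), 0.5)
  xy <- outer(grid_coords(g2, 1)^2, grid_coords(g2, 2)^2, `+`)
  lap2 <- laplacian(xy, g2)
  expect_rel(lap2[3:8, 3:8], matrix(4, 6, 6), 1e-10)
  expect_error(laplacian(rep(1, 3), g), "mismatch")
})

test_that("nothing happens when there is nothing to eat", {
  g <- tiny_grid(extent = 6)
  p <- kinetic_params(alpha_coop = 0, alpha_cheat = 0)
  st <- initial_state(g)                     # S only, E = H = 0
  tr <- integrate_rd(st, light_uniform(g, 0), p, t_end = 10,
                     out_times = c(0, 10))
  fin <- tr$states[[2]]
  expect_equal(fin$N, st$N)
  expect_rel(fin$S, st$S, 1e-12)
  expect_true(all(fin$H == 0) && all(fin$E == 0))
})

test_that("pure diffusion reproduces the heat kernel", {
  g <- rd_grid(40, 0.2)
  p <- inert_params(D_H = 600)
  sig0 <- 1                                   # 5 grid cells
  x <- grid_coords(g)
  h0 <- 1e-3 * exp(-(x - 20)^2 / (2 * sig0^2))
  st <- sim_state(g, H = h0)
  D <- internal_units(p)$D_H_mm2h
  t1 <- 2
  tr <- integrate_rd(st, 0, p, t_end = t1, out_times = c(0, t1),
                     control = list(max_dt = 0.01))
  sig2 <- sig0^2 + 2 * D * t1
  exact <- 1e-3 * sig0 / sqrt(sig2) * exp(-(x - 20)^2 / (2 * sig2))
  got <- tr$states[[2]]$H
  expect_lt(sqrt(sum((got - exact)^2) / sum(exact^2)), 1e-3)
})

test_that("spatial solver agrees with the independent 0D oracle", {
  g <- tiny_grid(extent = 2, spacing = 0.5)
  p <- kinetic_params()
  ot <- seq(0, 30, by = 5)
  tr <- integrate_rd(initial_state(g), light_uniform(g), p, t_end = 30,
                     out_times = ot, control = list(rtol = 1e-8,
                                                    atol = 1e-11))
  od <- run_0d(c(S = 10 / 342.30, N = 1e6), alpha = p$alpha_coop, p,
               t_end = 30, out_times = ot)
  for (f in c("S", "H", "E", "N")) {
    sim <- vapply(tr$states, function(s) s[[f]][1], numeric(1))
    ref <- od[[f]]
    expect_lt(max(abs(sim - ref) / pmax(abs(ref), max(ref) * 1e-9)), 1e-4)
  }
})

test_that("0D oracle conserves 2S + H + U and hits mu_max", {
  p <- kinetic_params()
  od <- run_0d(c(S = 0.01, H = 0.005, N = 5e7), alpha = 1e-24, p,
               t_end = 20, out_times = seq(0, 20, 2))
  tot <- 2 * od$S + od$H + od$U
  expect_rel(tot, rep(tot[1], length(tot)), 1e-9)
  # saturating hexose, no sucrose: exponential growth at mu_max
  p2 <- kinetic_params(V_hi = 0, V_lo = 0)   # keep H saturating
  od2 <- run_0d(c(H = 1, N = 1e5), alpha = 0, p2, t_end = 10,
                out_times = c(0, 10))
  r <- log(od2$N[2] / od2$N[1]) / 10
  expect_rel(r, 0.27 / (1 + p2$K_H), 1e-6)  # exact Monod rate at H = 1
  expect_rel(r, 0.27, 1e-3)                 # approaches mu_max
})

test_that("no-flux conservation holds on a patterned run", {
  g <- rd_grid(20, 0.2)
  p <- kinetic_params()
  pat <- light_periodic_lines(g, 5, 0.25)
  tr <- integrate_rd(initial_state(g), pat, p, t_end = 10,
                     out_times = seq(0, 10, 2))
  tot <- sugar_total(tr)
  expect_rel(tot, rep(tot[1], length(tot)), 1e-8)
  # positivity bookkeeping
  expect_true(all(tr$diagnostics$min_value >= 0))
  expect_lt(sum(tr$diagnostics$clipped[c("S", "H", "U")]) /
              (tot[1] + 1e-300), 1e-8)
})

test_that("a symmetric pattern yields a symmetric trajectory", {
  g <- rd_grid(20, 0.2)
  p <- kinetic_params()
  pat <- light_single_line(g, 4, center = 10)
  tr <- integrate_rd(initial_state(g), pat, p, t_end = 8,
                     out_times = c(0, 8))
  N <- tr$states[[2]]$N
  expect_rel(N, rev(N), 1e-9)
})

test_that("spatial accuracy improves at second order under refinement", {
  # pure diffusion against the heat kernel at two resolutions with a
  # fixed small time step, so the spatial truncation error dominates
  err_at <- function(dx) {
    g <- rd_grid(40, dx)
    p <- inert_params(D_H = 600)
    x <- grid_coords(g)
    st <- sim_state(g, H = exp(-(x - 20)^2 / 2))
    D <- internal_units(p)$D_H_mm2h
    tr <- integrate_rd(st, 0, p, t_end = 1, out_times = 1,
                       control = list(max_dt = 0.002))
    s2 <- 1 + 2 * D
    exact <- 1 / sqrt(s2) * exp(-(x - 20)^2 / (2 * s2))
    sqrt(mean((tr$states[[1]]$H - exact)^2))
  }
  e1 <- err_at(0.8)
  e2 <- err_at(0.4)
  expect_gt(e1 / e2, 3)   # ratio 4 expected for a 2nd-order stencil
})

test_that("solver guards its contract", {
  g <- tiny_grid()
  p <- kinetic_params()
  st <- initial_state(g)
  expect_error(integrate_rd(st, rep(1e-24, 3), p, t_end = 1), "aligned")
  expect_error(integrate_rd(st, 0, p, t_end = 0), "exceed")
  expect_error(integrate_rd(st, 0, p, t_end = 1, out_times = c(0, 2)),
               "out_times")
  tr <- integrate_rd(st, 0, p, t_end = 1, out_times = c(0, 0.5, 1))
  expect_warning(traj_field(tr, "N", 0.7), "nearest")
  expect_equal(traj_field(tr, "S", 0), st$S)
})
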