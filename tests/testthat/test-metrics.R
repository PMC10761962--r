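test_that("mean_density_curve averages the requested region", {
  g <- rd_grid(10, 0.5)
  # two-region lawn: rate 0.2 left half, 0.4 right half
  mask <- ifelse(grid_coords(g) < 5, 0.5, 1)
  tr <- phenomenological_lawn(g, growth_rate = 0.4, carrying_capacity = 1e12,
                              N0 = 1e6, t_points = c(0, 5, 10),
                              modulation = mask)
  full <- mean_density_curve(tr)
  # area-weighted average of the two closed-form logistic branches
  byhand <- function(t) mean(c(1e12 * 1e6 * exp(0.2 * t) /
                                 (1e12 + 1e6 * (exp(0.2 * t) - 1)),
                               1e12 * 1e6 * exp(0.4 * t) /
                                 (1e12 + 1e6 * (exp(0.4 * t) - 1))))
  expect_rel(full$N, vapply(c(0, 5, 10), byhand, numeric(1)), 1e-12)
  # sub-roi picks out a single branch, equal to any point trace
  left <- mean_density_curve(tr, roi = c(0, 4.9))
  expect_equal(left$N, vapply(tr$states, function(s) s$N[1], numeric(1)))
  expect_error(mean_density_curve(tr, roi = c(20, 30)), "empty roi")
})

test_that("max_growth_rate recovers exponential and logistic rates", {
  t <- seq(0, 10, by = 5 / 60)                  # 5-minute sampling
  curve <- data.frame(t = t, N = 2e5 * exp(0.3 * t))
  expect_lt(abs(max_growth_rate(curve) - 0.300), 0.001)
  # invariant to rescaling N
  expect_equal(max_growth_rate(transform(curve, N = N * 7.3)),
               max_growth_rate(curve))
  # logistic: d ln N/dt = r (1 - N/K), maximal at t = 0, below r,
  # approaching r as K grows
  logi <- function(K) {
    N <- K * 1e6 * exp(0.5 * t) / (K + 1e6 * (exp(0.5 * t) - 1))
    max_growth_rate(data.frame(t = t, N = N))
  }
  r1 <- logi(1e8); r2 <- logi(1e10)
  expect_lt(r1, 0.5 + 1e-6)
  expect_lt(r2, 0.5 + 1e-6)
  expect_gt(r2, r1)
  expect_lt(abs(r2 - 0.5 * (1 - 1e6 / 1e10)), 5e-3)
  expect_error(max_growth_rate(curve[1:5, ]), "10 time points")
  expect_error(max_growth_rate(data.frame(t = t, N = 0 * t)), "positive")
})

test_that("final_density detects plateaus and warns otherwise", {
  t <- seq(0, 40, by = 0.5)
  expect_equal(as.numeric(final_density(data.frame(t = t, N = 5e8))), 5e8)
  # saturating logistic reaches its carrying capacity
  N <- 1e9 / (1 + 999 * exp(-0.5 * t))
  fd <- final_density(data.frame(t = t, N = N))
  expect_true(attr(fd, "plateau"))
  expect_rel(as.numeric(fd), 1e9, 0.01)
  # still-growing curve: end value plus warning
  Ng <- 1e6 * exp(0.2 * t)
  expect_warning(fd2 <- final_density(data.frame(t = t, N = Ng)),
                 "no plateau")
  expect_equal(as.numeric(fd2), Ng[length(Ng)])
  expect_false(attr(fd2, "plateau"))
})

test_that("density_profile restricts and transverse-averages correctly", {
  g <- rd_grid(10, 0.5)
  tr <- phenomenological_lawn(g, t_points = c(0, 2))
  pr <- density_profile(tr, 2)
  expect_equal(pr$x, grid_coords(g))
  expect_equal(pr$N, tr$states[[2]]$N)
  # 2D stripe field: transverse average equals the hand-built rowMeans
  g2 <- rd_grid(c(4, 3), 0.5)
  f <- matrix(runif(prod(g2$n)), g2$n[1], g2$n[2])
  st <- sim_state(g2, N = f)
  tr2 <- structure(list(times = 0, states = list(st), grid = g2,
                        diagnostics = NULL), class = "trajectory")
  pr2 <- density_profile(tr2, 0)
  expect_equal(pr2$N, rowMeans(f))
  band <- density_profile(tr2, 0, band = c(0, 1))
  expect_equal(band$N, rowMeans(f[, 1:2]))
  expect_error(density_profile(tr2, 0, band = c(5, 6)), "band outside")
})

test_that("cooperator_benefit reads stripe centers from the pattern", {
  g <- rd_grid(40, 0.1)
  pat <- light_periodic_lines(g, 8, 0.25)
  # brute-force stripe centers from the alpha field itself
  p <- kinetic_params()
  a <- alpha_map(pat, p)
  runs <- rle(a == p$alpha_coop)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  centers_mm <- (starts + ends) / 2 * g$spacing - g$spacing / 2
  lit_centers <- centers_mm[runs$values]
  dist_to_expected <- apply(abs(outer(lit_centers, 1 + 8 * (0:4), `-`)),
                            1, min)
  expect_true(all(dist_to_expected < g$spacing))
  # a uniform lawn gives B = 0 exactly
  tr <- phenomenological_lawn(g, t_points = c(0, 1))
  row <- cooperator_benefit(tr, pat, 1)
  expect_identical(row$B, 0)
  expect_equal(row$lambda, 8)
  # stripe-modulated lawn gives the closed-form contrast
  mod <- ifelse(a == p$alpha_coop, 1, 0.5)
  tr2 <- phenomenological_lawn(g, growth_rate = 0.4,
                               carrying_capacity = 1e12,
                               t_points = c(0, 10), modulation = mod)
  row2 <- cooperator_benefit(tr2, pat, 10)
  expect_rel(row2$B, 1e6 * (exp(4) - exp(2)), 1e-3)
  # uniform pattern is a hard error, not zero
  expect_error(cooperator_benefit(tr, light_uniform(g), 1), "striped")
})

test_that("single-line benefit uses the larger dark flank", {
  g <- rd_grid(40, 0.1)
  pat <- light_single_line(g, 5.6, center = 10)
  tr <- phenomenological_lawn(g, t_points = c(0, 1))
  row <- cooperator_benefit(tr, pat, 1)
  expect_identical(row$B, 0)
  expect_true(is.na(row$lambda))
})

test_that("cutoff_wavelengths interpolates linearly and flags edge cases", {
  # triangular benefit: peak 100 at 15 mm, zero at 5 and 25 mm
  sweep <- data.frame(lambda = c(5, 10, 15, 20, 25),
                      B = c(0, 50, 100, 50, 0))
  co <- cutoff_wavelengths(sweep, fraction = 0.7)
  # hand interpolation: 70 crossed between (10,50)-(15,100) at 12 mm
  # and between (15,100)-(20,50) at 18 mm
  expect_equal(co$lambda_minus, 12)
  expect_equal(co$lambda_plus, 18)
  expect_equal(co$B_max, 100)
  expect_true(co$unimodal)
  # independent oracle via approx() on each flank
  left <- stats::approx(c(50, 100), c(10, 15), xout = 70)$y
  right <- stats::approx(c(100, 50), c(15, 20), xout = 70)$y
  expect_equal(co$lambda_minus, left)
  expect_equal(co$lambda_plus, right)

  # invariance to positive rescaling and to reindexing
  co2 <- cutoff_wavelengths(transform(sweep, B = B * 3.7))
  expect_equal(co2$lambda_minus, co$lambda_minus)
  expect_equal(co2$lambda_plus, co$lambda_plus)
  co3 <- cutoff_wavelengths(sweep[sample(5), ])
  expect_equal(co3$lambda_minus, co$lambda_minus)

  # constant benefit: both sides undefined
  cc <- cutoff_wavelengths(data.frame(lambda = 1:5, B = rep(4, 5)))
  expect_true(is.na(cc$lambda_minus) && is.na(cc$lambda_plus))
  expect_match(cc$reason["minus"], "no crossing")
  # monotone benefit: right side undefined, flagged
  cm <- cutoff_wavelengths(data.frame(lambda = 1:5, B = 1:5 * 10))
  expect_true(is.na(cm$lambda_plus))
  expect_error(cutoff_wavelengths(sweep[1:3, ]), "at least 4")
})
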