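# shared fixtures: tiny grids and convenience expectations

tiny_grid <- function(extent = 4, spacing = 0.5, bc = "noflux") {
  rd_grid(extent, spacing = spacing, bc = bc)
}

# relative-difference expectation (b is the reference)
expect_rel <- function(a, b, tol) {
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-300)), tol)
}

# parameters with all reactions switched off (pure transport)
inert_params <- function(...) {
  kinetic_params(k_cat = 0, k_spont = 0, V_hi = 0, V_lo = 0, mu_max = 0,
                 alpha_coop = 0, alpha_cheat = 0, ...)
}
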