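#' Simulation state of the sucrose cooperation model
#'
#' Holds the five coupled fields at one time point: sucrose `S` and hexose
#' `H` concentrations (mol/L), periplasmic invertase `E` (mol of enzyme per
#' litre of gel), cell density `N` (CFU/mL) and the cumulative hexose
#' uptake `U` (mol/L, a diagnostic used for the sugar mass audit
#' 2S + H + U = const).
#'
#' @param grid an [rd_grid()] shared by all fields.
#' @param S,H,E,N,U fields (scalar values are recycled over the grid).
#' @param t time, hours.
#' @return Object of class `sim_state`.
#' @examples
#' st <- sim_state(rd_grid(10), S = 29.2e-3, N = 1e6)
#' @export
sim_state <- function(grid, S = 0, H = 0, E = 0, N = 0, U = 0, t = 0) {
  stopifnot(inherits(grid, "rd_grid"))
  expand <- function(f, nm) {
    if (length(f) == 1L) {
      f <- if (grid$ndim == 1L) rep(f, grid$n[1]) else
        matrix(f, grid$n[1], grid$n[2])
    }
    check_field(f, grid, nm)
    if (any(!is.finite(f)) || any(f < 0))
      stop(nm, ": state fields must be finite and non-negative")
    f
  }
  structure(list(t = t, S = expand(S, "S"), H = expand(H, "H"),
                 E = expand(E, "E"), N = expand(N, "N"), U = expand(U, "U"),
                 grid = grid),
            class = "sim_state")
}

#' Default initial condition: fresh sucrose gel with a homogeneous lawn
#'
#' 1% w/v sucrose = 10 g/L / 342.30 g/mol = 29.2 mM; no hexose, no
#' pre-formed invertase; a uniform lawn at `N0` CFU/mL.
#'
#' @param grid an [rd_grid()].
#' @param S0 initial sucrose, mol/L.
#' @param N0 initial lawn density, CFU/mL.
#' @return A [sim_state()].
#' @export
initial_state <- function(grid, S0 = 10 / 342.30, N0 = 1e6) {
  sim_state(grid, S = S0, N = N0)
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state at t = %g h on a %dD grid (%s cells)\n",
              x$t, x$grid$ndim, paste(x$grid$n, collapse = " x ")))
  for (f in c("S", "H", "E", "N", "U"))
    cat(sprintf("  %s: [%.4g, %.4g]\n", f, min(x[[f]]), max(x[[f]])))
  invisible(x)
}

# -- local (non-spatial) reaction terms ----------------------------------

#' Sucrose hydrolysis rate
#'
#' Michaelis-Menten invertase catalysis plus optional spontaneous (acid)
#' hydrolysis: `v = k_cat * E * S / (K_S + S) + k_spont * S`.
#'
#' @param S sucrose field, mol/L.
#' @param E invertase field, mol/L of gel.
#' @param p [kinetic_params()].
#' @return Hydrolysis rate field, mol sucrose / L / s.
#' @export
hydrolysis_rate <- function(S, E, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (length(S) != length(E))
    stop("S and E must share one grid")
  if (any(!is.finite(S)) || any(!is.finite(E)) || any(S < 0) || any(E < 0))
    stop("S and E must be finite and non-negative")
  p$k_cat * E * mm_frac(S, p$K_S) + p$k_spont * S
}

# saturating fraction x/(K+x), defined as 0 where both x and K vanish
mm_frac <- function(x, K) {
  d <- K + x
  out <- x / d
  out[d == 0] <- 0
  out
}

#' Hexose uptake rate by the lawn
#'
#' Sum of high- and low-affinity transporter Michaelis-Menten terms,
#' scaled by local cell density:
#' `u = N' * (V_hi H/(K_hi+H) + V_lo H/(K_lo+H))`
#' with `N'` the density in cells per litre of gel.
#'
#' @param H hexose field, mol/L.
#' @param N cell density field, CFU/mL.
#' @param p [kinetic_params()].
#' @return Uptake rate field, mol hexose / L / s; saturates at
#'   `N' * (V_hi + V_lo)` for large `H`.
#' @export
hexose_uptake_rate <- function(H, N, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (length(H) != length(N)) stop("H and N must share one grid")
  if (any(!is.finite(H)) || any(!is.finite(N)))
    stop("H and N must be finite")
  if (any(H < 0) || any(N < 0)) stop("H and N must be non-negative")
  cells_per_litre(N) * (p$V_hi * mm_frac(H, p$K_hi) +
                        p$V_lo * mm_frac(H, p$K_lo))
}

#' Specific growth rate (Monod in hexose)
#'
#' `mu = mu_max * H / (K_H + H)`. The optional carrying-capacity factor
#' `(1 - N/N_max)` is applied by the caller ([local_rhs()]), not here.
#'
#' @param H hexose field, mol/L.
#' @param p [kinetic_params()].
#' @return Specific growth rate field, 1/h, in `[0, mu_max)`.
#' @export
specific_growth_rate <- function(H, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(!is.finite(H)) || any(H < 0)) stop("H must be finite and >= 0")
  p$mu_max * mm_frac(H, p$K_H)
}

#' Invertase production (and decay) rate
#'
#' `dE/dt = alpha(x) * N' - delta_E * E`, with `alpha(x)` the local
#' per-cell production rate set by the illumination pattern (between the
#' dark leak `alpha_cheat` and the induced `alpha_coop`). With the default
#' `delta_E = 0` the enzyme persists, matching its measured stability.
#'
#' @param N cell density field, CFU/mL.
#' @param alpha per-cell production field, mol/s/cell (see [alpha_map()]).
#' @param p [kinetic_params()].
#' @param E invertase field, mol/L (only needed when `delta_E > 0`).
#' @return dE/dt field, mol enzyme / L / s.
#' @export
invertase_production_rate <- function(N, alpha, p, E = 0) {
  stopifnot(inherits(p, "kinetic_params"))
  if (length(alpha) != 1L && length(alpha) != length(N))
    stop("alpha field not aligned with N grid")
  cells_per_litre(N) * alpha - p$delta_E * E
}

#' All local (non-spatial) time derivatives
#'
#' Returns the reaction part of the model, excluding diffusion:
#' \itemize{
#'   \item dS = -v (hydrolysis removes sucrose)
#'   \item dH = 2 phi_leak v - u (each sucrose yields two hexoses; a
#'     fraction `phi_leak` reaches the shared pool, the rest is captured
#'     directly by the producing cell and routed into `U`)
#'   \item dE = alpha N' - delta_E E
#'   \item dN = mu(H) (1 - N/N_max) N
#'   \item dU = u + 2 (1 - phi_leak) v
#' }
#' so that `2 dS + dH + dU = 0` identically (hexose-equivalent
#' conservation). Sugar and enzyme derivatives are returned per hour
#' (per-second rates times 3600) and dN in CFU/mL/h, i.e. ready for the
#' hour-unit solver.
#'
#' @param state a [sim_state()] (or a bare list with fields S,H,E,N,U).
#' @param alpha per-cell invertase production field, mol/s/cell.
#' @param p [kinetic_params()].
#' @return Named list of derivative fields `dS, dH, dE, dN, dU` (per hour).
#' @export
local_rhs <- function(state, alpha, p) {
  with_fields_rhs(state$S, state$H, state$E, state$N, alpha, p)
}

# core RHS on bare fields (hot path: no class checks)
with_fields_rhs <- function(S, H, E, N, alpha, p) {
  v <- (p$k_cat * E * mm_frac(S, p$K_S) + p$k_spont * S) * SECONDS_PER_HOUR
  u <- cells_per_litre(N) *
    (p$V_hi * mm_frac(H, p$K_hi) + p$V_lo * mm_frac(H, p$K_lo)) *
    SECONDS_PER_HOUR
  mu <- p$mu_max * mm_frac(H, p$K_H)
  if (is.finite(p$N_max)) mu <- mu * pmin(pmax(1 - N / p$N_max, 0), 1)
  twophi_v <- 2 * p$phi_leak * v
  list(dS = -v,
       dH = twophi_v - u,
       dE = (cells_per_litre(N) * alpha - p$delta_E * E) * SECONDS_PER_HOUR,
       dN = mu * N,
       dU = u + (2 * v - twophi_v))
}
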