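#' Well-mixed (0D) reference solution
#'
#' Integrates the local kinetics alone -- no diffusion -- with an adaptive
#' Cash-Karp Runge-Kutta 4(5) routine that shares no stepping code with
#' the spatial integrator. A spatially homogeneous problem must agree with
#' [integrate_rd()] to solver tolerance, so this is the independent oracle
#' for the reaction part of the PDE path.
#'
#' @param state0 named numeric vector or list with entries `S`, `H`, `E`,
#'   `N`, `U` (scalars; missing entries default to 0).
#' @param alpha scalar per-cell invertase production rate, mol/s/cell.
#' @param p [kinetic_params()].
#' @param t_end final time, h.
#' @param out_times output times, h (default 101 evenly spaced).
#' @param rtol,atol relative tolerance and absolute tolerance (the latter
#'   scaled by each variable's running magnitude).
#' @return data.frame with columns `t`, `S`, `H`, `E`, `N`, `U`.
#' @examples
#' run_0d(c(S = 29.2e-3, N = 1e6), alpha = 1.8e-24, kinetic_params(),
#'        t_end = 5, out_times = c(0, 5))
#' @export
run_0d <- function(state0, alpha, p, t_end, out_times = NULL,
                   rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(p, "kinetic_params"), length(alpha) == 1L)
  y <- stats::setNames(numeric(5), FIELDS)
  st <- as.list(state0)
  bad <- setdiff(names(st), FIELDS)
  if (length(bad)) stop("unknown state entries: ", paste(bad, collapse = ", "))
  for (f in intersect(names(st), FIELDS)) y[f] <- st[[f]]
  if (any(!is.finite(y)) || any(y < 0))
    stop("state0 must be finite and non-negative")
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(out_times)) out_times <- seq(0, t_end, length.out = 101L)
  out_times <- sort(unique(out_times))
  if (any(out_times < 0) || any(out_times > t_end + 1e-9))
    stop("out_times must lie in [0, t_end]")

  f <- function(y) {
    d <- with_fields_rhs(y[1L], y[2L], y[3L], y[4L], alpha, p)
    c(d$dS, d$dH, d$dE, d$dN, d$dU)
  }

  # Cash-Karp embedded 4(5) tableau
  a2 <- 1 / 5
  a3 <- c(3 / 40, 9 / 40)
  a4 <- c(3 / 10, -9 / 10, 6 / 5)
  a5 <- c(-11 / 54, 5 / 2, -70 / 27, 35 / 27)
  a6 <- c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
  b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

  out <- matrix(NA_real_, nrow = length(out_times), ncol = 5,
                dimnames = list(NULL, FIELDS))
  t <- 0
  oi <- 1L
  while (oi <= length(out_times) && out_times[oi] <= 1e-12) {
    out[oi, ] <- y
    oi <- oi + 1L
  }
  dt <- t_end / 1e4
  dt_floor <- t_end * 1e-13
  while (t < t_end - 1e-12) {
    t_stop <- if (oi <= length(out_times)) out_times[oi] else t_end
    h <- min(dt, t_stop - t)
    k1 <- f(y)
    k2 <- f(y + h * a2 * k1)
    k3 <- f(y + h * (a3[1] * k1 + a3[2] * k2))
    k4 <- f(y + h * (a4[1] * k1 + a4[2] * k2 + a4[3] * k3))
    k5 <- f(y + h * (a5[1] * k1 + a5[2] * k2 + a5[3] * k3 + a5[4] * k4))
    k6 <- f(y + h * (a6[1] * k1 + a6[2] * k2 + a6[3] * k3 + a6[4] * k4 +
                       a6[5] * k5))
    K <- cbind(k1, k2, k3, k4, k5, k6)
    y5 <- y + h * as.numeric(K %*% b5)
    y4 <- y + h * as.numeric(K %*% b4)
    if (!all(is.finite(y5)))
      stop("numerical failure in run_0d at t = ", signif(t, 6), " h")
    refc <- max(abs(y[c(1L, 2L, 5L)]), 1e-300)
    refE <- max(abs(y[3L]),
                p$alpha_coop * cells_per_litre(max(y[4L], 1)) *
                  SECONDS_PER_HOUR * 1e-6, 1e-300)
    refN <- max(abs(y[4L]), 1)
    sc <- atol * c(refc, refc, refE, refN, refc) +
      rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {
      y <- pmax(y5, 0)
      t <- t + h
      if (oi <= length(out_times) && abs(t - out_times[oi]) < 1e-9) {
        out[oi, ] <- y
        oi <- oi + 1L
      }
      dt <- h * min(5, max(0.2, 0.9 * err^(-1 / 5)))
    } else {
      dt <- h * max(0.1, 0.9 * err^(-1 / 5))
      if (dt < dt_floor)
        stop("step size underflow in run_0d at t = ", signif(t, 6), " h")
    }
  }
  data.frame(t = out_times, out)
}
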