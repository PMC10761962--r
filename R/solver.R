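#' @title Reaction-diffusion integrator
#' @description Method-of-lines integration of the sucrose cooperation
#'   model. Sucrose and hexose diffuse; invertase, cells and the uptake
#'   tally are immobile (cells are gel-trapped microcolonies and the
#'   enzyme is retained in the periplasm). Diffusion is advanced by
#'   unconditionally stable Crank-Nicolson half-steps (Strang splitting,
#'   sparse Cholesky factors cached per step size) and the stiff local
#'   kinetics by an embedded Bogacki-Shampine RK23 pair with proportional
#'   step-size control, so accuracy is tolerance-controlled rather than
#'   scheme-named.
#' @name solver
NULL

FIELDS <- c("S", "H", "E", "N", "U")

default_control <- function() {
  list(rtol = 1e-6, atol = 1e-9, max_dt = 0.05, min_dt_factor = 2^-40)
}

#' Integrate the reaction-diffusion model
#'
#' @param state0 initial [sim_state()] (non-negative fields).
#' @param alpha per-cell invertase production field (mol/s/cell), or a
#'   `light_pattern` (then converted with the default binary [alpha_map()]).
#' @param p [kinetic_params()].
#' @param t_end final time, hours.
#' @param out_times times (h) at which to store snapshots; default 25
#'   evenly spaced times from `state0$t` to `t_end`.
#' @param control list overriding `rtol`, `atol` (relative to each field's
#'   running magnitude), `max_dt` (h), `min_dt_factor`.
#' @return Object of class `trajectory`: `times`, `states` (list of
#'   [sim_state()]), `grid`, `params`, `pattern_meta`, `diagnostics`
#'   (steps, rejected steps, clipped mass per field, minimum field values).
#' @examples
#' g <- rd_grid(10, spacing = 0.5)
#' pat <- light_uniform(g)
#' tr <- integrate_rd(initial_state(g), pat, kinetic_params(), t_end = 2,
#'                    out_times = c(1, 2))
#' @export
integrate_rd <- function(state0, alpha, p, t_end, out_times = NULL,
                         control = list()) {
  stopifnot(inherits(state0, "sim_state"), inherits(p, "kinetic_params"))
  ctrl <- utils::modifyList(default_control(), control)
  grid <- state0$grid
  pattern_meta <- NULL
  if (inherits(alpha, "light_pattern")) {
    pattern_meta <- alpha$meta
    alpha <- alpha_map(alpha, p)
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, n_cells(grid))
  if (length(alpha) != n_cells(grid))
    stop("alpha field not aligned with the state grid")
  a <- as.numeric(alpha)
  t0 <- state0$t
  if (t_end <= t0) stop("t_end must exceed the initial time")
  if (is.null(out_times)) out_times <- seq(t0, t_end, length.out = 25L)
  out_times <- sort(unique(out_times))
  if (any(out_times < t0 - 1e-12) || any(out_times > t_end + 1e-9))
    stop("out_times must lie in [state0$t, t_end]")

  n <- n_cells(grid)
  Y <- vapply(FIELDS, function(f) as.numeric(state0[[f]]), numeric(n))
  Y <- matrix(Y, nrow = n, dimnames = list(NULL, FIELDS))

  iu <- internal_units(p)
  Dv <- c(S = iu$D_S_mm2h, H = iu$D_H_mm2h)
  L <- laplacian_matrix(grid)
  chol_cache <- new.env(parent = emptyenv())
  cn_solve <- function(f, h, y) {
    # one Crank-Nicolson step of length h for field f
    key <- sprintf("%s_%a", f, h)
    ch <- chol_cache[[key]]
    if (is.null(ch)) {
      A <- Matrix::Diagonal(n) - (h / 2 * Dv[[f]]) * L
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(A))
      chol_cache[[key]] <- ch
    }
    rhs <- y + (h / 2 * Dv[[f]]) * as.numeric(L %*% y)
    as.numeric(Matrix::solve(ch, rhs))
  }
  diffuse <- function(Y, h) {
    for (f in c("S", "H")) if (Dv[[f]] > 0) Y[, f] <- cn_solve(f, h, Y[, f])
    Y
  }
  rhs_mat <- function(Y) {
    d <- with_fields_rhs(Y[, 1L], Y[, 2L], Y[, 3L], Y[, 4L], a, p)
    matrix(c(d$dS, d$dH, d$dE, d$dN, d$dU), nrow = n)
  }
  react_bs23 <- function(Y, h) {
    k1 <- rhs_mat(Y)
    k2 <- rhs_mat(Y + (h / 2) * k1)
    k3 <- rhs_mat(Y + (3 * h / 4) * k2)
    Yn <- Y + h * ((2 / 9) * k1 + (1 / 3) * k2 + (4 / 9) * k3)
    k4 <- rhs_mat(Yn)
    est <- h * ((-5 / 72) * k1 + (1 / 12) * k2 + (1 / 9) * k3 - (1 / 8) * k4)
    # per-field error scales; S/H/U share concentration units so they share
    # one reference, E and N get floors tied to enzyme production and to
    # 1 CFU/mL so all-zero fields do not collapse the scale
    refc <- max(abs(Y[, c(1L, 2L, 5L)]), .Machine$double.xmin)
    refE <- max(abs(Y[, 3L]),
                p$alpha_coop * cells_per_litre(max(Y[, 4L], 1)) *
                  SECONDS_PER_HOUR * 1e-6,
                .Machine$double.xmin)
    refN <- max(abs(Y[, 4L]), 1)
    ref <- c(refc, refc, refE, refN, refc)
    sc <- rep(ctrl$atol * ref, each = n) + ctrl$rtol * abs(Y)
    list(Y = Yn, err = sqrt(mean((est / sc)^2)))
  }

  dV <- grid$spacing^grid$ndim
  diag_ <- list(steps = 0L, rejected = 0L,
                clipped = stats::setNames(numeric(5), FIELDS),
                min_value = stats::setNames(rep(Inf, 5), FIELDS),
                dt_min = Inf, dt_max = 0)
  snaps <- vector("list", length(out_times))
  take_snap <- function(i, t, Y) {
    fl <- lapply(seq_along(FIELDS), function(j) {
      y <- Y[, j]
      if (grid$ndim == 2L) dim(y) <- grid$n
      y
    })
    names(fl) <- FIELDS
    structure(c(list(t = t), fl, list(grid = grid)), class = "sim_state")
  }
  oi <- 1L
  while (oi <= length(out_times) && out_times[oi] <= t0 + 1e-12) {
    snaps[[oi]] <- take_snap(oi, out_times[oi], Y)
    oi <- oi + 1L
  }

  t <- t0
  dt <- ctrl$max_dt / 16
  dt_floor <- ctrl$max_dt * ctrl$min_dt_factor
  ladder <- function(x) ctrl$max_dt / 2^max(0, ceiling(log2(ctrl$max_dt / x)))
  while (t < t_end - 1e-12) {
    t_stop <- if (oi <= length(out_times)) out_times[oi] else t_end
    dt_try <- min(dt, t_stop - t)
    Yd <- diffuse(Y, dt_try / 2)
    st <- react_bs23(Yd, dt_try)
    if (!all(is.finite(st$Y)))
      stop("numerical failure: non-finite state at t = ", signif(t, 6), " h")
    if (st$err <= 1) {
      Yn <- diffuse(st$Y, dt_try / 2)
      neg <- Yn < 0
      if (any(neg)) {
        diag_$clipped <- diag_$clipped + colSums(matrix(
          ifelse(neg, -Yn, 0), nrow = n)) * dV
        Yn[neg] <- 0
      }
      diag_$min_value <- pmin(diag_$min_value, apply(Yn, 2, min))
      Y <- Yn
      t <- t + dt_try
      diag_$steps <- diag_$steps + 1L
      diag_$dt_min <- min(diag_$dt_min, dt_try)
      diag_$dt_max <- max(diag_$dt_max, dt_try)
      if (abs(t - t_stop) < 1e-9 && oi <= length(out_times) &&
          abs(t - out_times[oi]) < 1e-9) {
        snaps[[oi]] <- take_snap(oi, out_times[oi], Y)
        oi <- oi + 1L
      }
      dt <- ladder(dt_try * min(4, max(0.3, 0.85 * st$err^(-1 / 3))))
    } else {
      diag_$rejected <- diag_$rejected + 1L
      dt <- dt_try * max(0.1, 0.85 * st$err^(-1 / 3))
      if (dt < dt_floor)
        stop("step size underflow at t = ", signif(t, 6),
             " h (err = ", signif(st$err, 3), ")")
    }
  }

  structure(list(times = out_times, states = snaps, grid = grid,
                 params = p, pattern_meta = pattern_meta,
                 alpha = a, diagnostics = diag_),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("trajectory: %d snapshots over t = [%g, %g] h ",
                     "(%d steps, %d rejected, dt in [%.3g, %.3g] h)\n"),
              length(x$times), min(x$times), max(x$times),
              d$steps, d$rejected, d$dt_min, d$dt_max))
  cat(sprintf("  clipped mass: %s\n",
              paste(sprintf("%s=%.3g", FIELDS, d$clipped), collapse = " ")))
  invisible(x)
}

#' Extract one field at one time from a trajectory
#'
#' @param traj a `trajectory`.
#' @param field one of `"S"`, `"H"`, `"E"`, `"N"`, `"U"`.
#' @param t requested time, h (must be among the stored times, otherwise
#'   the nearest stored time is used with a warning).
#' @return The stored field (vector or matrix).
#' @export
traj_field <- function(traj, field = "N", t = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  field <- match.arg(field, FIELDS)
  i <- traj_time_index(traj, t)
  traj$states[[i]][[field]]
}

traj_time_index <- function(traj, t) {
  if (is.null(t)) return(length(traj$times))
  i <- which.min(abs(traj$times - t))
  if (abs(traj$times[i] - t) > 1e-6)
    warning(sprintf("t = %g h not among stored times; using nearest %g h",
                    t, traj$times[i]))
  i
}

#' Domain total of the conserved hexose-equivalent 2S + H + U
#'
#' Under no-flux boundaries this integral is an exact invariant of the
#' model and a sensitive end-to-end check of the integrator.
#'
#' @param traj a `trajectory`.
#' @return Numeric vector (one total per stored time), in mol/L * mm^ndim.
#' @export
sugar_total <- function(traj) {
  dV <- traj$grid$spacing^traj$grid$ndim
  vapply(traj$states, function(s) sum(2 * s$S + s$H + s$U) * dV, numeric(1))
}
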