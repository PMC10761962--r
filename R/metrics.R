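#' @title Quantitative readouts
#' @description Growth curves, maximal growth rate, final density, spatial
#'   density profiles, the cooperator benefit B (density at the center of
#'   an illuminated stripe minus density at the center of a dark stripe)
#'   and the bandpass cut-off wavelengths at which B crosses a fraction of
#'   its maximum.
#' @name metrics
NULL

#' Mean cell density over a region of interest, per stored time
#'
#' @param traj a `trajectory`.
#' @param roi region in mm: `c(xmin, xmax)` in 1D,
#'   `c(xmin, xmax, ymin, ymax)` in 2D; `NULL` = whole domain.
#' @return data.frame with columns `t` (h) and `N` (CFU/mL).
#' @export
mean_density_curve <- function(traj, roi = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  g <- traj$grid
  x <- grid_coords(g, 1L)
  if (is.null(roi)) roi <- c(0, g$extent[1], 0, g$extent[min(2, g$ndim)])
  ix <- which(x >= roi[1] & x <= roi[2])
  if (!length(ix)) stop("empty roi")
  if (g$ndim == 2L) {
    if (length(roi) < 4L) roi <- c(roi, 0, g$extent[2])
    y <- grid_coords(g, 2L)
    iy <- which(y >= roi[3] & y <= roi[4])
    if (!length(iy)) stop("empty roi")
    N <- vapply(traj$states, function(s) mean(s$N[ix, iy]), numeric(1))
  } else {
    N <- vapply(traj$states, function(s) mean(s$N[ix]), numeric(1))
  }
  data.frame(t = traj$times, N = N)
}

#' Maximal specific growth rate from a density curve
#'
#' Fits a smoothing spline to ln(N) versus time (default 15 effective
#' degrees of freedom, the convention used for plate-reader growth
#' curves) and returns the maximum of its derivative. Invariant under
#' rescaling of N by a positive constant. A centered finite-difference
#' `"window"` smoother is provided as a fallback for short or irregular
#' curves.
#'
#' @param curve data.frame with columns `t` (h) and `N` (> 0, CFU/mL or
#'   any proportional unit).
#' @param smoother `"spline"` or `"window"`.
#' @param df effective degrees of freedom of the spline.
#' @param window half-width (number of points) of the window smoother.
#' @return Maximal growth rate, 1/h.
#' @export
max_growth_rate <- function(curve, smoother = c("spline", "window"),
                            df = 15, window = 3L) {
  smoother <- match.arg(smoother)
  t <- curve$t
  N <- curve$N
  if (length(t) < 10L) stop("need at least 10 time points")
  if (any(!is.finite(N)) || any(N <= 0))
    stop("densities must be positive; floor the curve before calling")
  lN <- log(N)
  if (smoother == "spline") {
    fit <- stats::smooth.spline(t, lN, df = min(df, length(unique(t)) - 1))
    tt <- seq(min(t), max(t), length.out = max(200L, 4L * length(t)))
    max(stats::predict(fit, tt, deriv = 1)$y)
  } else {
    k <- max(1L, as.integer(window))
    n <- length(t)
    i0 <- pmax(seq_len(n) - k, 1L)
    i1 <- pmin(seq_len(n) + k, n)
    max((lN[i1] - lN[i0]) / (t[i1] - t[i0]))
  }
}

#' Final (stationary-phase) density of a growth curve
#'
#' Mean density over the trailing `window` hours, provided the curve has
#' plateaued there (relative change across the window below `slope_tol`);
#' otherwise the end value is returned with a warning and the result
#' carries `attr(, "plateau") = FALSE`.
#'
#' @param curve data.frame with `t` (h) and `N`.
#' @param window trailing window, h.
#' @param slope_tol maximal relative change over the window still counted
#'   as a plateau.
#' @return Final density (same unit as `N`), with attribute `plateau`.
#' @export
final_density <- function(curve, window = 5, slope_tol = 0.05) {
  t <- curve$t
  N <- curve$N
  sel <- t >= max(t) - window
  if (sum(sel) < 2L) sel[length(sel)] <- TRUE
  Nw <- N[sel]
  tw <- t[sel]
  rel <- if (mean(Nw) > 0 && diff(range(tw)) > 0)
    abs(stats::coef(stats::lm(Nw ~ tw))[2]) * diff(range(tw)) / mean(Nw)
  else 0
  plateau <- rel <= slope_tol
  if (!plateau) {
    warning("no plateau reached; returning end-of-run density")
    return(structure(N[length(N)], plateau = FALSE))
  }
  structure(mean(Nw), plateau = TRUE)
}

#' Spatial density profile at one time
#'
#' @param traj a `trajectory`.
#' @param t time, h (nearest stored time with a warning if absent).
#' @param band averaging band: in 2D, `c(ymin, ymax)` over which the
#'   transverse mean is taken; in 1D ignored except for restricting to
#'   `c(xmin, xmax)` when given as a 2-vector within the domain.
#' @param field field to profile (default `"N"`).
#' @return data.frame with `x` (mm, cell centers) and the field column.
#' @export
density_profile <- function(traj, t = NULL, band = NULL, field = "N") {
  stopifnot(inherits(traj, "trajectory"))
  g <- traj$grid
  f <- traj_field(traj, field, t)
  x <- grid_coords(g, 1L)
  if (g$ndim == 2L) {
    y <- grid_coords(g, 2L)
    iy <- if (is.null(band)) seq_along(y) else
      which(y >= band[1] & y <= band[2])
    if (!length(iy)) stop("band outside domain")
    v <- rowMeans(f[, iy, drop = FALSE])
  } else {
    v <- f
    if (!is.null(band)) {
      ix <- which(x >= band[1] & x <= band[2])
      if (!length(ix)) stop("band outside domain")
      x <- x[ix]
      v <- v[ix]
    }
  }
  out <- data.frame(x = x, v = v)
  names(out)[2] <- field
  out
}

# stripe centers (mm) from pattern metadata; centers are defined by the
# projected pattern, never inferred from the density field
stripe_centers <- function(meta, extent) {
  gen <- meta$generator
  if (identical(gen, "periodic_lines")) {
    lam <- meta$lambda
    duty <- meta$duty
    k <- 0:floor(extent / lam)
    lit <- (k + duty / 2) * lam
    dark <- (k + (1 + duty) / 2) * lam
    list(lit = lit[lit < extent], dark = dark[dark < extent])
  } else if (identical(gen, "single_line")) {
    lo <- meta$center - meta$w / 2
    hi <- meta$center + meta$w / 2
    flanks <- rbind(c(0, max(lo, 0)), c(min(hi, extent), extent))
    widths <- flanks[, 2] - flanks[, 1]
    if (max(widths) <= 0) stop("pattern has no dark region")
    fk <- flanks[which.max(widths), ]
    list(lit = meta$center, dark = mean(fk))
  } else {
    stop("cooperator benefit requires a striped pattern ",
         "(uniform or raster patterns have no lit/dark stripe centers)")
  }
}

#' Cooperator benefit at one time
#'
#' B = N(center of an illuminated stripe) - N(center of a dark stripe),
#' the study's proxy for how much cooperators out-grow cheaters. Stripe
#' centers come from the pattern metadata (the experimental regions of
#' interest were defined by the projected pattern); among the candidate
#' stripes the one closest to the domain center is used, preferring
#' interior stripes over boundary-truncated ones.
#'
#' @param traj a `trajectory`.
#' @param pattern the `light_pattern` that was projected (or its `meta`).
#' @param t evaluation time, h.
#' @return One-row data.frame: `lambda` (mm; NA for a single line), `B`,
#'   `N_lit_center`, `N_dark_center` (CFU/mL), `t_eval` (h).
#' @export
cooperator_benefit <- function(traj, pattern, t = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  meta <- if (inherits(pattern, "light_pattern")) pattern$meta else pattern
  g <- traj$grid
  ctr <- stripe_centers(meta, g$extent[1])
  N <- traj_field(traj, "N", t)
  if (g$ndim == 2L) N <- rowMeans(N)
  x <- grid_coords(g, 1L)
  at <- function(pos) {
    pos <- pos[which.min(abs(pos - g$extent[1] / 2))]  # most interior
    N[which.min(abs(x - pos))]
  }
  n_lit <- at(ctr$lit)
  n_dark <- at(ctr$dark)
  i <- traj_time_index(traj, t)
  data.frame(lambda = if (is.null(meta$lambda)) NA_real_ else meta$lambda,
             B = n_lit - n_dark, N_lit_center = n_lit,
             N_dark_center = n_dark, t_eval = traj$times[i])
}

#' Cooperator benefit versus pattern wavelength
#'
#' Runs one simulation per wavelength (constant duty cycle, so mean
#' illumination and cooperator frequency stay fixed) and tabulates the
#' cooperator benefit at `t_eval`. The domain covers `periods` full
#' wavelengths; periodic boundaries are the natural unit cell for an
#' infinite stripe array.
#'
#' @param lambdas wavelengths to sweep, mm (each an integer multiple of
#'   `spacing`).
#' @param p [kinetic_params()].
#' @param duty lit fraction (default 0.25: 75% dark / 25% illuminated).
#' @param t_eval evaluation time, h (default 40 h).
#' @param I0 intensity, mW/cm^2.
#' @param spacing grid spacing, mm.
#' @param periods number of wavelengths in the domain (>= 2).
#' @param bc boundary condition for the sweep domain.
#' @param S0,N0 initial sucrose (mol/L) and lawn density (CFU/mL).
#' @param control solver control list, see [integrate_rd()].
#' @return Object of classes `benefit_sweep`/`data.frame`, one row per
#'   wavelength, ordered by `lambda`.
#' @export
benefit_sweep <- function(lambdas, p = kinetic_params(), duty = 0.25,
                          t_eval = 40, I0 = DEVICE_I_MAX, spacing = 0.1,
                          periods = 2L, bc = "periodic",
                          S0 = 10 / 342.30, N0 = 1e6, control = list()) {
  stopifnot(length(lambdas) >= 1L, periods >= 2L)
  lambdas <- sort(lambdas)
  rows <- lapply(lambdas, function(lam) {
    g <- rd_grid(periods * lam, spacing = spacing, bc = bc)
    pat <- light_periodic_lines(g, lam, duty = duty, I0 = I0)
    tr <- integrate_rd(initial_state(g, S0 = S0, N0 = N0), pat, p,
                       t_end = t_eval, out_times = c(0, t_eval),
                       control = control)
    cooperator_benefit(tr, pat, t = t_eval)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("benefit_sweep", "data.frame")
  out
}

#' Bandpass cut-off wavelengths of a benefit sweep
#'
#' The benefit curve B(lambda) is bell-shaped: too-fine patterns
#' homogenize (cheaters reach the hexoses as easily as cooperators) and
#' too-coarse patterns starve the stripe interior of sucrose. The
#' cut-offs are the wavelengths at which B crosses `fraction` (default
#' 70%) of its maximum, read off by linear interpolation between sampled
#' wavelengths; a missing crossing on either side is reported as `NA`
#' with a reason.
#'
#' @param sweep a [benefit_sweep()] (or data.frame with `lambda`, `B`).
#' @param fraction threshold fraction of the maximal benefit.
#' @return Object of class `cutoff_pair`: `lambda_minus`, `lambda_plus`
#'   (mm or NA), `B_max`, `lambda_peak`, `fraction`, `reason` (character,
#'   per side), `unimodal` (logical).
#' @export
cutoff_wavelengths <- function(sweep, fraction = 0.7) {
  lam <- sweep$lambda
  B <- sweep$B
  if (length(lam) < 4L) stop("need at least 4 wavelengths")
  o <- order(lam)
  lam <- lam[o]
  B <- B[o]
  if (anyDuplicated(lam)) stop("duplicate wavelengths")
  imax <- which.max(B)
  B_max <- B[imax]
  thr <- fraction * B_max
  tol <- 1e-3 * max(abs(B_max), .Machine$double.xmin)
  d <- diff(B)
  sign_changes <- sum(diff(sign(d[abs(d) > tol])) != 0)
  unimodal <- sign_changes <= 1L
  if (!unimodal)
    warning("benefit curve is not unimodal up to noise; ",
            "cut-offs may be unreliable")
  reason <- c(minus = "", plus = "")
  cross <- function(i) lam[i] + (thr - B[i]) / (B[i + 1] - B[i]) *
    (lam[i + 1] - lam[i])
  lam_minus <- NA_real_
  if (imax == 1L || all(B[seq_len(imax - 1L)] >= thr)) {
    reason["minus"] <- "no crossing left of the peak (sweep range too narrow)"
  } else {
    for (i in seq_len(imax - 1L))
      if (B[i] < thr && B[i + 1L] >= thr) { lam_minus <- cross(i); break }
  }
  lam_plus <- NA_real_
  n <- length(B)
  if (imax == n || all(B[(imax + 1L):n] >= thr)) {
    reason["plus"] <- "no crossing right of the peak (sweep range too narrow)"
  } else {
    for (i in (n - 1L):imax)
      if (B[i] >= thr && B[i + 1L] < thr) { lam_plus <- cross(i); break }
  }
  if (B_max <= 0) {
    lam_minus <- lam_plus <- NA_real_
    reason[] <- "benefit never positive"
  }
  structure(list(lambda_minus = lam_minus, lambda_plus = lam_plus,
                 B_max = B_max, lambda_peak = lam[imax],
                 fraction = fraction, reason = reason, unimodal = unimodal),
            class = "cutoff_pair")
}

#' @export
print.cutoff_pair <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3g mm", v)
  cat(sprintf(paste0("bandpass cut-offs at %.0f%% of B_max = %.4g CFU/mL ",
                     "(peak at %.3g mm):\n  lambda- = %s\n  lambda+ = %s\n"),
              100 * x$fraction, x$B_max, x$lambda_peak,
              fmt(x$lambda_minus), fmt(x$lambda_plus)))
  for (s in names(x$reason))
    if (nzchar(x$reason[[s]])) cat("  note (", s, "): ", x$reason[[s]], "\n",
                                   sep = "")
  invisible(x)
}
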