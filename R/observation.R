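#' @title Synthetic scanner observation model
#' @description Forward model turning simulated cell-density fields into
#'   flatbed-scanner-like grayscale frames (monotone calibration curve,
#'   optical blur, additive noise, quantization) and the inverse pipeline
#'   (background subtraction, calibration inversion) used to analyse such
#'   frames. The generator emulates a homogeneous lawn of gel-embedded
#'   microcolonies imaged from below; it exists so the whole analysis
#'   pipeline can be exercised without experimental data.
#' @name observation
NULL

#' Scanner calibration curve (density to gray level)
#'
#' Monotone saturating map
#' `intensity = I_bg + a * log10(1 + N / N_ref)`, clipped to the bit
#' range. The logarithmic form mimics how scattering from increasingly
#' dense microcolony lawns saturates scanner response; its parameters are
#' the synthetic module's own ground truth (correctness of the pipeline
#' is closure of forward and inverse, not matching any real instrument).
#'
#' @param I_bg background gray level of a cell-free gel.
#' @param a gain, gray levels per decade of density.
#' @param N_ref reference density, CFU/mL.
#' @param bits bit depth of the scanner (default 16).
#' @param N_cal_max upper end of the calibrated density range, CFU/mL.
#' @return Object of class `calibration_curve` with `forward(N)` and
#'   `inverse(gray)` closures (inverse acts on background-subtracted
#'   levels).
#' @export
calibration_curve <- function(I_bg = 1500, a = 12000, N_ref = 1e6,
                              bits = 16L, N_cal_max = 1e10) {
  stopifnot(a > 0, N_ref > 0, I_bg >= 0, bits %in% c(8L, 16L))
  gmax <- 2^bits - 1
  structure(list(I_bg = I_bg, a = a, N_ref = N_ref, bits = bits,
                 gmax = gmax, N_cal_max = N_cal_max,
                 forward = function(N) I_bg + a * log10(1 + N / N_ref),
                 inverse = function(dg) N_ref * (10^(dg / a) - 1)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("calibration: gray = %g + %g*log10(1 + N/%g), ",
                     "%d-bit, calibrated to %.3g CFU/mL\n"),
              x$I_bg, x$a, x$N_ref, x$bits, x$N_cal_max))
  invisible(x)
}

#' Write a calibration curve as a small CSV (gray level vs CFU/mL)
#'
#' @param calib a [calibration_curve()].
#' @param file output path.
#' @param n number of tabulated densities.
#' @return Invisibly, the written data.frame.
#' @export
write_calibration_csv <- function(calib, file, n = 50L) {
  N <- c(0, 10^seq(3, log10(calib$N_cal_max), length.out = n - 1L))
  df <- data.frame(gray = calib$forward(N), cfu_per_ml = N)
  hdr <- sprintf("# calibration I_bg=%g a=%g N_ref=%g bits=%d",
                 calib$I_bg, calib$a, calib$N_ref, calib$bits)
  writeLines(c(hdr, "gray,cfu_per_ml",
               sprintf("%.17g,%.17g", df$gray, df$cfu_per_ml)), file)
  invisible(df)
}

#' Read a calibration curve written by [write_calibration_csv()]
#'
#' @param file path to the CSV.
#' @return A [calibration_curve()].
#' @export
read_calibration_csv <- function(file) {
  hdr <- readLines(file, n = 1L)
  kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[0-9.eE+-]+", hdr))[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  calibration_curve(I_bg = vals[["I_bg"]], a = vals[["a"]],
                    N_ref = vals[["N_ref"]], bits = as.integer(vals[["bits"]]))
}

# separable Gaussian blur with reflected edges; sigma in pixels
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    if (2 * r + 1 > 2 * n) stop("blur kernel wider than domain")
    ext <- c(rev(v[seq_len(r)]), v, rev(v[n - seq_len(r) + 1L]))
    as.numeric(stats::filter(ext, k, sides = 2))[r + seq_len(n)]
  }
  if (is.matrix(img) && all(dim(img) > 1L)) {
    img <- apply(img, 2, blur1)
    t(apply(img, 1, blur1))
  } else {
    was_mat <- is.matrix(img)
    out <- blur1(as.numeric(img))
    if (was_mat) dim(out) <- dim(img)
    out
  }
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Render a density field as a scanner frame
#'
#' Applies the calibration curve, Gaussian optical blur, additive
#' Gaussian read noise and quantization to the scanner bit depth.
#' Deterministic for a given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param N density field (vector or matrix), CFU/mL.
#' @param calib a [calibration_curve()].
#' @param psf_sigma optical blur width, mm.
#' @param noise_sd read-noise standard deviation, gray levels.
#' @param seed integer seed (mandatory when `noise_sd > 0`).
#' @param spacing pixel pitch of the field, mm.
#' @return Integer frame (same shape as `N`) in `[0, 2^bits - 1]`.
#' @export
density_to_image <- function(N, calib, psf_sigma = 0, noise_sd = 0,
                             seed = NULL, spacing = 0.1) {
  stopifnot(inherits(calib, "calibration_curve"))
  if (any(N < 0)) stop("N must be non-negative")
  g <- calib$forward(N)
  g <- gaussian_blur(g, psf_sigma / spacing)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    g <- g + with_seed(seed, stats::rnorm(length(g), sd = noise_sd))
  }
  q <- round(pmin(pmax(g, 0), calib$gmax))
  storage.mode(q) <- "integer"
  if (is.matrix(N)) dim(q) <- dim(N)
  q
}

#' Invert a scanner frame back to a density field
#'
#' Subtracts the background frame (the pre-growth scan), clamps negative
#' differences to zero and inverts the calibration curve. Pixels at
#' sensor saturation or mapping beyond the calibrated density range are
#' clamped and their fraction reported in the `flagged_fraction`
#' attribute.
#'
#' @param frame integer frame from the scanner (or [density_to_image()]).
#' @param calib a [calibration_curve()].
#' @param background_frame frame to subtract; `NULL` subtracts the
#'   calibration's cell-free level `I_bg`.
#' @return Density field, CFU/mL, with attribute `flagged_fraction`.
#' @export
image_to_density <- function(frame, calib, background_frame = NULL) {
  stopifnot(inherits(calib, "calibration_curve"))
  if (is.null(background_frame)) {
    dg <- frame - calib$I_bg
  } else {
    if (length(frame) != length(background_frame))
      stop("frame and background_frame shapes differ")
    dg <- frame - background_frame
  }
  flagged <- frame >= calib$gmax
  dg <- pmax(dg, 0)
  N <- calib$inverse(dg)
  over <- N > calib$N_cal_max
  N[over] <- calib$N_cal_max
  flagged <- flagged | over
  out <- pmax(N, 0)
  if (is.matrix(frame)) dim(out) <- dim(frame)
  attr(out, "flagged_fraction") <- mean(flagged)
  out
}

#' Synthetic scanner timelapse of a simulated scenario
#'
#' Runs the reaction-diffusion model for a scenario, renders every stored
#' time with the forward observation model and returns both the observed
#' frame stack and the hidden ground truth, so recovery of the analysis
#' pipeline can be scored against truth.
#'
#' @param scenario list with `grid` ([rd_grid()]), `pattern`
#'   (`light_pattern`), `params` ([kinetic_params()]), `t_points` (output
#'   times, h), and optionally `state0`, `mapping` arguments for
#'   [alpha_map()], `control` for [integrate_rd()].
#' @param calib a [calibration_curve()].
#' @param psf_sigma blur width, mm.
#' @param noise_sd read noise, gray levels.
#' @param seed integer seed for the noise (mandatory).
#' @return List of class `synth_timelapse`: `frames` (one integer frame
#'   per time), `background` (pre-growth cell-free frame), `times`,
#'   `truth` (the `trajectory`), `calib`, `meta`.
#' @export
synth_timelapse <- function(scenario, calib = calibration_curve(),
                            psf_sigma = 0.2, noise_sd = 30, seed) {
  stopifnot(is.list(scenario), inherits(scenario$grid, "rd_grid"),
            inherits(scenario$pattern, "light_pattern"))
  if (missing(seed)) stop("seed is mandatory")
  st0 <- scenario$state0
  if (is.null(st0)) st0 <- initial_state(scenario$grid)
  tr <- integrate_rd(st0, scenario$pattern, scenario$params,
                     t_end = max(scenario$t_points),
                     out_times = scenario$t_points,
                     control = scenario$control %||% list())
  sp <- scenario$grid$spacing
  zero <- st0$N * 0
  frames <- lapply(seq_along(tr$times), function(i) {
    density_to_image(tr$states[[i]]$N, calib, psf_sigma, noise_sd,
                     seed = seed + i, spacing = sp)
  })
  bg <- density_to_image(zero, calib, psf_sigma, noise_sd, seed = seed,
                         spacing = sp)
  structure(list(frames = frames, background = bg, times = tr$times,
                 truth = tr, calib = calib,
                 meta = list(pattern = scenario$pattern$meta,
                             psf_sigma = psf_sigma, noise_sd = noise_sd,
                             seed = seed, spacing = sp)),
            class = "synth_timelapse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fast phenomenological lawn trajectory (no PDE solve)
#'
#' Independent per-pixel logistic growth
#' `N(t) = K N0 exp(rt) / (K + N0 (exp(rt) - 1))`, optionally with the
#' rate modulated by a spatial mask, packaged as a `trajectory` so the
#' metrics layer can be unit-tested in closed form without running the
#' solver.
#'
#' @param grid an [rd_grid()].
#' @param growth_rate intrinsic rate r, 1/h (scalar or field).
#' @param carrying_capacity K, CFU/mL.
#' @param N0 initial density, CFU/mL.
#' @param t_points output times, h.
#' @param modulation optional multiplicative field on the rate (e.g. a
#'   stripe mask).
#' @param cv_noise optional lognormal coefficient of variation applied
#'   per pixel and time (deterministic per `seed`).
#' @param seed integer seed (required when `cv_noise > 0`).
#' @return A `trajectory` whose `N` fields follow the logistic closed
#'   form (other fields zero).
#' @export
phenomenological_lawn <- function(grid, growth_rate = 0.3,
                                  carrying_capacity = 1e9, N0 = 1e6,
                                  t_points = seq(0, 40, by = 2),
                                  modulation = NULL, cv_noise = 0,
                                  seed = NULL) {
  stopifnot(inherits(grid, "rd_grid"))
  n <- n_cells(grid)
  r <- rep_len(as.numeric(growth_rate), n)
  if (!is.null(modulation)) {
    if (length(modulation) != n) stop("modulation field not on grid")
    r <- r * as.numeric(modulation)
  }
  noise <- if (cv_noise > 0) {
    if (is.null(seed)) stop("seed required when cv_noise > 0")
    sdl <- sqrt(log(1 + cv_noise^2))
    with_seed(seed, matrix(stats::rlnorm(n * length(t_points),
                                         -sdl^2 / 2, sdl), nrow = n))
  } else NULL
  shape <- function(v) { if (grid$ndim == 2L) dim(v) <- grid$n; v }
  states <- lapply(seq_along(t_points), function(i) {
    e <- exp(r * t_points[i])
    N <- carrying_capacity * N0 * e / (carrying_capacity + N0 * (e - 1))
    if (!is.null(noise)) N <- N * noise[, i]
    z <- shape(numeric(n))
    structure(list(t = t_points[i], S = z, H = z, E = z, N = shape(N),
                   U = z, grid = grid), class = "sim_state")
  })
  structure(list(times = t_points, states = states, grid = grid,
                 params = NULL, pattern_meta = NULL, alpha = NULL,
                 diagnostics = list(steps = 0L, rejected = 0L,
                                    clipped = stats::setNames(numeric(5),
                                                              FIELDS),
                                    min_value = NULL,
                                    dt_min = NA, dt_max = NA)),
            class = "trajectory")
}
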