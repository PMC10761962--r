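#' @title Illumination patterns
#' @description Generators for the light patterns projected onto the plate
#'   (uniform fields, single lines, periodic stripes, raster masks) and the
#'   mapping from local light intensity to the per-cell invertase
#'   production rate alpha(x).
#' @name patterns
NULL

# device intensity range, mW/cm^2
DEVICE_I_MAX <- 1.13
DEVICE_I_MIN <- 0.0014

new_light_pattern <- function(I, grid, meta) {
  if (any(I < 0)) stop("light intensity must be >= 0")
  if (any(I > DEVICE_I_MAX + 1e-12))
    warning("intensity exceeds the device maximum of ", DEVICE_I_MAX,
            " mW/cm^2")
  structure(list(I = I, grid = grid, meta = meta), class = "light_pattern")
}

#' @export
print.light_pattern <- function(x, ...) {
  cat(sprintf("light_pattern '%s': I in [%.4g, %.4g] mW/cm^2 on %dD grid\n",
              x$meta$generator, min(x$I), max(x$I), x$grid$ndim))
  invisible(x)
}

#' Uniform illumination
#'
#' @param grid an [rd_grid()].
#' @param I0 intensity, mW/cm^2 (device range 0.0014-1.13).
#' @return A `light_pattern`.
#' @export
light_uniform <- function(grid, I0 = DEVICE_I_MAX) {
  stopifnot(inherits(grid, "rd_grid"), I0 >= 0)
  I <- if (grid$ndim == 1L) rep(I0, grid$n[1]) else
    matrix(I0, grid$n[1], grid$n[2])
  new_light_pattern(I, grid, list(generator = "uniform", I0 = I0))
}

#' Single line of light
#'
#' A stripe of width `w` centred at `center` along the first axis,
#' constant along the second (1D representation is canonical: stripes are
#' translationally symmetric).
#'
#' @param grid an [rd_grid()].
#' @param w line width, mm.
#' @param I0 intensity, mW/cm^2.
#' @param center line center, mm (default: domain center).
#' @return A `light_pattern`; realized width is within one grid cell of `w`.
#' @export
light_single_line <- function(grid, w, I0 = DEVICE_I_MAX,
                              center = grid$extent[1] / 2) {
  stopifnot(inherits(grid, "rd_grid"))
  if (w < grid$spacing) stop("line width below one grid cell")
  if (w > grid$extent[1]) stop("line width exceeds domain extent")
  x <- grid_coords(grid, 1L)
  lit <- abs(x - center) < w / 2
  I <- ifelse(lit, I0, 0)
  if (grid$ndim == 2L) I <- matrix(I, grid$n[1], grid$n[2])
  new_light_pattern(I, grid, list(generator = "single_line", w = w, I0 = I0,
                                  center = center))
}

#' Periodic stripes of light at constant duty cycle
#'
#' Square-wave pattern of period `lambda` along the first axis with a lit
#' fraction `duty` (the study sweep keeps duty = 0.25, i.e. 75% dark /
#' 25% illuminated, so mean illumination -- and cooperator frequency -- is
#' constant across wavelengths). Lit stripes start at x = 0.
#'
#' @param grid an [rd_grid()].
#' @param lambda spatial wavelength (lit + dark width), mm.
#' @param duty lit fraction of one period, in (0, 1).
#' @param I0 intensity, mW/cm^2.
#' @return A `light_pattern`.
#' @export
light_periodic_lines <- function(grid, lambda, duty = 0.25,
                                 I0 = DEVICE_I_MAX) {
  stopifnot(inherits(grid, "rd_grid"))
  if (duty <= 0 || duty >= 1) stop("duty must lie in (0, 1)")
  if (lambda < 2 * grid$spacing) stop("lambda not resolvable on grid")
  ntile <- grid$extent[1] / lambda
  if (abs(ntile - round(ntile)) > 1e-8)
    warning("domain extent is not an integer multiple of lambda; ",
            "pattern truncated at the boundary")
  x <- grid_coords(grid, 1L)
  phase <- (x / lambda) %% 1
  I <- ifelse(phase < duty, I0, 0)
  if (grid$ndim == 2L) I <- matrix(I, grid$n[1], grid$n[2])
  new_light_pattern(I, grid, list(generator = "periodic_lines",
                                  lambda = lambda, duty = duty, I0 = I0))
}

#' Pattern from a grayscale raster mask
#'
#' Reads an 8-bit (or 16-bit) grayscale mask -- PNG or plain-text PGM --
#' scaled so white maps to `I0`, and resamples it onto the grid by exact
#' area averaging (each grid cell gets the mean of the pixel area it
#' covers).
#'
#' @param mask path to a PNG/PGM file, or a numeric matrix in `[0, 1]`
#'   (rows = x axis).
#' @param mm_per_px pixel pitch of the mask, mm.
#' @param grid an [rd_grid()] (2D, or 1D to use only the first mask row).
#' @param I0 intensity assigned to white pixels, mW/cm^2.
#' @return A `light_pattern` with intensities in `[0, I0]`.
#' @export
light_from_image <- function(mask, mm_per_px, grid, I0 = DEVICE_I_MAX) {
  stopifnot(inherits(grid, "rd_grid"), mm_per_px > 0)
  if (is.character(mask)) mask <- read_gray_image(mask)
  if (!is.matrix(mask) || any(dim(mask) == 0L)) stop("zero-size mask")
  if (any(mask < 0) || any(mask > 1)) stop("mask values must lie in [0, 1]")
  if (grid$ndim == 1L) {
    I <- area_resample_1d(mask[, 1], mm_per_px, grid$n[1], grid$spacing)
  } else {
    tmp <- apply(mask, 2, area_resample_1d, mm_per_px, grid$n[1],
                 grid$spacing)
    tmp <- matrix(tmp, nrow = grid$n[1])
    I <- t(apply(tmp, 1, area_resample_1d, mm_per_px, grid$n[2],
                 grid$spacing))
    I <- matrix(I, grid$n[1], grid$n[2])
  }
  new_light_pattern(I * I0, grid,
                    list(generator = "from_image", mm_per_px = mm_per_px,
                         I0 = I0))
}

# exact area-average resampling of a piecewise-constant 1D signal
# (pixels of width mm_per_px) onto n cells of width spacing; the signal is
# clamped-extended beyond its support.
area_resample_1d <- function(v, mm_per_px, n, spacing) {
  m <- length(v)
  cum <- c(0, cumsum(v)) * mm_per_px   # integral of signal up to pixel edges
  total_len <- m * mm_per_px
  int_at <- function(pos) {            # integral of extended signal on [0,pos]
    pos2 <- pmin(pmax(pos, 0), total_len)
    px <- pos2 / mm_per_px
    lo <- pmin(floor(px), m - 1)
    val <- cum[lo + 1] + (px - lo) * mm_per_px * v[lo + 1]
    # clamp-extension beyond the right edge
    val + pmax(pos - total_len, 0) * v[m] + pmin(pos, 0) * v[1]
  }
  edges <- seq(0, n * spacing, by = spacing)
  diff(int_at(edges)) / spacing
}

#' Map light intensity to per-cell invertase production rate
#'
#' Converts a `light_pattern` into the alpha(x) field of the model. The
#' default mapping is binary -- above `threshold` a cell is fully induced
#' (`alpha_coop`), below it only the leaky dark rate `alpha_cheat` remains
#' -- because the underlying model does not resolve the graded dose
#' response at low intensity. A Hill mapping is provided for exploration.
#'
#' @param pattern a `light_pattern`.
#' @param p [kinetic_params()].
#' @param mapping `"binary"` or `"hill"`.
#' @param threshold binary switching intensity, mW/cm^2 (default 10% of
#'   the device maximum).
#' @param I_half,n Hill half-saturation (mW/cm^2) and exponent.
#' @return alpha field (mol/s/cell) on the pattern's grid, bounded by
#'   `[alpha_cheat, alpha_coop]`.
#' @export
alpha_map <- function(pattern, p, mapping = c("binary", "hill"),
                      threshold = 0.1 * DEVICE_I_MAX, I_half = NULL,
                      n = 2) {
  stopifnot(inherits(pattern, "light_pattern"), inherits(p, "kinetic_params"))
  mapping <- match.arg(mapping)
  I <- pattern$I
  if (mapping == "binary") {
    if (threshold > DEVICE_I_MAX || threshold < DEVICE_I_MIN)
      warning("binary threshold outside the device intensity range")
    alpha <- ifelse(I >= threshold, p$alpha_coop, p$alpha_cheat)
  } else {
    if (is.null(I_half)) stop("hill mapping requires I_half")
    f <- mm_frac(I^n, I_half^n)
    alpha <- p$alpha_cheat + (p$alpha_coop - p$alpha_cheat) * f
  }
  if (pattern$grid$ndim == 2L) alpha <- matrix(alpha, nrow = pattern$grid$n[1])
  alpha
}
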