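#' Uniform finite-difference grid (1D or 2D)
#'
#' The model lives on the two horizontal dimensions of a thin gel (vertical
#' diffusion equilibrates much faster than horizontal); line and stripe
#' illumination experiments are translationally symmetric along the stripe,
#' so 1D is the canonical faithful reduction and 2D is reserved for raster
#' masks.
#'
#' @param extent domain extent in mm; length 1 (1D) or 2 (2D).
#' @param spacing uniform grid spacing in mm (default 0.1 mm, the light
#'   patterning resolution of the plate device).
#' @param bc boundary condition, `"noflux"` (dish walls) or `"periodic"`
#'   (natural for single-wavelength stripe unit cells); one value or one
#'   per axis.
#' @return Object of class `rd_grid`: `ndim`, `extent`, `spacing`, `bc`,
#'   `n` (cells per axis), `x` (cell-center coordinates, first axis).
#' @examples
#' g <- rd_grid(40)            # 40 mm line, 400 cells
#' g2 <- rd_grid(c(10, 10), spacing = 0.25, bc = "periodic")
#' @export
rd_grid <- function(extent, spacing = 0.1, bc = "noflux") {
  if (!is.numeric(extent) || !length(extent) %in% 1:2 || any(extent <= 0))
    stop("extent must be 1 or 2 positive lengths in mm")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive scalar in mm")
  bc <- match.arg(bc, c("noflux", "periodic"), several.ok = TRUE)
  bc <- rep_len(bc, length(extent))
  n <- extent / spacing
  if (any(abs(n - round(n)) > 1e-8))
    stop("extent must be an integer multiple of spacing")
  n <- as.integer(round(n))
  if (any(n < 4L)) stop("need at least 4 grid cells per axis")
  structure(list(ndim = length(extent), extent = extent, spacing = spacing,
                 bc = bc, n = n,
                 x = (seq_len(n[1]) - 0.5) * spacing),
            class = "rd_grid")
}

#' @export
print.rd_grid <- function(x, ...) {
  cat(sprintf("%dD grid: %s mm at %g mm spacing (%s cells), bc = %s\n",
              x$ndim, paste(x$extent, collapse = " x "), x$spacing,
              paste(x$n, collapse = " x "), paste(x$bc, collapse = "/")))
  invisible(x)
}

n_cells <- function(grid) prod(grid$n)

#' Cell-center coordinates of a grid
#'
#' @param grid an [rd_grid()].
#' @param axis axis index (1 or 2).
#' @return Numeric vector of cell-center positions in mm.
#' @export
grid_coords <- function(grid, axis = 1L) {
  (seq_len(grid$n[axis]) - 0.5) * grid$spacing
}

# 1D Laplacian matrix (second difference / dx^2) with mirror-ghost no-flux
# or wraparound periodic closure. Row and column sums are exactly zero for
# both closures, which is what makes Crank-Nicolson conserve mass.
laplacian_matrix_1d <- function(n, spacing, bc) {
  main <- rep(-2, n)
  i <- c(seq_len(n), seq_len(n - 1L), 2:n)
  j <- c(seq_len(n), 2:n, seq_len(n - 1L))
  x <- c(main, rep(1, n - 1L), rep(1, n - 1L))
  if (bc == "noflux") {
    x[1] <- -1
    x[n] <- -1
  } else {
    i <- c(i, 1L, n)
    j <- c(j, n, 1L)
    x <- c(x, 1, 1)
  }
  Matrix::sparseMatrix(i = i, j = j, x = x / spacing^2, dims = c(n, n))
}

laplacian_matrix <- function(grid) {
  L1 <- laplacian_matrix_1d(grid$n[1], grid$spacing, grid$bc[1])
  if (grid$ndim == 1L) return(L1)
  L2 <- laplacian_matrix_1d(grid$n[2], grid$spacing, grid$bc[2])
  I1 <- Matrix::Diagonal(grid$n[1])
  I2 <- Matrix::Diagonal(grid$n[2])
  # fields stored column-major as n1 x n2 matrices flattened to vectors
  Matrix::kronecker(I2, L1) + Matrix::kronecker(L2, I1)
}

#' Discrete Laplacian of a field
#'
#' Standard 3-point (1D) / 5-point (2D) stencil; no-flux boundaries use
#' mirror ghost cells, periodic boundaries wrap around. Under either
#' closure the domain sum of the Laplacian is zero (discrete divergence
#' theorem), which the diffusion step inherits as exact mass conservation.
#'
#' @param field numeric vector (1D) or matrix (2D) on `grid`.
#' @param grid an [rd_grid()].
#' @return Field of the same shape, in field units per mm^2.
#' @export
laplacian <- function(field, grid) {
  check_field(field, grid)
  L <- laplacian_matrix(grid)
  out <- as.numeric(L %*% as.numeric(field))
  if (grid$ndim == 2L) dim(out) <- grid$n
  out
}

check_field <- function(field, grid, name = deparse(substitute(field))) {
  if (grid$ndim == 1L) {
    if (!is.numeric(field) || length(field) != grid$n[1])
      stop(name, ": field/grid mismatch (expected length ", grid$n[1], ")")
  } else {
    if (!is.matrix(field) || !all(dim(field) == grid$n))
      stop(name, ": field/grid mismatch (expected ",
           paste(grid$n, collapse = " x "), " matrix)")
  }
  invisible(TRUE)
}
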