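#' Regular periodic grid
#'
#' A rectangular grid of square cells on a periodic (torus) domain.  All
#' simulation and spectral routines in the package operate on such grids;
#' periodicity avoids edge artifacts in FFT-based diagnostics and matches the
#' spectral generation of the heterogeneity fields.
#'
#' @param nx number of cells along x (the flow axis for sloped runs).
#' @param ny number of cells along y; use `ny = 1` for one-dimensional domains.
#' @param dx cell size in metres (cells are square).
#' @return An object of class `vp_grid` with elements `nx`, `ny`, `dx`,
#'   `Lx = nx * dx` and `Ly = ny * dx`.
#' @examples
#' g <- vp_grid(256, 256, dx = 1)
#' g$Lx
#' @export
vp_grid <- function(nx, ny = nx, dx = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("grid dimensions must be positive integers")
  if (!is.finite(dx) || dx <= 0) stop("dx must be a positive cell size in metres")
  structure(list(nx = nx, ny = ny, dx = dx, Lx = nx * dx, Ly = ny * dx),
            class = "vp_grid")
}

#' @export
print.vp_grid <- function(x, ...) {
  cat(sprintf("periodic grid: %d x %d cells, dx = %g m (%g x %g m)\n",
              x$nx, x$ny, x$dx, x$Lx, x$Ly))
  invisible(x)
}

#' Gridded scalar field
#'
#' Wraps a numeric matrix (dimensions `nx` by `ny`) together with its physical
#' cell size and a unit label.  Fields hold biomass, water depths, or
#' spatially varying model coefficients.
#'
#' @param values numeric matrix (or vector for 1-D fields) of cell values.
#' @param dx cell size in metres.
#' @param units free-form unit label (e.g. `"g/m^2"`).
#' @return Object of class `vp_field`.
#' @export
vp_field <- function(values, dx = 1, units = "") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (!all(is.finite(values))) stop("field values must be finite everywhere")
  structure(list(values = values, dx = dx, units = units), class = "vp_field")
}

#' @export
print.vp_field <- function(x, ...) {
  v <- x$values
  cat(sprintf("field %d x %d, dx = %g m%s: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              nrow(v), ncol(v), x$dx,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              mean(v), stats::sd(v), min(v), max(v)))
  invisible(x)
}

#' @export
plot.vp_field <- function(x, main = "", ...) {
  v <- x$values
  if (ncol(v) == 1L) {
    graphics::plot((seq_len(nrow(v)) - 1) * x$dx, v[, 1], type = "l",
                   xlab = "x [m]", ylab = x$units, main = main, ...)
  } else {
    graphics::image((seq_len(nrow(v)) - 1) * x$dx, (seq_len(ncol(v)) - 1) * x$dx,
                    v, xlab = "x [m]", ylab = "y [m]", main = main, useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "Greens", rev = TRUE), asp = 1, ...)
  }
  invisible(x)
}

#' @export
mean.vp_field <- function(x, ...) mean(x$values, ...)

# coerce anything field-like to a values matrix
field_values <- function(x) {
  if (inherits(x, "vp_field")) x$values
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, ncol = 1L)
  else stop("expected a vp_field or numeric matrix")
}

field_dx <- function(x, dx = NULL) {
  if (!is.null(dx)) dx else if (inherits(x, "vp_field")) x$dx else 1
}

grid_of <- function(x, dx = NULL) {
  v <- field_values(x)
  vp_grid(nrow(v), ncol(v), field_dx(x, dx))
}

#' Angular wavenumber axis of a periodic grid
#'
#' Returns the unshifted (FFT-ordered) angular wavenumbers `2*pi*j/(n*dx)` for
#' `j = 0, 1, ..., n/2-1, -n/2, ..., -1`, in rad/m.
#'
#' @param n number of cells.
#' @param dx cell size in metres.
#' @export
k_axis <- function(n, dx = 1) {
  j <- c(0:(ceiling(n / 2) - 1), if (n > 1) -(floor(n / 2):1))
  2 * pi * j / (n * dx)
}

# matrices of kx, ky over a grid, FFT order
k_grids <- function(nx, ny, dx) {
  kx <- k_axis(nx, dx); ky <- k_axis(ny, dx)
  list(kx = matrix(kx, nx, ny), ky = matrix(ky, nx, ny, byrow = TRUE),
       kx_axis = kx, ky_axis = ky)
}

#' Coefficient of variation of a field
#'
#' The ratio of the population standard deviation to the mean of the cell
#' values, the dimensionless measure used to report the degree of spatial
#' heterogeneity.
#'
#' @param x a `vp_field` or numeric matrix.
#' @return Non-negative scalar `sd(x)/mean(x)`.
#' @export
cv_field <- function(x) {
  v <- as.vector(field_values(x))
  m <- mean(v)
  if (abs(m) < .Machine$double.eps * 100 * max(1, stats::sd(v)))
    stop("coefficient of variation is undefined for a zero-mean field")
  n <- length(v)
  sqrt(sum((v - m)^2) / n) / m
}
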