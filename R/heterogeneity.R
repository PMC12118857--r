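# Spatially correlated log-normal heterogeneity fields: the time-constant
# exogenous "noise" (soil properties, microtopography) that perturbs the
# pattern-forming models.  e = exp(eps), eps Gaussian with exponentially
# decaying isotropic autocorrelation R(r) = exp(-r/theta).

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Log-normal parameters from mean and coefficient of variation
#'
#' Moment matching for a log-normal variable `e = exp(eps)`: given the target
#' mean `mu` and coefficient of variation `cv` of `e`, returns the mean and
#' variance of the underlying Gaussian `eps` such that `E[e] = mu` and
#' `sd(e)/E[e] = cv`.
#'
#' @param mean target mean of the log-normal field (units of the coefficient
#'   it modulates); must be positive.
#' @param cv target coefficient of variation (dimensionless, >= 0).
#' @return List with `mu_log` and `sigma2_log`, the Gaussian mean and variance.
#' @examples
#' p <- lognormal_params(0.2, 0.3)
#' exp(p$mu_log + p$sigma2_log / 2)  # = 0.2
#' @export
lognormal_params <- function(mean, cv) {
  if (!is.finite(mean) || mean <= 0) stop("mean of a log-normal field must be positive")
  if (!is.finite(cv) || cv < 0) stop("cv must be non-negative")
  sigma2 <- log(1 + cv^2)
  list(mu_log = log(mean) - sigma2 / 2, sigma2_log = sigma2)
}

#' Discrete autocorrelation kernel of the heterogeneity process
#'
#' The isotropic first-order autocorrelation `R(r) = exp(-r/theta)` of the
#' continuous Gaussian stage, discretized for a periodic grid: at short lags
#' the correlation is averaged over the relative displacement of two grid
#' cells (cell-average correction), and at lags beyond a fraction of the
#' domain half-width it is tapered to zero with a raised-cosine window so
#' that the periodic wrap-around does not introduce spurious long-range
#' correlation.  The Fourier transform of the returned kernel (attached as
#' attribute `"spectrum"`) is clipped at zero, so it is a valid covariance
#' spectrum on the torus.
#'
#' @param theta correlation length in metres (lag at which `R = exp(-1)`).
#' @param grid a [vp_grid()].
#' @param taper_start fraction of the domain half-width at which the
#'   raised-cosine taper begins (default 0.25).
#' @param correct_lags cell-average correction is applied at lags up to this
#'   many cells (default 3); beyond, the point value `exp(-r/theta)` is used.
#' @return A `vp_field` of autocorrelation values (1 at zero lag), with the
#'   non-negative spectrum as attribute `"spectrum"`.
#' @export
correlation_kernel <- function(theta, grid, taper_start = 0.25, correct_lags = 3L) {
  if (!is.finite(theta) || theta <= 0) stop("correlation length theta must be positive")
  dx <- grid$dx
  if (theta < dx / 10)
    warning("correlation length theta < dx/10: kernel is unresolved at this grid spacing")
  nx <- grid$nx; ny <- grid$ny
  # minimum-image (periodic) lag distances
  lx <- pmin(0:(nx - 1), nx - 0:(nx - 1)) * dx
  ly <- pmin(0:(ny - 1), ny - 0:(ny - 1)) * dx
  DX <- matrix(lx, nx, ny)
  DY <- matrix(ly, nx, ny, byrow = TRUE)
  r <- sqrt(DX^2 + DY^2)
  R <- exp(-r / theta)

  # cell-average correction at short lags: average exp(-|d + delta|/theta)
  # over the triangular-distributed intra-cell displacement delta per axis
  gl <- gauss_legendre(32, -dx, dx)
  wtri <- gl$w * (1 - abs(gl$x) / dx) / dx   # triangular density weight
  near <- which(DX <= correct_lags * dx & DY <= correct_lags * dx, arr.ind = TRUE)
  if (ny == 1L) {
    for (i in seq_len(nrow(near))) {
      d <- DX[near[i, 1], 1]
      R[near[i, 1], 1] <- sum(wtri * exp(-abs(d + gl$x) / theta))
    }
  } else {
    W2 <- outer(wtri, wtri)
    for (i in seq_len(nrow(near))) {
      d1 <- DX[near[i, 1], near[i, 2]]; d2 <- DY[near[i, 1], near[i, 2]]
      rq <- sqrt(outer((d1 + gl$x)^2, (d2 + gl$x)^2, "+"))
      R[near[i, 1], near[i, 2]] <- sum(W2 * exp(-rq / theta))
    }
  }
  R <- R / R[1, 1]   # unit value at zero lag after correction

  # raised-cosine taper towards the domain half-width
  half <- min(nx, if (ny > 1L) ny else nx) * dx / 2
  r0 <- taper_start * half
  w <- ifelse(r <= r0, 1,
              ifelse(r >= half, 0, cos(pi / 2 * (r - r0) / (half - r0))^2))
  w[1, 1] <- 1
  R <- R * w

  spec <- Re(stats::fft(R))
  spec[spec < 0] <- 0
  out <- vp_field(R, dx = dx, units = "")
  attr(out, "spectrum") <- spec
  out
}

# Gauss-Legendre nodes/weights on [a, b]
gauss_legendre <- function(n, a = -1, b = 1) {
  # Golub-Welsch from the Jacobi matrix of Legendre polynomials
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta; J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

#' Generate a correlated log-normal heterogeneity field
#'
#' Draws a Gaussian random field with the discrete exponential autocorrelation
#' of [correlation_kernel()] by spectral synthesis (white noise transformed,
#' scaled by the square root of the kernel spectrum, back-transformed; exact
#' on a periodic domain), then exponentiates with the moment-matched
#' log-normal parameters so the field has the requested mean and coefficient
#' of variation.
#'
#' @param mean target field mean (positive; units of the target coefficient).
#' @param cv target coefficient of variation; `cv = 0` yields a constant field.
#' @param theta correlation length in metres.
#' @param grid a [vp_grid()].
#' @param seed integer seed; identical arguments give bitwise-identical fields.
#' @param units unit label attached to the returned field.
#' @return A strictly positive `vp_field`.
#' @examples
#' g <- vp_grid(64, 64)
#' a <- heterogeneity_field(0.2, 0.3, theta = 8, grid = g, seed = 1)
#' @export
heterogeneity_field <- function(mean, cv, theta, grid, seed = NULL, units = "") {
  p <- lognormal_params(mean, cv)
  if (cv == 0)
    return(vp_field(matrix(mean, grid$nx, grid$ny), dx = grid$dx, units = units))
  ker <- correlation_kernel(theta, grid)
  spec <- attr(ker, "spectrum")
  z <- with_seed(seed, {
    w <- matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
    Re(stats::fft(stats::fft(w) * sqrt(spec), inverse = TRUE)) / (grid$nx * grid$ny)
  })
  eps <- p$mu_log + sqrt(p$sigma2_log) * z
  vp_field(exp(eps), dx = grid$dx, units = units)
}
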