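# Parametric linear filter families and pattern synthesis.  Three families
# cover the observed pattern classes:
#   low-pass  S(k) = C / (1 + (k/k0)^(2p))        irregular patterns
#   band-pass S(k) = C (k/k*)^(2a) / (1+(k/k*)^2)^(2a+1)   isotropic regular
#   oscillator: Lorentzian line pair (perpendicular) x Lorentzian (parallel)
#               for striped patterns with Brownian phase noise
# All exported densities are normalized per cycle frequency nu = k/2pi, the
# same convention as the empirical densities in spectra.R.

#' Higher-order low-pass spectral density
#'
#' `S(k) = C / (1 + (k/k0)^(2p))`: flat up to the corner wavenumber `k0`
#' (which is the half-power point, `S(k0) = S(0)/2`, so the cut-off
#' wavelength is `2*pi/k0`) and decaying like `k^(-2p)` beyond.  `C`
#' normalizes the density to unit integral over `nu = k/2pi` on the positive
#' half-axis.
#'
#' @param k wavenumbers (rad/m) at which to evaluate.
#' @param k0 corner wavenumber, rad/m.
#' @param p filter order (>= 1 for an integrable 2-D radial density).
#' @return Density values (per cycles/m).
#' @export
lowpass_density <- function(k, k0, p) {
  if (k0 <= 0) stop("corner wavenumber k0 must be positive")
  if (p < 1) stop("low-pass order p must be >= 1 for an integrable density")
  # closed-form normalization: int_0^inf dk/(1+(k/k0)^(2p)) = k0 pi/(2p sin(pi/(2p)))
  C <- 2 * pi / (k0 * pi / (2 * p * sin(pi / (2 * p))))
  C / (1 + (k / k0)^(2 * p))
}

# band-pass shape in u = k/kstar with tail exponent beta = alpha + 1;
# evaluated in log space (u^(2 alpha) underflows for large alpha)
bp_shape <- function(u, alpha) {
  out <- u * 0
  pos <- u > 0
  out[pos] <- exp(2 * alpha * log(u[pos]) - (2 * alpha + 1) * log1p(u[pos]^2))
  out
}

# int_0^inf bp_shape du (Beta-function closed form)
bp_shape_integral <- function(alpha) {
  exp(lbeta(alpha + 1 / 2, alpha + 1 / 2)) / 2
}

#' Band-pass spectral density
#'
#' `S(k) = C (k/k*)^(2 alpha) / (1 + (k/k*)^2)^(2 alpha + 1)`: zero at the
#' origin, a single interior lobe, and integrable tails.  The lobe maximum
#' sits at `k_c = k* sqrt(alpha/(alpha+1))`; the shape parameter `alpha`
#' controls the lobe width and hence the regularity, to which it is mapped
#' one-to-one by [bandpass_params()].
#'
#' @param k wavenumbers (rad/m).
#' @param k_c characteristic (lobe maximum) wavenumber, rad/m.
#' @param alpha positive shape parameter.
#' @return Density values (per cycles/m), unit integral on the half-axis.
#' @export
bandpass_density <- function(k, k_c, alpha) {
  if (k_c <= 0 || alpha <= 0) stop("k_c and alpha must be positive")
  kstar <- k_c / sqrt(alpha / (alpha + 1))
  C <- 2 * pi / (kstar * bp_shape_integral(alpha))
  C * bp_shape(k / kstar, alpha)
}

#' Regularity implied by a band-pass shape parameter
#'
#' The regularity `S_c/lambda_c` of the band-pass family depends only on the
#' shape parameter `alpha` (it is scale-invariant in `k_c`).
#'
#' @param alpha shape parameter.
#' @return Dimensionless regularity.
#' @export
bandpass_regularity <- function(alpha) {
  ustar <- sqrt(alpha / (alpha + 1))
  # S(kc)/lambda_c with kc = 1: kstar = 1/ustar
  kstar <- 1 / ustar
  Sc <- 2 * pi / (kstar * bp_shape_integral(alpha)) * bp_shape(ustar, alpha)
  Sc / (2 * pi)
}

#' Band-pass parameters for a target wavelength and regularity
#'
#' Numerically inverts the regularity calibration of the band-pass family.
#'
#' @param lambda_c target characteristic wavelength, metres.
#' @param regularity target regularity `S_c/lambda_c`.
#' @return List with `k_c` and `alpha`.
#' @export
bandpass_params <- function(lambda_c, regularity) {
  lo <- 0.02; hi <- 400
  rlo <- bandpass_regularity(lo); rhi <- bandpass_regularity(hi)
  if (regularity < rlo || regularity > rhi)
    stop(sprintf("requested regularity %.3g outside the attainable range [%.3g, %.3g]",
                 regularity, rlo, rhi))
  a <- stats::uniroot(function(la) bandpass_regularity(exp(la)) - regularity,
                      lower = log(lo), upper = log(hi), tol = 1e-12)$root
  list(k_c = 2 * pi / lambda_c, alpha = exp(a))
}

#' Noisy-oscillator spectral densities for striped patterns
#'
#' A stripe train whose phase performs a Brownian random walk decorrelates
#' exponentially: the autocorrelation perpendicular to the stripes is
#' `cos(k_c x) exp(-gamma |x|)`, whose Fourier transform is a pair of
#' Lorentzian lines at `+-k_c` of half-width `gamma`.  Parallel to the
#' stripes the correlation decays as `exp(-gamma |y|)`, a Lorentzian line at
#' the origin.  Both densities are normalized to unit integral over
#' `nu = k/2pi` on the positive half-axis; the 2-D density is their outer
#' product.
#'
#' @param k wavenumbers (rad/m).
#' @param k_c characteristic wavenumber (perpendicular axis), rad/m.
#' @param gamma phase-diffusion half-width, rad/m.
#' @return Density values (per cycles/m).
#' @export
oscillator_density_x <- function(k, k_c, gamma) {
  if (gamma <= 0 || k_c <= 0) stop("k_c and gamma must be positive")
  2 * (gamma / ((k - k_c)^2 + gamma^2) + gamma / ((k + k_c)^2 + gamma^2))
}

#' @rdname oscillator_density_x
#' @export
oscillator_density_y <- function(k, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  4 * gamma / (k^2 + gamma^2)
}

#' Regularity pair implied by oscillator parameters
#'
#' @param k_c characteristic wavenumber, rad/m.
#' @param gamma_x,gamma_y Lorentzian half-widths perpendicular/parallel to
#'   the stripes, rad/m.
#' @return Named vector with the perpendicular (`x`) and parallel (`y`)
#'   regularities.
#' @export
oscillator_regularity <- function(k_c, gamma_x, gamma_y) {
  lambda_c <- 2 * pi / k_c
  c(x = oscillator_density_x(k_c, k_c, gamma_x) / lambda_c,
    y = oscillator_density_y(0, gamma_y) / lambda_c)
}

# evaluate a family's 2-D spectral density on the FFT wavenumber grid
density_on_grid <- function(family, par, nx, ny, dx) {
  kg <- k_grids(nx, ny, dx)
  kr <- sqrt(kg$kx^2 + kg$ky^2)
  S <- switch(family,
    lowpass   = lowpass_density(kr, par[["k0"]], par[["p"]]),
    bandpass  = bandpass_density(kr, par[["k_c"]], par[["alpha"]]),
    oscillator = outer(oscillator_density_x(kg$kx_axis, par[["k_c"]], par[["gamma_x"]]),
                       oscillator_density_y(kg$ky_axis, par[["gamma_y"]])),
    stop("unknown filter family: ", family))
  S <- matrix(S, nx, ny)
  S[1, 1] <- if (family == "oscillator") S[1, 1] else 0
  S
}

#' Synthesize a generic pattern by linear filtering of noise
#'
#' Frequency-domain filtering: `b = Finv(T * F(e))` with the zero-phase
#' transfer function `T = sqrt(S)`.  The noise field `e` is mean-removed
#' first; the mean carries no spatial structure.  The tile-averaged density
#' of the output converges to `S` as the domain grows.
#'
#' @param S the filter spectral density: a `pattern_filter` fit, a function
#'   `f(kx, ky)` of wavenumber matrices, or a matrix already on the FFT grid.
#' @param noise noise field (`vp_field`/matrix); if `NULL`, white Gaussian
#'   noise is drawn on `grid` (seeded).
#' @param grid a [vp_grid()] (required when `noise` is `NULL`).
#' @param seed integer seed for generated noise.
#' @param dx cell size when `noise` is a bare matrix.
#' @return A `vp_field`, scaled to unit variance.
#' @export
synthesize <- function(S, noise = NULL, grid = NULL, seed = NULL, dx = NULL) {
  if (is.null(noise)) {
    if (is.null(grid)) stop("either a noise field or a grid must be supplied")
    noise <- with_seed(seed,
      matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny))
    dx <- grid$dx
  }
  v <- field_values(noise); dx <- field_dx(noise, dx)
  nx <- nrow(v); ny <- ncol(v)
  Sm <- if (inherits(S, "pattern_filter")) {
    density_on_grid(S$family, coef(S), nx, ny, dx)
  } else if (is.function(S)) {
    kg <- k_grids(nx, ny, dx)
    S(kg$kx, kg$ky)
  } else if (is.matrix(S)) {
    if (!all(dim(S) == c(nx, ny))) stop("density matrix does not match the noise grid")
    S
  } else stop("S must be a pattern_filter, a function of (kx, ky), or a matrix")
  if (any(Sm < 0)) stop("spectral density must be non-negative")
  Tf <- sqrt(Sm)
  b <- Re(stats::fft(stats::fft(v - mean(v)) * Tf, inverse = TRUE)) / (nx * ny)
  s <- stats::sd(b)
  if (s > 0) b <- b / s
  vp_field(b, dx = dx)
}

#' Threshold a generic pattern to a vegetation cover fraction
#'
#' Sets the highest `cover` fraction of cells to a uniform biomass and the
#' rest to zero: cells above the `(1-cover)` quantile get `mean_biomass /
#' cover`, so the spatial mean is exactly `mean_biomass` and the cover
#' fraction exactly `cover` (to the nearest cell).  Supplying `exclude_top`
#' additionally zeroes the top fraction, yielding ringed patterns.
#'
#' @param x generic pattern (`vp_field` or matrix).
#' @param cover target vegetated fraction, in (0, 1].
#' @param mean_biomass spatial mean of the thresholded pattern.
#' @param exclude_top optional fraction (< cover) of highest cells set bare.
#' @return A `vp_field` taking the values 0 and `mean_biomass/cover`.
#' @export
threshold_pattern <- function(x, cover, mean_biomass = 1, exclude_top = 0) {
  if (cover <= 0 || cover > 1) stop("cover must be in (0, 1]")
  if (exclude_top < 0 || exclude_top >= cover) stop("exclude_top must be in [0, cover)")
  v <- field_values(x)
  n <- length(v)
  m_hi <- round(exclude_top * n)
  m <- round(cover * n) - m_hi
  r <- rank(v, ties.method = "first")
  sel <- r > n - m - m_hi & r <= n - m_hi
  out <- matrix(0, nrow(v), ncol(v))
  out[sel] <- mean_biomass * n / sum(sel)
  vp_field(out, dx = field_dx(x), units = "g/m^2")
}

#' Generate a striped pattern with the noisy-oscillator model
#'
#' Constructs the stripe phase field as a Brownian random walk: independent
#' Brownian bridges along x and y with increment variance `2 gamma dx`
#' (bridged so the field is periodic), added to the deterministic carrier
#' `k_c x`, then maps the phase through a clipped cosine so the output is
#' bimodal at the requested cover.  The measured directional densities of
#' large syntheses match [oscillator_density_x()] / [oscillator_density_y()].
#' `k_c` is rounded to the nearest Fourier mode of the domain to preserve
#' periodicity.
#'
#' @param k_c characteristic wavenumber, rad/m.
#' @param gamma_x,gamma_y phase-diffusion widths (rad/m); may be 0 for a
#'   perfectly periodic stripe train.
#' @param grid a [vp_grid()].
#' @param cover vegetated fraction of the output.
#' @param mean_biomass spatial mean of the output.
#' @param seed integer seed.
#' @return A `vp_field` striped pattern (stripes parallel to y, wavevector
#'   along x).
#' @export
oscillator_generate <- function(k_c, gamma_x, gamma_y, grid, cover = 0.5,
                                mean_biomass = 1, seed = NULL) {
  if (k_c <= 0) stop("k_c must be positive")
  if (gamma_x < 0 || gamma_y < 0) stop("gamma values must be non-negative")
  k_c <- 2 * pi * max(1, round(k_c * grid$Lx / (2 * pi))) / grid$Lx
  brownian_bridge <- function(n, gam, d) {
    if (gam == 0 || n == 1L) return(numeric(n))
    w <- cumsum(c(0, stats::rnorm(n - 1, sd = sqrt(2 * gam * d))))
    w - (seq_len(n) - 1) / n * (w[n] + stats::rnorm(1, sd = sqrt(2 * gam * d)))
  }
  phi <- with_seed(seed, {
    bx <- brownian_bridge(grid$nx, gamma_x, grid$dx)
    by <- brownian_bridge(grid$ny, gamma_y, grid$dx)
    outer(bx, by, "+")
  })
  xs <- (seq_len(grid$nx) - 1) * grid$dx
  generic <- cos(k_c * xs + phi)   # recycles xs down columns
  threshold_pattern(vp_field(generic, grid$dx), cover, mean_biomass)
}

#' Vegetated cover fraction of a pattern
#'
#' Classifies cells as vegetated/bare with a bimodal histogram (Otsu)
#' threshold and returns the vegetated fraction.
#'
#' @param x a `vp_field` or matrix with (near-)bimodal values.
#' @return Cover fraction in (0, 1).
#' @export
cover_fraction <- function(x) {
  v <- field_values(x)
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps * 100 * max(abs(rng), 1))
    stop("cover fraction is undefined for a constant pattern")
  v01 <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(v01), range = c(0, 1))
  mean(v01 > thr)
}
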