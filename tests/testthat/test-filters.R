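# parametric filter families, synthesis and thresholding

test_that("low-pass density has its half-power point at the corner wavenumber", {
  expect_equal(lowpass_density(0.3, k0 = 0.3, p = 2),
               lowpass_density(0, 0.3, 2) / 2)
  expect_equal(lowpass_density(0.3, k0 = 0.3, p = 7),
               lowpass_density(0, 0.3, 7) / 2)
  expect_error(lowpass_density(1, 0.3, p = 0.5), ">= 1")
  # closed-form normalization agrees with numeric integration
  num <- integrate(function(k) lowpass_density(k, 0.4, 2.5), 0, Inf)$value
  expect_equal(num / (2 * pi), 1, tolerance = 1e-6)
  # p -> large approaches the ideal (indicator) low-pass
  kk <- seq(0, 1, by = 0.01)
  S <- lowpass_density(kk, 0.5, 50)
  expect_lt(max(S[kk > 0.55]) / S[1], 0.01)
  expect_gt(min(S[kk < 0.45]) / S[1], 0.99)
})

test_that("band-pass density vanishes at 0, peaks at k_c, and calibrates to regularity", {
  expect_equal(bandpass_density(0, 0.2, 3), 0)
  kk <- seq(1e-4, 2, length.out = 4000)
  S <- bandpass_density(kk, k_c = 0.2, alpha = 3)
  expect_equal(kk[which.max(S)], 0.2, tolerance = 1e-3)
  num <- integrate(function(k) bandpass_density(k, 0.2, 3), 0, Inf)$value
  expect_equal(num / (2 * pi), 1, tolerance = 1e-6)

  # calibration round trip, and scale invariance in k_c
  for (reg in c(0.3, 1, 4, 10)) {
    p <- bandpass_params(50, reg)
    expect_equal(bandpass_regularity(p$alpha), reg, tolerance = 1e-6)
    # the (lambda_c, regularity) pair measured from the analytic density
    # (numeric normalization on a truncated grid: 2% tolerance)
    kk <- seq(1e-5, 6, length.out = 6e4)
    S <- bandpass_density(kk, p$k_c, p$alpha)
    Sc <- max(S) / (sum(S) * (kk[2] - kk[1]) / (2 * pi))
    expect_equal(Sc / (2 * pi / kk[which.max(S)]), reg, tolerance = 0.02)
  }
  expect_error(bandpass_params(50, 1e5), "attainable")
})

test_that("oscillator densities match the closed-form Fourier transform", {
  kc <- 0.3; gam <- 0.04
  # numeric FT oracle of cos(kc x) exp(-gamma |x|)
  xs <- seq(-4000, 4000, by = 0.05)
  for (k in c(0, 0.1, 0.28, 0.3, 0.5)) {
    num <- sum(cos(kc * xs) * exp(-gam * abs(xs)) * cos(k * xs)) * 0.05
    expect_equal(oscillator_density_x(k, kc, gam), 2 * num, tolerance = 1e-4)
  }
  expect_gt(oscillator_density_x(0, kc, gam), 0)   # positive at the origin
  # parallel axis: Lorentzian line at 0, unit half-axis integral
  num <- integrate(function(k) oscillator_density_y(k, 0.07), 0, Inf)$value
  expect_equal(num / (2 * pi), 1, tolerance = 1e-6)
  # implied regularity pair is computable and scale-invariant
  r <- oscillator_regularity(kc, gam, 0.02)
  expect_true(all(r > 0))
  r2 <- oscillator_regularity(kc / 3, gam / 3, 0.02 / 3)
  expect_equal(unname(r2), unname(r), tolerance = 1e-10)
})

test_that("synthesis reproduces the target density and is seed-deterministic", {
  g <- vp_grid(256, 256)
  p1 <- synthesize(function(kx, ky) bandpass_density(sqrt(kx^2 + ky^2), 2 * pi / 32, 4),
                   grid = g, seed = 5)
  p2 <- synthesize(function(kx, ky) bandpass_density(sqrt(kx^2 + ky^2), 2 * pi / 32, 4),
                   grid = g, seed = 5)
  expect_identical(p1$values, p2$values)

  # identity transfer returns the (mean-removed, rescaled) input
  noise <- white_field(64, seed = 3)
  out <- synthesize(matrix(1, 64, 64), noise = noise)
  expect_equal(cor(as.vector(out$values), as.vector(noise$values)), 1, tolerance = 1e-12)

  expect_error(synthesize(matrix(1, 32, 32), noise = noise), "match")
  expect_error(synthesize(matrix(-1, 64, 64), noise = noise), "non-negative")
})

test_that("thresholding hits the cover and mean exactly and makes ringed patterns", {
  f <- bandpass_field(128, lambda = 16, reg = 2, seed = 7)
  n <- 128 * 128
  for (p in c(0.2, 0.5, 0.8)) {
    th <- threshold_pattern(f, p, mean_biomass = 3)
    expect_equal(mean(th$values), 3, tolerance = 1e-12)
    expect_equal(mean(th$values > 0), p, tolerance = 1.5 / n)
  }
  th1 <- threshold_pattern(f, 1, mean_biomass = 2)
  expect_true(all(th1$values == 2))
  expect_error(threshold_pattern(f, 0), "cover")

  ring <- threshold_pattern(f, 0.4, exclude_top = 0.15)
  expect_equal(mean(ring$values > 0), 0.25, tolerance = 2 / n)
  expect_equal(mean(ring$values), 1, tolerance = 1e-12)
  # the excluded top cells are bare in the ringed pattern
  top <- f$values >= quantile(f$values, 1 - 0.15 + 1e-9)
  expect_true(all(ring$values[top] == 0))
})

test_that("oscillator generation matches its spectral model", {
  g <- vp_grid(256, 256)
  # gamma -> 0: perfectly periodic stripes
  per <- oscillator_generate(2 * pi / 16, 0, 0, g, cover = 0.4, seed = 1)
  m <- pattern_metrics(directional_density(periodogram(per), "x"))
  expect_equal(m$lambda_c, 16, tolerance = 0.01)
  # near the periodic bound L/lambda_c; the square-wave profile keeps 8/pi^2
  # of the variance in the fundamental
  expect_gt(m$regularity, 0.7 * 256 / 16)

  # measured Sx of a large 1-D synthesis matches the Lorentzian pair
  g1 <- vp_grid(4096, 1, 1)
  kc <- 2 * pi / 32
  pat <- oscillator_generate(kc, gamma_x = 0.02, gamma_y = 0, g1, cover = 0.5, seed = 3)
  # 1-D bins are chi^2_2-noisy without ring averaging: smooth before fitting
  fit <- fit_filter(pat, "oscillator", smooth = 2)
  expect_equal(unname(coef(fit)["k_c"]), kc, tolerance = 0.05)
  expect_equal(unname(coef(fit)["gamma_x"]), 0.02, tolerance = 0.5)
  expect_gt(fit$R2[1], 0.6)

  # same seed determinism
  p2 <- oscillator_generate(kc, 0.02, 0, g1, cover = 0.5, seed = 3)
  expect_identical(pat$values, p2$values)

  # anisotropy: larger gamma_x/gamma_y -> more ragged stripe edges (more
  # variance of the stripe-boundary position along y)
  ragged <- oscillator_generate(2 * pi / 16, 0.10, 0.002, g, seed = 4)
  smoothe <- oscillator_generate(2 * pi / 16, 0.01, 0.002, g, seed = 4)
  edge_var <- function(x) mean(apply(x$values, 1, var))
  expect_gt(edge_var(ragged), edge_var(smoothe))
})

test_that("cover fraction is recovered from bimodal patterns", {
  f <- bandpass_field(128, lambda = 16, reg = 2, seed = 9)
  th <- threshold_pattern(f, 0.3)
  expect_equal(cover_fraction(th), mean(th$values > 0), tolerance = 1e-12)
  # stable under small additive noise
  noisy <- th$values + with_seed_test(1, matrix(rnorm(128 * 128, sd = 0.05), 128))
  expect_equal(cover_fraction(noisy), 0.3, tolerance = 0.02)
  expect_error(cover_fraction(matrix(1, 8, 8)), "constant")
})

test_that("fitted filters close the synthesis loop within 5%", {
  # synthesize at known parameters, fit, compare
  f <- bandpass_field(512, lambda = 40, reg = 2.5, seed = 13)
  fit <- fit_filter(f, "bandpass")
  expect_equal(fit$lambda_c, 40, tolerance = 0.05)
  expect_equal(unname(fit$regularity), 2.5, tolerance = 0.05)
  # simulate method regenerates a pattern with matching measured metrics
  re <- simulate(fit, seed = 21, grid = vp_grid(512, 512))
  msr <- pattern_summary(re)
  expect_equal(msr$lambda_c, 40, tolerance = 0.07)
  expect_equal(msr$regularity, 2.5, tolerance = 0.15)
})
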