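# Hellinger-distance fitting of the parametric filter families to empirical
# spectral densities.  fit_filter() is the package's modelling centrepiece:
# it returns a classed object with the usual print/summary/coef/predict/
# simulate/plot/residuals methods, so a fitted filter can be inspected and
# used to generate statistically equivalent patterns.

#' Fit a parametric linear filter to a pattern's spectral density
#'
#' Estimates the parameters of a filter family by minimizing the Hellinger
#' distance `sum((sqrt(S_fit) - sqrt(S_emp))^2 dnu)` between the family's
#' density and the empirical radial (isotropic families) or directional
#' (oscillator) density of the pattern.  The mean and the first wavenumber
#' bin are excluded and both densities are renormalized over the retained
#' bins before comparison.  The goodness of fit is reported as
#' `R^2 = 1 - SSE/SST` on the square-root densities.
#'
#' @param x a `vp_field`/matrix (its density is computed internally) or a
#'   `vp_rdensity` from [radial_density()]/[directional_density()].
#' @param family `"lowpass"`, `"bandpass"` or `"oscillator"` (the oscillator
#'   fits the perpendicular-axis line pair and the parallel-axis line).
#' @param dx cell size in metres when `x` is a bare matrix.
#' @param smooth periodogram smoothing half-width (see [pattern_summary()])
#'   used when `x` is a field.
#' @param init optional named list of starting parameters.
#' @return Object of class `pattern_filter` with elements `family`, `par`,
#'   `R2`, `hellinger`, the empirical densities, and derived `lambda_c` /
#'   `regularity`.
#' @examples
#' g <- vp_grid(128, 128)
#' pat <- synthesize(function(kx, ky) bandpass_density(sqrt(kx^2 + ky^2), 0.5, 4),
#'                   grid = g, seed = 1)
#' f <- fit_filter(pat, "bandpass")
#' coef(f)
#' @export
fit_filter <- function(x, family = c("lowpass", "bandpass", "oscillator"),
                       dx = NULL, smooth = 0L, init = NULL) {
  family <- match.arg(family)
  if (inherits(x, "vp_rdensity")) {
    emp <- list(x)
  } else {
    spec <- periodogram(x, dx = dx)
    if (smooth > 0) spec$values <- smooth_periodogram(spec$values, as.integer(smooth))
    emp <- if (family == "oscillator") {
      if (length(spec$ky) > 1L)
        list(directional_density(spec, "x"), directional_density(spec, "y"))
      else list(directional_density(spec, "x"))
    } else list(radial_density(spec))
  }
  fits <- switch(family,
    lowpass = list(fit_family_1d(emp[[1]], "lowpass", c("k0", "p"),
                                 init %||% init_lowpass(emp[[1]]),
                                 function(k, p) lowpass_density(k, p[1], p[2]),
                                 # enforce the integrability bound p >= 1
                                 map = function(th) c(exp(th[1]), 1 + exp(th[2])),
                                 unmap = function(p) c(log(p[1]), log(max(p[2] - 1, 1e-3))))),
    bandpass = list(fit_family_1d(emp[[1]], "bandpass", c("k_c", "alpha"),
                                  init %||% init_bandpass(emp[[1]]),
                                  function(k, p) bandpass_density(k, p[1], p[2]))),
    oscillator = {
      fx <- fit_family_1d(emp[[1]], "oscillator_x", c("k_c", "gamma_x"),
                          init %||% init_osc_x(emp[[1]]),
                          function(k, p) oscillator_density_x(k, p[1], p[2]))
      if (length(emp) >= 2L) {
        fy <- fit_family_1d(emp[[2]], "oscillator_y", "gamma_y",
                            init %||% init_osc_y(emp[[2]]),
                            function(k, p) oscillator_density_y(k, p[1]))
        list(fx, fy)
      } else list(fx)   # 1-D transect: only the perpendicular line pair
    })
  par <- unlist(lapply(fits, `[[`, "par"))
  R2 <- vapply(fits, `[[`, numeric(1), "R2")
  conv <- all(vapply(fits, `[[`, numeric(1), "convergence") == 0)
  if (!conv) warning("filter fit did not fully converge; inspect $optim")
  derived <- switch(family,
    lowpass = list(lambda_c = NA_real_, regularity = 0,
                   lambda_l = 2 * pi / par[["k0"]]),
    bandpass = list(lambda_c = 2 * pi / par[["k_c"]],
                    regularity = bandpass_regularity(par[["alpha"]]),
                    lambda_l = NA_real_),
    oscillator = list(lambda_c = 2 * pi / par[["k_c"]],
                      regularity = if ("gamma_y" %in% names(par))
                        oscillator_regularity(par[["k_c"]], par[["gamma_x"]],
                                              par[["gamma_y"]])
                      else c(x = oscillator_density_x(par[["k_c"]], par[["k_c"]],
                                                      par[["gamma_x"]]) *
                                 par[["k_c"]] / (2 * pi), y = NA_real_),
                      lambda_l = NA_real_))
  structure(c(list(family = family, par = par, R2 = unname(R2),
                   hellinger = vapply(fits, `[[`, numeric(1), "value"),
                   empirical = emp,
                   optim = lapply(fits, `[[`, "opt")),
              derived),
            class = "pattern_filter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared 1-parameter-vector Hellinger fit on one empirical density;
# map/unmap move between the optimizer's unconstrained space and the
# (positive, possibly bounded) parameter space
fit_family_1d <- function(emp, name, parnames, start, dens,
                          map = exp, unmap = log) {
  dk <- attr(emp, "dk")
  keep <- emp$k > 1.5 * dk
  k <- emp$k[keep]
  Semp <- pmax(emp$S[keep], 0)
  Semp <- Semp / (sum(Semp) * dk / (2 * pi))
  sq_emp <- sqrt(Semp)
  obj <- function(th) {
    p <- map(th)
    Sf <- dens(k, p)
    Sf <- Sf / (sum(Sf) * dk / (2 * pi))
    sum((sqrt(Sf) - sq_emp)^2) * dk / (2 * pi)
  }
  start <- unlist(start)[seq_along(parnames)]
  opt <- if (length(start) == 1L) {
    o <- stats::optimize(obj, interval = unmap(c(start / 100, start * 100)))
    list(par = o$minimum, value = o$objective, convergence = 0)
  } else stats::optim(unmap(start), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  par <- map(opt$par); names(par) <- parnames
  Sfit <- dens(k, par)
  Sfit <- Sfit / (sum(Sfit) * dk / (2 * pi))
  sst <- sum((sq_emp - mean(sq_emp))^2)
  r2 <- 1 - sum((sqrt(Sfit) - sq_emp)^2) / sst
  list(par = par, value = opt$value, convergence = opt$convergence,
       R2 = r2, opt = opt, k = k, Semp = Semp, Sfit = Sfit, name = name)
}

init_lowpass <- function(emp) {
  dk <- attr(emp, "dk"); keep <- emp$k > 1.5 * dk
  S <- emp$S[keep]; k <- emp$k[keep]
  S0 <- max(S[1:min(3, length(S))])
  j <- which(S < S0 / 2)
  k0 <- if (length(j)) k[j[1]] else k[round(length(k) / 2)]
  list(k0 = k0, p = 2)
}

init_bandpass <- function(emp) {
  m <- pattern_metrics(emp)
  if (m$lobe == "origin") {
    dk <- attr(emp, "dk")
    return(list(k_c = 4 * dk, alpha = 1))
  }
  reg <- min(max(m$regularity, bandpass_regularity(0.05)), bandpass_regularity(300))
  p <- bandpass_params(2 * pi / m$k_c, reg)
  list(k_c = p$k_c, alpha = p$alpha)
}

init_osc_x <- function(emp) {
  m <- pattern_metrics(emp)
  kc <- if (m$lobe == "origin") 4 * attr(emp, "dk") else m$k_c
  # half-width at half maximum around the lobe
  keep <- emp$k > 1.5 * attr(emp, "dk")
  S <- emp$S[keep]; k <- emp$k[keep]
  imax <- which.max(S)
  above <- which(S > S[imax] / 2)
  hw <- max(attr(emp, "dk"), (max(k[above]) - min(k[above])) / 2)
  list(k_c = kc, gamma_x = hw)
}

init_osc_y <- function(emp) {
  keep <- emp$k > 1.5 * attr(emp, "dk")
  S <- emp$S[keep]; k <- emp$k[keep]
  j <- which(S < max(S) / 2)
  list(gamma_y = if (length(j)) k[j[1]] else k[round(length(k) / 2)])
}

#' @export
coef.pattern_filter <- function(object, ...) object$par

#' @export
print.pattern_filter <- function(x, ...) {
  cat(sprintf("%s filter fit (Hellinger distance)\n", x$family))
  cat("  parameters: ",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  R^2 = %s\n", paste(sprintf("%.3f", x$R2), collapse = " / ")))
  if (!is.na(x$lambda_c))
    cat(sprintf("  lambda_c = %.3g m, regularity = %s\n", x$lambda_c,
                paste(signif(x$regularity, 3), collapse = " / ")))
  if (!is.null(x$lambda_l) && !is.na(x$lambda_l))
    cat(sprintf("  cut-off wavelength lambda_l = %.3g m\n", x$lambda_l))
  invisible(x)
}

#' @export
summary.pattern_filter <- function(object, ...) {
  print(object)
  cat(sprintf("  Hellinger distance: %s\n",
              paste(signif(object$hellinger, 4), collapse = " / ")))
  invisible(object)
}

#' Predict filter density values
#'
#' @param object a `pattern_filter`.
#' @param k wavenumbers (rad/m) at which to evaluate the fitted density.
#' @param axis for oscillator fits: `"x"` (perpendicular, the line pair) or
#'   `"y"` (parallel).
#' @param ... unused.
#' @return Density values (per cycles/m).
#' @export
predict.pattern_filter <- function(object, k, axis = c("x", "y"), ...) {
  axis <- match.arg(axis)
  p <- object$par
  switch(object$family,
    lowpass = lowpass_density(k, p[["k0"]], p[["p"]]),
    bandpass = bandpass_density(k, p[["k_c"]], p[["alpha"]]),
    oscillator = if (axis == "x")
      oscillator_density_x(k, p[["k_c"]], p[["gamma_x"]])
    else oscillator_density_y(k, p[["gamma_y"]]))
}

#' Simulate patterns from a fitted filter
#'
#' Draws new patterns with the fitted spectral density by filtering white
#' noise (or a supplied heterogeneity field), optionally thresholded to a
#' vegetation cover.
#'
#' @param object a `pattern_filter`.
#' @param nsim number of patterns.
#' @param seed integer seed.
#' @param grid a [vp_grid()] (required unless `noise` given).
#' @param noise optional noise field to filter (e.g. the heterogeneity map
#'   that produced the original pattern).
#' @param cover optional cover fraction; if supplied the patterns are
#'   thresholded via [threshold_pattern()].
#' @param mean_biomass mean biomass of thresholded output.
#' @param ... unused.
#' @return A `vp_field`, or a list of them when `nsim > 1`.
#' @export
simulate.pattern_filter <- function(object, nsim = 1, seed = NULL, grid = NULL,
                                    noise = NULL, cover = NULL,
                                    mean_biomass = 1, ...) {
  one <- function(s) {
    pat <- synthesize(object, noise = noise, grid = grid, seed = s)
    if (!is.null(cover)) threshold_pattern(pat, cover, mean_biomass) else pat
  }
  if (nsim == 1L) return(one(seed))
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  lapply(seeds, one)
}

#' @export
residuals.pattern_filter <- function(object, ...) {
  f <- object$optim[[1]]
  # recompute on the fitted bins of the first (or only) axis
  emp <- object$empirical[[1]]
  dk <- attr(emp, "dk"); keep <- emp$k > 1.5 * dk
  k <- emp$k[keep]; S <- emp$S[keep]
  S <- S / (sum(S) * dk / (2 * pi))
  Sf <- predict(object, k, axis = "x")
  Sf <- Sf / (sum(Sf) * dk / (2 * pi))
  stats::setNames(sqrt(S) - sqrt(Sf), signif(k, 4))
}

#' @export
plot.pattern_filter <- function(x, log = "", ...) {
  emp <- x$empirical[[1]]
  dk <- attr(emp, "dk"); keep <- emp$k > 1.5 * dk
  k <- emp$k[keep]; S <- emp$S[keep]
  S <- S / (sum(S) * dk / (2 * pi))
  Sf <- predict(x, k, axis = "x")
  Sf <- Sf / (sum(Sf) * dk / (2 * pi))
  graphics::plot(k, S, type = "p", pch = 16, cex = 0.6, log = log,
                 xlab = "k [rad/m]", ylab = "spectral density [m]", ...)
  graphics::lines(k, Sf, col = 2, lwd = 2)
  graphics::legend("topright", c("empirical", "fitted"), pch = c(16, NA),
                   lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}
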