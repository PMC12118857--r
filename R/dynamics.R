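# Nonlinear pattern-forming models: a single-species grazing model (irregular
# patterns) and the Rietkerk scale-dependent feedback model (regular
# patterns), integrated on periodic 1-D/2-D grids with spatially varying
# coefficients.

#' Parameters of the grazing model
#'
#' Logistic regrowth, saturating grazing loss and lateral spread:
#' `db/dt = a b (1 - b/K) - c b^2/(b_n^2 + b^2) + e lap(b)`.
#' Defaults are the standard parameterization used throughout the package.
#'
#' @param a minimum regrowth rate, 1/d.
#' @param c grazing scale, g/m^2/d.
#' @param b_n grazing half-saturation biomass, g/m^2.
#' @param e biomass diffusion, m^2/d.
#' @param K mean carrying capacity, g/m^2 (a field can be supplied at
#'   simulation time to make it spatially heterogeneous).
#' @return Object of class `grazing_params`.
#' @export
grazing_params <- function(a = 1, c = 2, b_n = 1, e = 0.1, K = 8) {
  p <- list(a = a, c = c, b_n = b_n, e = e, K = K)
  if (any(!is.finite(unlist(p))) || any(unlist(p) <= 0))
    stop("all grazing-model parameters must be positive")
  structure(p, class = "grazing_params")
}

#' Parameters of the Rietkerk model
#'
#' Three coupled fields: biomass `b`, soil water `w`, surface water `h`, with
#' plant uptake `U = g_b w/(w + k_U) b`, vegetation-enhanced infiltration
#' `I = a h (b + k_I w_0)/(b + k_I)`, rainfall `R_h`, downslope surface-water
#' advection `v_h` and diffusive spread of all three fields.
#'
#' @param c_b conversion of water uptake to biomass growth, g/mm/m^2.
#' @param d_b biomass dieback rate, 1/d.
#' @param g_b maximum specific uptake rate, mm g^-1 m^-2 d^-1.
#' @param e_b biomass diffusion, m^2/d.
#' @param a infiltration coefficient (mean), 1/d.
#' @param k_I infiltration half-saturation biomass, mm.
#' @param r_w soil-water percolation rate, 1/d.
#' @param e_w soil-water diffusion, m^2/d.
#' @param v_h surface-water advection velocity, m/d (0 on flat terrain).
#' @param e_h surface-water diffusion along x (the flow axis), m^2/d.
#' @param e_hy surface-water diffusion along y; defaults to `e_h`
#'   (isotropic).  Sloped runs typically use `e_h = 0`, `e_hy > 0`.
#' @param R_h precipitation rate, mm/d.
#' @param w_0 relative infiltration on bare ground, dimensionless.
#' @param k_U uptake half-saturation soil-water content, g/m^2.
#' @return Object of class `rietkerk_params`.
#' @export
rietkerk_params <- function(c_b = 10, d_b = 0.25, g_b = 0.05, e_b = 0.1,
                            a = 0.2, k_I = 5, r_w = 0.2, e_w = 0.1,
                            v_h = 0, e_h = 100, e_hy = NULL,
                            R_h = 0.7, w_0 = 0.2, k_U = 5) {
  p <- list(c_b = c_b, d_b = d_b, g_b = g_b, e_b = e_b, a = a, k_I = k_I,
            r_w = r_w, e_w = e_w, v_h = v_h, e_h = e_h,
            e_hy = if (is.null(e_hy)) e_h else e_hy,
            R_h = R_h, w_0 = w_0, k_U = k_U)
  if (any(!is.finite(unlist(p))) || any(unlist(p)[setdiff(names(p), "v_h")] < 0))
    stop("Rietkerk parameters must be non-negative (v_h may have either sign)")
  structure(p, class = "rietkerk_params")
}

# periodic 5-point Laplacian (R reference implementation, used by the rhs
# functions and tests; the steppers have their own C++ version)
lap_periodic_r <- function(x, dx) {
  l <- rbind(x[-1, , drop = FALSE], x[1, , drop = FALSE]) +
       rbind(x[nrow(x), , drop = FALSE], x[-nrow(x), , drop = FALSE]) - 2 * x
  if (ncol(x) > 1L)
    l <- l + cbind(x[, -1, drop = FALSE], x[, 1, drop = FALSE]) +
             cbind(x[, ncol(x), drop = FALSE], x[, -ncol(x), drop = FALSE]) - 2 * x
  l / dx^2
}

#' Right-hand side of the grazing model
#'
#' @param b biomass field (`vp_field` or matrix), g/m^2, non-negative.
#' @param params a [grazing_params()].
#' @param K carrying-capacity field (matrix or `vp_field`); defaults to the
#'   homogeneous `params$K`.
#' @param dx cell size in metres (taken from `b` if it is a `vp_field`).
#' @return Matrix `db/dt` in g/m^2/d.
#' @export
grazing_rhs <- function(b, params, K = NULL, dx = NULL) {
  bv <- field_values(b); dx <- field_dx(b, dx)
  Kv <- if (is.null(K)) matrix(params$K, nrow(bv), ncol(bv)) else field_values(K)
  if (!all(dim(Kv) == dim(bv))) stop("carrying-capacity field does not match the biomass grid")
  if (any(bv < 0)) stop("biomass must be non-negative")
  params$a * bv * (1 - bv / Kv) - params$c * bv^2 / (params$b_n^2 + bv^2) +
    params$e * lap_periodic_r(bv, dx)
}

#' Right-hand side of the Rietkerk model
#'
#' @param state list with non-negative fields `b`, `w`, `h` (matrices or
#'   `vp_field`s on a common grid).
#' @param params a [rietkerk_params()].
#' @param a infiltration-coefficient field; defaults to homogeneous `params$a`.
#' @param dx cell size in metres.
#' @return List of matrices `db`, `dw`, `dh` (time derivatives).
#' @export
rietkerk_rhs <- function(state, params, a = NULL, dx = NULL) {
  b <- field_values(state$b); w <- field_values(state$w); h <- field_values(state$h)
  dx <- field_dx(state$b, dx)
  if (any(b < 0) || any(w < 0) || any(h < 0)) stop("state fields must be non-negative")
  av <- if (is.null(a)) matrix(params$a, nrow(b), ncol(b)) else field_values(a)
  U <- params$g_b * w / (w + params$k_U) * b
  I <- av * h * (b + params$k_I * params$w_0) / (b + params$k_I)
  adv <- if (params$v_h != 0) {
    # v_h dh/dx, centred difference on the periodic x axis
    params$v_h * (rbind(h[-1, , drop = FALSE], h[1, , drop = FALSE]) -
                  rbind(h[nrow(h), , drop = FALSE], h[-nrow(h), , drop = FALSE])) / (2 * dx)
  } else 0
  d2x <- function(x) (rbind(x[-1, , drop = FALSE], x[1, , drop = FALSE]) +
                      rbind(x[nrow(x), , drop = FALSE], x[-nrow(x), , drop = FALSE]) -
                      2 * x) / dx^2
  d2y <- function(x) if (ncol(x) > 1L)
    (cbind(x[, -1, drop = FALSE], x[, 1, drop = FALSE]) +
     cbind(x[, ncol(x), drop = FALSE], x[, -ncol(x), drop = FALSE]) - 2 * x) / dx^2
  else 0 * x
  ehy <- if (is.null(params$e_hy)) params$e_h else params$e_hy
  list(db = params$c_b * U - params$d_b * b + params$e_b * lap_periodic_r(b, dx),
       dw = I - U - params$r_w * w + params$e_w * lap_periodic_r(w, dx),
       dh = params$R_h - I + adv + params$e_h * d2x(h) + ehy * d2y(h))
}

#' Spatially homogeneous equilibria
#'
#' All non-negative roots of the homogeneous steady-state equations, each
#' flagged stable or unstable with respect to homogeneous perturbations.
#'
#' @param params a [grazing_params()] or [rietkerk_params()].
#' @return Data frame with columns `b` (and `w`, `h` for the Rietkerk model)
#'   and `stable`.
#' @export
homogeneous_equilibria <- function(params) UseMethod("homogeneous_equilibria")

#' @export
homogeneous_equilibria.grazing_params <- function(params) {
  a <- params$a; K <- params$K; c <- params$c; bn <- params$b_n
  # a(1 - b/K)(bn^2 + b^2) - c b = 0, plus the bare state b = 0
  co <- c(a * bn^2, -(a * bn^2 / K + c), a, -a / K)  # ascending powers
  r <- polyroot(co)
  b <- Re(r[abs(Im(r)) < 1e-8 & Re(r) > 1e-12])
  b <- sort(c(0, b))
  drhs <- function(b) a * (1 - 2 * b / K) -
    c * 2 * b * bn^2 / (bn^2 + b^2)^2
  data.frame(b = b, stable = drhs(b) < 0)
}

#' @export
homogeneous_equilibria.rietkerk_params <- function(params) {
  p <- params
  out <- data.frame(b = 0, w = p$R_h / p$r_w, h = p$R_h / (p$a * p$w_0))
  wstar <- p$k_U * p$d_b / (p$c_b * p$g_b - p$d_b)
  if (p$c_b * p$g_b > p$d_b) {
    Ustar <- p$R_h - p$r_w * wstar
    if (Ustar > 0) {
      bstar <- p$c_b * Ustar / p$d_b
      hstar <- p$R_h / (p$a * (bstar + p$k_I * p$w_0) / (bstar + p$k_I))
      out <- rbind(out, data.frame(b = bstar, w = wstar, h = hstar))
    }
  }
  out$stable <- vapply(seq_len(nrow(out)), function(i) {
    eq <- c(b = out$b[i], w = out$w[i], h = out$h[i])
    J <- numeric_jacobian(function(s) {
      r <- rietkerk_rhs(list(b = matrix(max(s[1], 0)), w = matrix(max(s[2], 0)),
                             h = matrix(max(s[3], 0))), p, dx = 1)
      c(r$db, r$dw, r$dh)
    }, eq)
    all(Re(eigen(J, only.values = TRUE)$values) < 1e-8)
  }, logical(1))
  out
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  f0 <- f(x)
  for (j in seq_len(n)) {
    dxj <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + dxj
    J[, j] <- (f(xp) - f0) / dxj
  }
  J
}

#' Integrate the grazing model
#'
#' Explicit integration to a fixed horizon.  With a spatially heterogeneous
#' carrying capacity the model develops an irregular vegetation pattern whose
#' spectral density has its maximum at the origin (a low-pass shape).
#'
#' @param params a [grazing_params()].
#' @param grid a [vp_grid()].
#' @param K carrying-capacity field (`vp_field`); defaults to homogeneous.
#' @param b0 initial homogeneous biomass, g/m^2; defaults to the intermediate
#'   root of the homogeneous equilibrium equation.
#' @param t_end integration horizon in days.
#' @param dt time step in days (must satisfy `dt <= dx^2/(4 e)`).
#' @return A `vp_field` of biomass with attributes `t` and `clipped` (total
#'   clipped negative mass).
#' @export
simulate_grazing <- function(params, grid, K = NULL, b0 = NULL,
                             t_end = 500, dt = 0.1) {
  if (dt > grid$dx^2 / (4 * params$e))
    stop("dt violates the explicit diffusion stability bound dx^2/(4e)")
  Kv <- if (is.null(K)) matrix(params$K, grid$nx, grid$ny) else field_values(K)
  if (is.null(b0)) {
    eq <- homogeneous_equilibria(params)
    pos <- eq$b[eq$b > 1e-6]
    b0 <- if (length(pos) >= 2) sort(pos)[2] else max(eq$b)
  }
  bv <- matrix(b0, grid$nx, grid$ny)
  res <- cpp_grazing_run(bv, Kv, params$a, params$c, params$b_n, params$e,
                         grid$dx, dt, as.integer(round(t_end / dt)))
  out <- vp_field(res$b, dx = grid$dx, units = "g/m^2")
  attr(out, "t") <- t_end
  attr(out, "clipped") <- res$clipped
  out
}

#' Integrate the Rietkerk model
#'
#' Semi-implicit integration: reactions and the slow biomass/soil-water
#' diffusion are advanced explicitly, the stiff surface-water diffusion and
#' advection exactly in Fourier space.  The run stops when the radial
#' spectral density of the biomass is stationary (relative L1 change below
#' `tol` across a `check_interval`-day window) or at `t_end`.
#'
#' @param params a [rietkerk_params()].
#' @param grid a [vp_grid()].
#' @param a infiltration-coefficient field (`vp_field`); defaults to the
#'   homogeneous `params$a`.
#' @param init initial biomass: a `vp_field`/matrix used directly (e.g. a
#'   [stripe_train()] for controlled stripe experiments), or one of
#'   `"random"` (each cell independently
#'   vegetated at `b_init` with probability `init_cover` -- scattered random
#'   colonization), `"clumped"` (a log-normal field with mean `b_init/2`,
#'   unit coefficient of variation and correlation length `init_theta`), or
#'   `"homogeneous"`.  Water fields start at the bare-state values.  At the
#'   rainfall levels where patterns form the vegetated state is subcritical,
#'   so vanishing or very diffuse initial biomass dies out; establishment
#'   requires finite local biomass concentrations.
#' @param b_init biomass of seeded cells (or twice the mean of the clumped
#'   field), g/m^2.
#' @param init_cover seeding probability for `init = "random"`.
#' @param init_theta correlation length of the `"clumped"` initial field, m.
#' @param t_end hard cap on the integration horizon, days.
#' @param t_min minimum integration time before stationarity is tested, days.
#' @param dt time step, days.
#' @param tol stationarity tolerance (relative L1 change of the radial
#'   spectral density of `b`).
#' @param check_interval interval between stationarity checks, days.
#' @param seed seed for the random initial condition.
#' @param snapshots optional vector of times (days) at which biomass
#'   snapshots are stored.
#' @return Object of class `rietkerk_sim`: fields `b`, `w`, `h`, elapsed time
#'   `t`, `converged` flag, clipped mass, parameters, and any snapshots.
#' @export
simulate_rietkerk <- function(params, grid,
                              a = NULL, init = c("random", "clumped", "homogeneous"),
                              b_init = 20, init_cover = 0.1, init_theta = 10,
                              t_end = 5000, t_min = 500, dt = 0.25,
                              tol = 1e-3, check_interval = 50, seed = NULL,
                              snapshots = NULL) {
  emax <- max(params$e_b, params$e_w)
  if (emax > 0 && dt > grid$dx^2 / (4 * emax))
    stop("dt violates the explicit diffusion stability bound dx^2/(4 max(e_b, e_w))")
  if (params$v_h != 0 && abs(params$v_h) * dt / grid$dx > 1)
    stop("dt violates the advection CFL bound dx/|v_h|")
  av <- if (is.null(a)) matrix(params$a, grid$nx, grid$ny) else field_values(a)
  abar <- mean(av)
  w <- matrix(params$R_h / params$r_w, grid$nx, grid$ny)
  h <- matrix(params$R_h / (abar * params$w_0), grid$nx, grid$ny)
  b <- if (is.matrix(init) || inherits(init, "vp_field")) {
    bv <- field_values(init)
    if (!all(dim(bv) == c(grid$nx, grid$ny))) stop("initial biomass field does not match the grid")
    bv
  } else switch(match.arg(init),
    random = with_seed(seed, matrix(
      b_init * (stats::runif(grid$nx * grid$ny) < init_cover),
      grid$nx, grid$ny)),
    clumped = field_values(heterogeneity_field(b_init / 2, 1, theta = init_theta,
                                               grid = grid, seed = seed)),
    homogeneous = matrix(b_init / 2, grid$nx, grid$ny))

  nsteps_chunk <- max(1L, as.integer(round(check_interval / dt)))
  t <- 0; clipped <- 0; converged <- FALSE
  prev_rd <- NULL
  snaps <- list()
  next_snap <- if (!is.null(snapshots)) sort(snapshots) else numeric(0)
  while (t < t_end - 1e-9) {
    nchunk <- min(nsteps_chunk, as.integer(ceiling((t_end - t) / dt)))
    if (length(next_snap) && next_snap[1] < t + nchunk * dt)
      nchunk <- max(1L, as.integer(round((next_snap[1] - t) / dt)))
    res <- cpp_rietkerk_run(b, w, h, av, params$c_b, params$d_b, params$g_b,
                            params$e_b, params$k_I, params$r_w, params$e_w,
                            params$v_h, params$e_h, params$e_hy, params$R_h,
                            params$w_0, params$k_U, grid$dx, dt, nchunk)
    b <- res$b; w <- res$w; h <- res$h
    clipped <- clipped + res$clipped
    t <- t + nchunk * dt
    if (length(next_snap) && t >= next_snap[1] - 1e-9) {
      snaps[[sprintf("t%g", next_snap[1])]] <- vp_field(b, grid$dx, "g/m^2")
      next_snap <- next_snap[-1]
    }
    if (stats::sd(b) > 1e-10) {
      rd <- radial_density(periodogram(vp_field(b, grid$dx)))
      if (!is.null(prev_rd) && t >= t_min) {
        rel <- sum(abs(rd$S - prev_rd$S)) / sum(prev_rd$S)
        if (is.finite(rel) && rel < tol) { converged <- TRUE; break }
      }
      prev_rd <- rd
    }
  }
  total_mass <- sum(b) * grid$dx^2
  if (total_mass > 0 && clipped > 1e-3 * total_mass)
    warning(sprintf("clipped negative mass (%.3g) exceeds 0.1%% of the final biomass", clipped))
  structure(list(b = vp_field(b, grid$dx, "g/m^2"),
                 w = vp_field(w, grid$dx, "mm"),
                 h = vp_field(h, grid$dx, "mm"),
                 a = vp_field(av, grid$dx, "1/d"),
                 t = t, dt = dt, converged = converged, clipped = clipped,
                 params = params, snapshots = snaps),
            class = "rietkerk_sim")
}

#' @export
print.rietkerk_sim <- function(x, ...) {
  cat(sprintf("Rietkerk simulation: %d x %d grid, t = %g d (%s), mean biomass %.3g g/m^2\n",
              nrow(x$b$values), ncol(x$b$values), x$t,
              if (x$converged) "stationary" else "t_end reached", mean(x$b$values)))
  invisible(x)
}

#' @export
plot.rietkerk_sim <- function(x, ...) plot(x$b, main = "biomass", ...)

#' Periodic stripe-train initial condition
#'
#' Vegetation stripes of the given wavelength (rounded to the nearest number
#' of repeats fitting the periodic domain) perpendicular to the x axis, used
#' to initialize controlled experiments on established banded patterns.
#'
#' @param grid a [vp_grid()].
#' @param lambda stripe spacing in metres.
#' @param cover vegetated fraction of each period.
#' @param biomass biomass of the vegetated cells, g/m^2.
#' @return A `vp_field`.
#' @export
stripe_train <- function(grid, lambda, cover = 0.3, biomass = 15) {
  nstripes <- max(1L, round(grid$Lx / lambda))
  lam <- grid$nx / nstripes
  xs <- (seq_len(grid$nx) - 1)
  v <- matrix(ifelse((xs %% lam) < cover * lam, biomass, 0), grid$nx, grid$ny)
  vp_field(v, grid$dx, "g/m^2")
}

#' Decomposition of the infiltration heterogeneity
#'
#' The infiltration rate `I = a h i_e` with enhancement factor
#' `i_e = (b + k_I w_0)/(b + k_I)` combines the exogenous coefficient `a`
#' with the endogenous vegetation feedback and water depth.  The spatial
#' heterogeneity of `I` is decomposed into standardized contributions:
#' `(I - mean(I))/sd(I) = c_a za + c_ie zie + c_h zh` by a no-intercept
#' least-squares fit on the standardized explanatory fields; each
#' coefficient reduces to the plain correlation with `I` when the
#' explanatory fields are mutually independent.
#'
#' @param sim a `rietkerk_sim` (or list with fields `b`, `h` and `a`).
#' @param params model parameters; taken from `sim` if available.
#' @return Named vector `c(c_a, c_ie, c_h)`.
#' @export
infiltration_decomposition <- function(sim, params = NULL) {
  if (is.null(params)) params <- sim$params
  b <- field_values(sim$b); h <- field_values(sim$h); a <- field_values(sim$a)
  ie <- (b + params$k_I * params$w_0) / (b + params$k_I)
  I <- a * h * ie
  std <- function(x) {
    s <- stats::sd(x)
    if (s < .Machine$double.eps * 100) return(NULL)
    (x - mean(x)) / s
  }
  zI <- std(as.vector(I))
  if (is.null(zI)) stop("infiltration field has zero variance")
  vars <- list(c_a = std(as.vector(a)), c_ie = std(as.vector(ie)),
               c_h = std(as.vector(h)))
  keep <- !vapply(vars, is.null, logical(1))
  if (any(!keep))
    warning("explanatory variable(s) with zero variance reported as 0: ",
            paste(names(vars)[!keep], collapse = ", "))
  co <- c(c_a = 0, c_ie = 0, c_h = 0)
  if (any(keep)) {
    X <- do.call(cbind, vars[keep])
    co[names(vars)[keep]] <- stats::lm.fit(X, zI)$coefficients
  }
  co
}
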