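# Scripted numerical experiments: heterogeneity sweeps, paired model/filter
# pattern prediction, the chirped-coefficient frequency-response probe, and
# the phase experiments for striped (anisotropic) patterns.

#' Sweep the degree of environmental heterogeneity
#'
#' Runs the selected model over a grid of heterogeneity levels `cv` (of the
#' infiltration coefficient for the Rietkerk model, of the carrying capacity
#' for the grazing model), for several seeds each, and tabulates the
#' spectral metrics of the resulting patterns.
#'
#' @param model `"rietkerk"` or `"grazing"`.
#' @param cv_list numeric vector of coefficient-of-variation levels.
#' @param seeds integer vector of seeds (one run per cv x seed).
#' @param grid a [vp_grid()].
#' @param params model parameters; defaults to the standard set.
#' @param theta correlation length of the heterogeneity (m); defaults to
#'   50 m for the Rietkerk model (larger than the patch scale) and 1 m for
#'   the grazing model (smaller than the patch scale).
#' @param type pattern type passed to [pattern_summary()].
#' @param n_surrogates surrogates for the periodicity test (0 = skip).
#' @param ... further arguments to [simulate_rietkerk()] / [simulate_grazing()].
#' @return Data frame with one row per run: `cv`, `seed`, `lambda_c`,
#'   `regularity` (perpendicular axis for striped runs), `p_periodic`,
#'   coherence `c_mean`, and the exogenous infiltration contribution `c_a`
#'   (Rietkerk only).
#' @export
heterogeneity_sweep <- function(model = c("rietkerk", "grazing"),
                                cv_list, seeds = 1L, grid,
                                params = NULL, theta = NULL,
                                type = c("isotropic", "anisotropic"),
                                n_surrogates = 0, ...) {
  model <- match.arg(model); type <- match.arg(type)
  if (is.null(params))
    params <- if (model == "rietkerk") rietkerk_params() else grazing_params()
  if (is.null(theta)) theta <- if (model == "rietkerk") 50 else 1
  rows <- list()
  for (cv in cv_list) for (seed in seeds) {
    run <- tryCatch({
      if (model == "rietkerk") {
        af <- heterogeneity_field(params$a, cv, theta, grid, seed = seed + 1000L)
        sim <- simulate_rietkerk(params, grid, a = af, seed = seed, ...)
        list(pat = sim$b, noise = af, sim = sim)
      } else {
        Kf <- heterogeneity_field(params$K, cv, theta, grid, seed = seed + 1000L)
        b <- simulate_grazing(params, grid, K = Kf, ...)
        list(pat = b, noise = Kf, sim = NULL)
      }
    }, error = function(e) {
      message(sprintf("run cv=%g seed=%d failed: %s", cv, seed, conditionMessage(e)))
      NULL
    })
    if (is.null(run)) next
    ps <- pattern_summary(run$pat, type = type, n_surrogates = n_surrogates,
                          seed = seed + 2000L)
    cm <- if (cv > 0 && min(grid$nx, grid$ny) >= 8)
      coherence(run$noise, run$pat)$mean else NA_real_
    ca <- if (!is.null(run$sim)) infiltration_decomposition(run$sim)[["c_a"]]
          else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cv = cv, seed = seed,
      lambda_c = ps$lambda_c,
      regularity = unname(ps$regularity[1]),
      p_periodic = ps$p_periodic, c_mean = cm, c_a = ca)
  }
  do.call(rbind, rows)
}

#' Overlap between a model pattern and a filter-predicted pattern
#'
#' Thresholds both patterns to the same cover and measures their cell-wise
#' agreement: the squared Pearson correlation (`R^2`) between the
#' thresholded fields and the overlap map (both vegetated / both bare /
#' disagreeing cells).
#'
#' @param model_pattern,filter_pattern patterns on the same grid (generic or
#'   already thresholded).
#' @param cover cover fraction for thresholding; defaults to the cover of
#'   `model_pattern` estimated by [cover_fraction()].
#' @return List of class `overlap_result`: `r2`, `overlap_fraction` (share
#'   of cells agreeing), and the integer `map` (1 both vegetated, 0 both
#'   bare, -1 disagreement).
#' @export
paired_overlap <- function(model_pattern, filter_pattern, cover = NULL) {
  a <- field_values(model_pattern); b <- field_values(filter_pattern)
  if (!all(dim(a) == dim(b))) stop("patterns must share one grid")
  if (is.null(cover)) cover <- cover_fraction(model_pattern)
  ta <- field_values(threshold_pattern(a, cover))
  tb <- field_values(threshold_pattern(b, cover))
  va <- ta > 0; vb <- tb > 0
  r2 <- stats::cor(as.vector(ta), as.vector(tb))^2
  map <- matrix(0L, nrow(a), ncol(a))
  map[va & vb] <- 1L
  map[xor(va, vb)] <- -1L
  structure(list(r2 = r2, overlap_fraction = mean(map >= 0), map = map,
                 cover = cover),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("pattern overlap at cover %.2f: R^2 = %.3f, agreeing cells %.1f%%\n",
              x$cover, x$r2, 100 * x$overlap_fraction))
  invisible(x)
}

#' Frequency response of the Rietkerk model to a chirped coefficient
#'
#' Varies the infiltration coefficient sinusoidally along a 1-D domain with
#' a slowly increasing wavelength (`lambda_range[1]` at one end to
#' `lambda_range[2]` at the other), integrates the model, and computes the
#' correlation between biomass and coefficient in sliding windows.  The
#' correlation peaks where the local forcing wavelength matches the
#' pattern's characteristic wavelength.
#'
#' @param params a [rietkerk_params()].
#' @param grid a 1-D [vp_grid()] (`ny = 1`).
#' @param amplitude relative amplitude of the coefficient oscillation.
#' @param lambda_range range of forcing wavelengths, metres; defaults to
#'   `c(lambda_c/4, 4*lambda_c)` with `lambda_c` measured from a homogeneous
#'   companion run.
#' @param window correlation window size in local forcing wavelengths.
#' @param ... passed to [simulate_rietkerk()].
#' @return Data frame with window centre `x`, local forcing wavelength
#'   `lambda_a`, and correlation `cor_ba`; the homogeneous-run wavelength is
#'   attached as attribute `lambda_c`.
#' @export
chirp_response <- function(params, grid, amplitude = 0.05,
                           lambda_range = NULL, window = 4, ...) {
  if (grid$ny != 1L) stop("the chirp experiment runs on a 1-D grid")
  if (amplitude <= 0) stop("a homogeneous coefficient has no defined correlation")
  hom <- simulate_rietkerk(params, grid, seed = 1L, ...)
  lam_c <- pattern_summary(hom$b, "anisotropic")$lambda_c
  if (is.null(lambda_range)) lambda_range <- c(lam_c / 4, 4 * lam_c)
  xs <- (seq_len(grid$nx) - 1) * grid$dx
  # chirp linear in wavelength, so all forcing scales are sampled evenly
  lam_loc0 <- lambda_range[1] + (lambda_range[2] - lambda_range[1]) * xs / grid$Lx
  kx <- 2 * pi / lam_loc0
  phase <- cumsum(c(0, (kx[-1] + kx[-grid$nx]) / 2 * grid$dx))
  a_field <- vp_field(params$a * (1 + amplitude * sin(phase)), grid$dx, "1/d")
  sim <- simulate_rietkerk(params, grid, a = a_field, seed = 1L, ...)
  b <- as.vector(sim$b$values); a <- as.vector(a_field$values)
  lam_loc <- 2 * pi / kx
  centers <- seq(lam_loc[1] * window / 2, grid$Lx - lam_loc[grid$nx] * window / 2,
                 by = grid$Lx / 64)
  rows <- lapply(centers, function(cx) {
    i <- which.min(abs(xs - cx))
    half <- window * lam_loc[i] / 2
    if (2 * half > grid$Lx) stop("correlation window exceeds the domain")
    sel <- xs >= cx - half & xs <= cx + half
    data.frame(x = cx, lambda_a = lam_loc[i],
               cor_ba = suppressWarnings(stats::cor(b[sel], a[sel])))
  })
  out <- do.call(rbind, rows)
  attr(out, "lambda_c") <- lam_c
  out
}

#' Response of a striped pattern to a localized infiltration deficit
#'
#' Runs the 1-D advective Rietkerk model with the infiltration coefficient
#' reduced at a single location and returns the local phase profile of the
#' resulting stripe train relative to an unperturbed companion run.
#' Amplitude and wavelength recover downstream of the deficit; the phase
#' offset persists.
#'
#' @param params a [rietkerk_params()] with `v_h != 0`.
#' @param grid a 1-D [vp_grid()].
#' @param location index (cell) of the deficit.
#' @param magnitude relative reduction of the coefficient (0..1).
#' @param width deficit width in cells.
#' @param lambda0 wavelength of the initial stripe train (both runs start
#'   from the same established periodic pattern).
#' @param ... passed to [simulate_rietkerk()].
#' @return List with the perturbed-run phase profile (`profile`, from
#'   [local_phase()] of the biomass), the reference profile, `delta_phi`
#'   (their phase difference), and the biomass fields.
#' @export
point_perturbation <- function(params, grid, location = round(grid$nx / 2),
                               magnitude = 0.5, width = 2, lambda0 = 85, ...) {
  if (grid$ny != 1L) stop("the perturbation experiment runs on a 1-D grid")
  av <- matrix(params$a, grid$nx, 1)
  sel <- pmin(pmax(location + seq_len(width) - 1, 1), grid$nx)
  av[sel, 1] <- av[sel, 1] * (1 - magnitude)
  b0 <- stripe_train(grid, lambda0)
  ref <- simulate_rietkerk(params, grid, init = b0, ...)
  per <- simulate_rietkerk(params, grid, a = vp_field(av, grid$dx), init = b0, ...)
  kc <- 2 * pi / pattern_summary(ref$b, "anisotropic")$lambda_c
  pr <- local_phase(per$b, k_c = kc)
  rf <- local_phase(ref$b, k_c = kc)
  list(profile = pr, reference = rf,
       delta_phi = unwrap_phase(pr$phase - rf$phase),
       b = per$b, b_ref = ref$b, k_c = kc, location = location)
}

#' Phase random walk under half-domain heterogeneity
#'
#' The 1-D advective Rietkerk model with a homogeneous infiltration
#' coefficient in the uphill half of the domain and a randomly varying one
#' in the downhill half.  The stripe phase in the heterogeneous half drifts
#' away from the deterministic carrier like a random walk; over an ensemble
#' of runs its variance grows with distance, and for weak heterogeneity the
#' phase deviation tracks the along-slope integral of the coefficient
#' anomaly.
#'
#' @param params a [rietkerk_params()] with `v_h != 0`.
#' @param grid a 1-D [vp_grid()].
#' @param cv heterogeneity level of the infiltration coefficient.
#' @param theta correlation length of the heterogeneity, metres.
#' @param n_runs ensemble size (at least 10).
#' @param seeds seeds, one per run.
#' @param ... passed to [simulate_rietkerk()].
#' @return List with `x` (positions in the heterogeneous half), `dphi`
#'   (matrix, runs x positions), `var_dphi`, the per-run correlation
#'   `cor_integral` of `dphi` with the integrated coefficient anomaly, and
#'   the boundary index.
#' @export
phase_randomwalk <- function(params, grid, cv = 0.1, theta = 10,
                             n_runs = 20, seeds = seq_len(n_runs), ...) {
  if (grid$ny != 1L) stop("the phase experiment runs on a 1-D grid")
  if (length(seeds) < 10) stop("at least 10 runs are needed for a variance estimate")
  half <- grid$nx %/% 2
  halfgrid <- vp_grid(half, 1L, grid$dx)
  b0 <- stripe_train(grid, 85)
  # companion run in an idealized homogeneous environment, same initial
  # condition: the phase deviation is measured against its phase profile
  ref <- simulate_rietkerk(params, grid, init = b0, ...)
  kc_ref <- 2 * pi / pattern_summary(ref$b, "anisotropic")$lambda_c
  lp_ref <- local_phase(ref$b, k_c = kc_ref)
  idx <- (half + 1):grid$nx
  dphi <- NULL; corint <- numeric(0)
  for (s in seeds) {
    av <- matrix(params$a, grid$nx, 1)
    het <- heterogeneity_field(params$a, cv, theta, halfgrid, seed = s)
    av[idx, 1] <- het$values[, 1]
    sim <- simulate_rietkerk(params, grid, a = vp_field(av, grid$dx),
                             init = b0, ...)
    lp <- local_phase(sim$b, k_c = kc_ref)
    dp <- unwrap_phase(lp$phase - lp_ref$phase)[idx]
    dp <- dp - dp[1]   # deviation relative to the boundary
    anom <- cumsum(av[idx, 1] - params$a) * grid$dx
    dphi <- rbind(dphi, dp)
    corint <- c(corint, suppressWarnings(stats::cor(dp, anom)))
  }
  x <- ((half + 1):grid$nx - half) * grid$dx
  list(x = x, dphi = dphi, var_dphi = apply(dphi, 2, stats::var),
       cor_integral = corint, boundary = half, k_c = kc_ref)
}

#' Patch centroids of a spotted pattern
#'
#' Connected components (8-connectivity) of the vegetated cells, via
#' EBImage's labeling.
#'
#' @param x a thresholded (binary) pattern.
#' @return Matrix with columns `x`, `y` (centroid cell coordinates) and
#'   `size` (cells).
#' @export
patch_centroids <- function(x) {
  v <- field_values(x)
  lab <- EBImage::bwlabel(EBImage::Image(v > 0))
  lv <- as.integer(EBImage::imageData(lab))
  n <- max(lv)
  if (n == 0L) stop("no vegetated patches found")
  ix <- rep(seq_len(nrow(v)), times = ncol(v))
  iy <- rep(seq_len(ncol(v)), each = nrow(v))
  keep <- lv > 0L
  cx <- tapply(ix[keep], lv[keep], mean)
  cy <- tapply(iy[keep], lv[keep], mean)
  sz <- tabulate(lv[keep], n)
  cbind(x = as.numeric(cx), y = as.numeric(cy), size = sz)
}

#' Mean neighbor count of patch centroids
#'
#' Tessellates the domain by nearest patch centroid (a rasterized Voronoi
#' diagram), counts adjacent cells of each patch, and averages over interior
#' patches (cells of border-touching Voronoi regions are excluded from the
#' average, removing edge bias).  For any stationary random point pattern in
#' the plane the expected count is 6.
#'
#' @param x a spotted (binary/thresholded) pattern, or a 2-column matrix of
#'   point coordinates (in cell units on `grid`).
#' @param grid grid for the tessellation when `x` is a coordinate matrix.
#' @param min_patches minimum number of interior patches required.
#' @return List with `mean` neighbor count, per-patch `counts`, and the
#'   number of interior patches.
#' @export
neighbor_statistics <- function(x, grid = NULL, min_patches = 30) {
  if (is.matrix(x) && ncol(x) >= 2 && !inherits(x, "vp_field")) {
    cents <- x[, 1:2, drop = FALSE]
    if (is.null(grid)) stop("a grid is required for point input")
    nx <- grid$nx; ny <- grid$ny
  } else {
    v <- field_values(x)
    nx <- nrow(v); ny <- ncol(v)
    cents <- patch_centroids(x)[, 1:2, drop = FALSE]
  }
  np <- nrow(cents)
  if (np < 3) stop("too few patches to tessellate")
  # nearest-centroid label for every cell
  best <- matrix(Inf, nx, ny); lab <- matrix(0L, nx, ny)
  cx <- matrix(seq_len(nx), nx, ny); cy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (i in seq_len(np)) {
    d2 <- (cx - cents[i, 1])^2 + (cy - cents[i, 2])^2
    sel <- d2 < best
    best[sel] <- d2[sel]; lab[sel] <- i
  }
  # adjacency between labels across cell faces
  pairs <- rbind(cbind(as.vector(lab[-nx, ]), as.vector(lab[-1, ])),
                 cbind(as.vector(lab[, -ny]), as.vector(lab[, -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  adj <- matrix(FALSE, np, np)
  adj[pairs] <- TRUE
  adj <- adj | t(adj)
  border <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
  interior <- setdiff(seq_len(np), border)
  if (length(interior) < min_patches)
    stop(sprintf("only %d interior patches (need >= %d)", length(interior), min_patches))
  counts <- rowSums(adj)[interior]
  list(mean = mean(counts), counts = counts, n_interior = length(interior))
}
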