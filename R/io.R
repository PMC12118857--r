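# File formats and fixtures.  Gridded fields travel as plain TSV (exact
# round trip), greyscale PNG (8/16-bit quicklooks, values scaled to [0,1])
# or float TIFF; metric records as CSV/JSON.

#' Read a pattern raster
#'
#' Supported formats: TSV (as written by [write_field()], exact), greyscale
#' PNG (values in `[0,1]`) and TIFF.  The cell size is read from the TSV
#' header when present, otherwise `dx` must be supplied.
#'
#' @param path file path; format inferred from the extension unless `kind`
#'   is given.
#' @param kind `"tsv"`, `"png"` or `"tiff"`.
#' @param dx cell size in metres (required for image formats).
#' @param binarize if `TRUE`, threshold the loaded raster with the bimodal
#'   (Otsu) classifier to 0/1.
#' @return A `vp_field`.
#' @export
read_pattern <- function(path, kind = NULL, dx = NULL, binarize = FALSE) {
  if (is.null(kind))
    kind <- switch(tolower(tools::file_ext(path)),
                   tsv = , txt = "tsv", png = "png", tif = , tiff = "tiff",
                   stop("cannot infer format from extension; pass kind="))
  v <- switch(kind,
    tsv = {
      hdr <- readLines(path, n = 1L)
      if (grepl("^# dx=", hdr) && is.null(dx))
        dx <- as.numeric(sub("^# dx=([0-9.eE+-]+).*", "\\1", hdr))
      as.matrix(utils::read.table(path, comment.char = "#"))
    },
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
    },
    tiff = {
      img <- tiff::readTIFF(path)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
    },
    stop("unsupported format: ", kind))
  if (is.null(dx)) stop("no pixel size in the file; supply dx")
  dimnames(v) <- NULL
  f <- vp_field(v, dx = dx)
  if (binarize) {
    thr <- cover_fraction(f)
    f <- threshold_pattern(f, thr, mean_biomass = thr)  # 0/1 values
    f$values <- (f$values > 0) + 0
  }
  f
}

#' Write a field to disk
#'
#' TSV keeps full precision (with a `# dx=` header); PNG writes a 16-bit
#' greyscale quicklook scaled to the value range; TIFF writes 32-bit floats
#' scaled to `[0,1]` with the range in the file description.
#'
#' @param x a `vp_field` or matrix.
#' @param path destination; format from extension.
#' @param dx cell size when `x` is a bare matrix.
#' @export
write_field <- function(x, path, dx = NULL) {
  v <- field_values(x); dx <- field_dx(x, dx)
  kind <- tolower(tools::file_ext(path))
  if (kind %in% c("tsv", "txt")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# dx=%.17g units=%s", dx,
                       if (inherits(x, "vp_field")) x$units else ""), con)
    # 17 significant digits round-trip doubles exactly
    writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
               con)
  } else if (kind == "png") {
    rng <- range(v); sc <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    png::writePNG(t(sc[, rev(seq_len(ncol(sc))), drop = FALSE]), path)
  } else if (kind %in% c("tif", "tiff")) {
    rng <- range(v); sc <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    tiff::writeTIFF(t(sc[, rev(seq_len(ncol(sc))), drop = FALSE]), path,
                    bits.per.sample = 32L)
  } else stop("unsupported format: ", kind)
  invisible(path)
}

#' Write a metrics record
#'
#' One flat record per analyzed pattern (wavelength, regularity, cut-off,
#' p-value, coherence, fit statistics...), written as a single-row CSV or as
#' JSON, with stable column order.
#'
#' @param record named list or one-row data frame of scalar metrics.
#' @param path destination (`.csv` or `.json`).
#' @export
write_metrics <- function(record, path) {
  rec <- as.data.frame(lapply(record, function(x) if (is.null(x)) NA else x))
  kind <- tolower(tools::file_ext(path))
  if (kind == "csv") utils::write.csv(rec, path, row.names = FALSE)
  else if (kind == "json")
    jsonlite::write_json(as.list(rec), path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported metrics format: ", kind)
  invisible(path)
}

#' Deterministic fixture fields for tests and examples
#'
#' Small seeded instances exercising the analysis operations: pure cosines,
#' white noise, hexagonal spot lattices, known-filter syntheses and a tiny
#' Rietkerk run.
#'
#' @param suite `"spectral"`, `"filters"` or `"dynamics"`.
#' @param seed integer seed.
#' @param n grid side (cells).
#' @return Named list of `vp_field`s.
#' @export
fixture_suite <- function(suite = c("spectral", "filters", "dynamics"),
                          seed = 1L, n = 64L) {
  suite <- match.arg(suite)
  g <- vp_grid(n, n)
  xs <- (seq_len(n) - 1)
  switch(suite,
    spectral = {
      kc <- 2 * pi * 8 / n
      list(cosine = vp_field(matrix(cos(kc * xs), n, n), 1),
           cosine_diag = vp_field(outer(xs, xs, function(x, y) cos(kc * (x + y) / sqrt(2))), 1),
           white = vp_field(with_seed(seed, matrix(stats::rnorm(n * n), n, n)), 1))
    },
    filters = {
      regs <- c(0.5, 1.5, 4)
      out <- lapply(seq_along(regs), function(i) {
        p <- bandpass_params(n / 8, regs[i])
        synthesize(function(kx, ky)
          bandpass_density(sqrt(kx^2 + ky^2), p$k_c, p$alpha),
          grid = g, seed = seed + i)
      })
      names(out) <- paste0("bandpass_reg", regs)
      out
    },
    dynamics = {
      prm <- rietkerk_params()
      sim <- simulate_rietkerk(prm, g, t_end = 200, t_min = 200, seed = seed)
      list(b = sim$b, w = sim$w, h = sim$h)
    })
}

#' Hexagonal spot lattice (synthetic reference pattern)
#'
#' A perfectly periodic hexagonal arrangement of circular spots; the most
#' regular isotropic pattern a domain can carry, used as a reference in
#' tests.
#'
#' @param grid a [vp_grid()].
#' @param spacing lattice constant in metres.
#' @param radius spot radius in metres.
#' @return A binary `vp_field`.
#' @export
hexagonal_pattern <- function(grid, spacing, radius = spacing / 4) {
  nxs <- max(1, round(grid$Lx / spacing))
  sx <- grid$Lx / nxs
  sy <- sx * sqrt(3) / 2
  nys <- max(1, round(grid$Ly / sy))
  sy <- grid$Ly / nys
  centers <- do.call(rbind, lapply(0:(nys - 1), function(j) {
    offs <- if (j %% 2 == 0) 0 else sx / 2
    cbind(x = (0:(nxs - 1)) * sx + offs, y = j * sy)
  }))
  v <- matrix(0, grid$nx, grid$ny)
  cx <- (matrix(seq_len(grid$nx), grid$nx, grid$ny) - 1) * grid$dx
  cy <- (matrix(seq_len(grid$ny), grid$nx, grid$ny, byrow = TRUE) - 1) * grid$dx
  for (i in seq_len(nrow(centers))) {
    ddx <- abs(cx - centers[i, 1]); ddx <- pmin(ddx, grid$Lx - ddx)
    ddy <- abs(cy - centers[i, 2]); ddy <- pmin(ddy, grid$Ly - ddy)
    v[ddx^2 + ddy^2 <= radius^2] <- 1
  }
  vp_field(v, grid$dx)
}
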