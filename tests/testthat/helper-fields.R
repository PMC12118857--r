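# shared small fixtures, built in code

cosine_field <- function(n = 64, waves = 8, dx = 1) {
  xs <- (seq_len(n) - 1)
  vp_field(matrix(cos(2 * pi * waves * xs / n), n, n), dx)
}

white_field <- function(n = 64, seed = 1, dx = 1) {
  vp_field(with_seed_test(seed, matrix(rnorm(n * n), n, n)), dx)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

bandpass_field <- function(n = 256, lambda = 32, reg = 2, seed = 1, dx = 1) {
  p <- bandpass_params(lambda * dx, reg)
  synthesize(function(kx, ky) bandpass_density(sqrt(kx^2 + ky^2), p$k_c, p$alpha),
             grid = vp_grid(n, n, dx), seed = seed)
}

# session-level cache for expensive simulations shared across tests
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}
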