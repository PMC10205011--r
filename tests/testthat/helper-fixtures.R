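# Shared fixtures. The scaled stimulation grid (40 regions, 6 noise
# amplitudes, all sites, 5 realizations at dt = 1e-5) is the workhorse for
# the regime-trend checks; it is computed once per test run and reused.

two_node_conn <- function(dist_mm = 100) {
  connectome(matrix(c(0, 1, 1, 0), 2),
             matrix(c(0, dist_mm, dist_mm, 0), 2))
}

tiny_conn <- function(n = 5, seed = 99) {
  generate_synthetic_connectome(n_regions = n, n_hubs = 1, density = 0.6,
                                seed = seed)
}

.trend_cache <- new.env(parent = emptyenv())

trend_sigmas <- c(1e-9, 1e-7, 1e-5, 1e-4, 1e-3, 1e-2)

# 40-region study: own coupling sweep (coarse grid), then the full
# noise x site x realization stimulation grid at the working coupling
get_trend_grid <- function() {
  if (!is.null(.trend_cache$grid)) return(.trend_cache$grid)
  conn <- generate_synthetic_connectome(n_regions = 40, n_hubs = 7, seed = 2)
  params <- wc_params(dt = 1e-5)
  sw <- coupling_sweep(conn,
                       sweep_spec(c_grid = seq(0.02, 0.3, by = 0.01),
                                  sigmas = 1e-5, n_realizations = 1,
                                  base_seed = 11),
                       params = params)
  spec <- sweep_spec(sigmas = trend_sigmas, sites = NULL,
                     n_realizations = 5, base_seed = 7)
  grid <- stimulation_grid(conn, spec, c = sw$working_c, params = params)
  out <- list(conn = conn, params = params, sweep = sw, spec = spec,
              effects = grid$effects, ensemble = grid$ensemble,
              peaks = grid$peaks,
              degrees = structural_degree(conn))
  .trend_cache$grid <- out
  out
}

# random positive-definite-ish FC-like symmetric matrix with unit diagonal
random_fc <- function(n) {
  m <- matrix(runif(n * n, -1, 1), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
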