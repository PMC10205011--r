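#' Simulate the delay-coupled stochastic Wilson-Cowan network
#'
#' Integrates the network with the Euler-Maruyama scheme. Inter-regional
#' coupling links excitatory populations only, delayed by `D_ij / v` rounded
#' to the nearest integer number of steps (at least one step; the delay
#' history for t < 0 is the constant initial condition). Independent
#' standard-Gaussian noise drives every population with increment
#' `(sigma / tau) * sqrt(dt)` per step. The stimulus enters the excitatory
#' sigmoid argument of the stimulated site during `[onset, offset)`. States
#' are clipped to `[0, 1]` after each step (the count of clipped updates is
#' recorded). The first `discard` seconds are dropped and the output is
#' decimated to one sample per `sample_interval`.
#'
#' Randomness is fully determined by `(seed, stream)` through a
#' counter-splittable generator, so grid cells (realizations, sites, noise
#' levels) can be simulated independently and reproducibly.
#'
#' @param conn a [connectome()] object (or `NULL` for a single isolated
#'   region).
#' @param params a [wc_params()] object.
#' @param stim a [stim_protocol()] object.
#' @param duration total simulated time (s); at least 2 s for unstimulated
#'   runs and at least `stim$offset` for stimulated runs.
#' @param seed integer base seed.
#' @param stream integer sub-stream (default 0); different streams with the
#'   same seed give independent noise realizations.
#' @param record_inhibitory also return the inhibitory series.
#' @param discard initial transient to drop (s, default 1).
#' @param sample_interval output resolution (s, default 1e-3); must be an
#'   integer multiple of `params$dt`.
#' @return An object of class `wc_sim`: list with `excitatory` (region x
#'   time matrix), optional `inhibitory`, `times`, `sample_interval`,
#'   `stim`, `params`, `seed`, `stream`, `n_clipped`.
#' @export
simulate_network <- function(conn, params = wc_params(),
                             stim = stim_protocol(site = NULL),
                             duration = 3, seed = 1, stream = 0,
                             record_inhibitory = FALSE, discard = 1,
                             sample_interval = 1e-3) {
  stopifnot(inherits(params, "wc_params"), inherits(stim, "stim_protocol"))
  if (is.null(conn)) {
    weights <- matrix(0, 1, 1)
    distances <- matrix(0, 1, 1)
    n <- 1L
  } else {
    stopifnot(inherits(conn, "connectome"))
    weights <- conn$weights
    distances <- conn$distances
    n <- conn$n_regions
  }
  site <- stim$site
  if (!is.null(site)) {
    if (site < 1 || site > n) stop("stimulation site index out of range")
    if (duration < stim$offset)
      stop("duration must cover the stimulation window for stimulated runs")
  }
  out_every <- sample_interval / params$dt
  if (abs(out_every - round(out_every)) > 1e-9)
    stop("sample_interval must be an integer multiple of dt")
  out_every <- as.integer(round(out_every))

  delay_steps <- matrix(pmax(1L, as.integer(round(
    distances / params$v / params$dt / 1000))), n, n)

  res <- wc_integrate_cpp(
    weights, delay_steps, params$tau, params$c_EE, params$c_IE, params$c_EI,
    params$c_II, params$a_E, params$a_I, params$theta_E, params$theta_I,
    params$SE_max, params$SI_max, params$c, params$sigma, params$dt,
    duration, if (is.null(site)) -1L else as.integer(site - 1L),
    stim$amplitude, stim$onset, stim$offset, params$init_value, out_every,
    discard, record_inhibitory, as.double(seed), as.double(stream))

  times <- res$first_sample + (seq_len(ncol(res$excitatory)) - 1) *
    res$sample_interval
  structure(
    list(excitatory = res$excitatory,
         inhibitory = res$inhibitory,
         times = times,
         sample_interval = res$sample_interval,
         stim = stim, params = params, seed = seed, stream = stream,
         n_clipped = res$n_clipped),
    class = "wc_sim")
}

#' Extract a time segment from a simulation
#'
#' `before` is the second preceding stimulation onset, `during` the window
#' from onset to offset; `all` returns every retained sample.
#'
#' @param sim a `wc_sim` object.
#' @param segment `"before"`, `"during"` or `"all"`.
#' @param population `"excitatory"` or `"inhibitory"`.
#' @return Region x time matrix.
#' @export
sim_segment <- function(sim, segment = c("before", "during", "all"),
                        population = c("excitatory", "inhibitory")) {
  stopifnot(inherits(sim, "wc_sim"))
  segment <- match.arg(segment)
  population <- match.arg(population)
  x <- sim[[population]]
  if (is.null(x)) stop(population, " series were not recorded")
  eps <- 1e-9
  keep <- switch(segment,
    before = sim$times > sim$stim$onset - 1 + eps &
             sim$times <= sim$stim$onset + eps,
    during = sim$times > sim$stim$onset + eps &
             sim$times <= sim$stim$offset + eps,
    all = rep(TRUE, length(sim$times)))
  if (!any(keep)) stop("requested segment is empty")
  x[, keep, drop = FALSE]
}

#' Time-averaged excitatory activity
#'
#' Arithmetic mean of each region's excitatory series over the requested
#' segment. The network mean of the returned vector is the time- and
#' network-averaged activity.
#'
#' @inheritParams sim_segment
#' @return Numeric vector of per-region means.
#' @export
time_averaged_activity <- function(sim, segment = c("before", "during",
                                                    "all")) {
  rowMeans(sim_segment(sim, match.arg(segment)))
}
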