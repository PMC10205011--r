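test_that("sigmoid transfer functions match their closed forms", {
  expect_equal(sigmoid_E(0), 0)
  expect_equal(sigmoid_I(0), 0)
  expect_equal(round(sigmoid_max(1.3, 4), 4), 0.9945)
  expect_equal(round(sigmoid_max(2, 3.7), 4), 0.9994)
  x <- seq(-10, 20, by = 0.5)
  expect_true(all(diff(sigmoid_E(x)) > 0))
  expect_true(all(sigmoid_E(x) < sigmoid_max(1.3, 4)))
  expect_equal(sigmoid_E(1e4), sigmoid_max(1.3, 4))
})

test_that("integrator sigmoid/exponential kernel matches base R", {
  x <- seq(-60, 60, length.out = 5001)
  expect_equal(stimnet:::fast_exp_cpp(x), exp(x), tolerance = 1e-14)
})

test_that("noise generator produces standard normals", {
  z <- stimnet:::rng_normals_cpp(200000, 42, 0)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(var(z) - 1), 0.02)
  expect_lt(abs(mean(z^3)), 0.05)
  expect_lt(abs(mean(z^4) - 3), 0.1)
  # independent streams are uncorrelated
  z2 <- stimnet:::rng_normals_cpp(200000, 42, 1)
  expect_lt(abs(cor(z, z2)), 0.01)
})

test_that("deterministic trajectories match a plain-R reference integrator", {
  # 3 delayed, coupled regions; modest horizon at full resolution
  w <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3)
  d_mm <- matrix(c(0, 20, 50, 20, 0, 35, 50, 35, 0), 3)
  cn <- connectome(w, d_mm)
  p <- wc_params(c = 0.3, sigma = 0, dt = 1e-4, init_value = 0.4)
  sim <- simulate_network(cn, p, stim_protocol(site = 2, onset = 0,
                                               offset = 2),
                          duration = 2, seed = 1, discard = 0,
                          sample_interval = 1e-3)
  delay_steps <- pmax(round(d_mm / p$v / p$dt / 1000), 1)
  ref <- r_reference_sim(w, delay_steps, p, stim_site = 2,
                         stim_window = c(0, 2), n_steps = 20000,
                         record_every = 10)
  expect_equal(sim$excitatory, ref, tolerance = 1e-10)
})

test_that("unstimulated isolated node relaxes to the fixed point", {
  p <- wc_params(c = 0, sigma = 0)
  sim <- simulate_network(NULL, p, stim_protocol(site = NULL), duration = 2,
                          seed = 1, record_inhibitory = TRUE)
  root <- oracle_fixed_point(p)
  expect_equal(tail(sim$excitatory[1, ], 1), root[1], tolerance = 1e-4)
  expect_equal(tail(sim$inhibitory[1, ], 1), root[2], tolerance = 1e-4)
})

test_that("identical seed and stream reproduce the trajectory bit-exactly", {
  cn <- tiny_conn()
  p <- wc_params(c = 0.1, sigma = 1e-4, dt = 1e-4)
  a <- simulate_network(cn, p, stim_protocol(site = 1), duration = 3,
                        seed = 5, stream = 3)
  b <- simulate_network(cn, p, stim_protocol(site = 1), duration = 3,
                        seed = 5, stream = 3)
  expect_identical(a$excitatory, b$excitatory)
  c <- simulate_network(cn, p, stim_protocol(site = 1), duration = 3,
                        seed = 5, stream = 4)
  expect_false(identical(a$excitatory, c$excitatory))
})

test_that("states stay within [0, 1] under strong noise", {
  cn <- tiny_conn()
  p <- wc_params(c = 0.1, sigma = 1e-2, dt = 1e-4)
  sim <- simulate_network(cn, p, stim_protocol(site = 2), duration = 3,
                          seed = 3, record_inhibitory = TRUE)
  expect_true(all(sim$excitatory >= 0 & sim$excitatory <= 1))
  expect_true(all(sim$inhibitory >= 0 & sim$inhibitory <= 1))
  expect_gt(sim$n_clipped, 0)
})

test_that("fluctuation amplitude grows monotonically with noise", {
  p <- wc_params(c = 0, sigma = 0, dt = 1e-4)
  mean_var <- vapply(c(1e-5, 1e-4, 1e-3), function(sg) {
    p$sigma <- sg
    vs <- vapply(1:10, function(r) {
      sim <- simulate_network(NULL, p, stim_protocol(site = NULL),
                              duration = 2, seed = 17, stream = r)
      var(sim$excitatory[1, ])
    }, numeric(1))
    mean(vs)
  }, numeric(1))
  expect_true(all(diff(mean_var) > 0))
})

test_that("cross-correlation lag tracks the conduction delay", {
  lag_for <- function(dist_mm) {
    cn <- two_node_conn(dist_mm)
    p <- wc_params(c = 0.5, sigma = 0, dt = 1e-5)
    sim <- simulate_network(cn, p, stim_protocol(site = 1), duration = 3,
                            seed = 1)
    functional_connectivity(sim_segment(sim, "during"))$lags[1, 2]
  }
  l50 <- lag_for(50)
  l100 <- lag_for(100)
  l150 <- lag_for(150)
  # differences isolate the delay term (the driven node's response phase
  # is common to all three): 50 mm at 10 m/s = 5 ms
  expect_lte(abs((l100 - l50) - (-5)), 1)
  expect_lte(abs((l150 - l50) - (-10)), 1)
})

test_that("deterministic stimulated peak frequency is converged in dt", {
  peak_at_dt <- function(dt) {
    p <- wc_params(c = 0, sigma = 0, dt = dt)
    sim <- simulate_network(NULL, p, stim_protocol(site = 1), duration = 3,
                            seed = 1)
    peak_frequency(welch_psd(sim_segment(sim, "during")))$f_peak
  }
  expect_equal(peak_at_dt(5e-6), peak_at_dt(1e-6))
})

test_that("time-averaged activity equals an independent streaming mean", {
  cn <- tiny_conn()
  p <- wc_params(c = 0.05, sigma = 1e-4, dt = 1e-4)
  sim <- simulate_network(cn, p, stim_protocol(site = 1), duration = 3,
                          seed = 2)
  for (seg in c("before", "during", "all")) {
    m <- sim_segment(sim, seg)
    streaming <- apply(m, 1, function(v) {
      acc <- 0
      for (k in seq_along(v)) acc <- acc + (v[k] - acc) / k
      acc
    })
    expect_equal(time_averaged_activity(sim, seg), streaming,
                 tolerance = 1e-12)
  }
  expect_equal(time_averaged_activity(sim, "before"),
               rowMeans(sim$excitatory[, 1:1000]))
})

test_that("simulation argument validation catches misuse", {
  cn <- tiny_conn()
  p <- wc_params(dt = 1e-4)
  expect_error(simulate_network(cn, p, stim_protocol(site = 9),
                                duration = 3), "out of range")
  expect_error(simulate_network(cn, p, stim_protocol(site = 1),
                                duration = 2.5), "stimulation window")
  expect_error(simulate_network(cn, wc_params(dt = 3e-4),
                                stim_protocol(site = NULL), duration = 2),
               "integer multiple")
})
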