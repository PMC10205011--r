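test_that("Welch PSD localizes a pure tone on the 2 Hz grid", {
  t <- seq(0, 0.999, by = 1e-3)
  x <- sin(2 * pi * 20 * t)
  spec <- welch_psd(x)
  expect_equal(spec$frequencies[2] - spec$frequencies[1], 2)
  expect_equal(spec$n_segments, 3)
  pk <- peak_frequency(spec)
  expect_equal(pk$f_peak, 20)
  # a frequency between bins still lands in an adjacent bin
  x2 <- sin(2 * pi * 21 * t)
  expect_lte(abs(peak_frequency(welch_psd(x2))$f_peak - 21), 2)
})

test_that("Welch PSD is invariant to constant offsets and kills constants", {
  t <- seq(0, 0.999, by = 1e-3)
  x <- 0.3 * sin(2 * pi * 12 * t)
  a <- welch_psd(x)
  b <- welch_psd(x + 0.77)
  expect_lt(max(abs(a$power - b$power)), 1e-12)

  const <- welch_psd(rep(0.5, 1000))
  expect_true(all(const$power == 0))
  pk <- peak_frequency(const)
  expect_true(pk$flat)
  expect_equal(pk$f_peak, 0)
})

test_that("integrated Welch PSD approximates the series variance", {
  # Parseval-style check: for white noise, sum(P) * df ~ var(x)
  set.seed(1)
  ratios <- vapply(1:100, function(r) {
    x <- rnorm(1000)
    spec <- welch_psd(x)
    df <- spec$frequencies[2] - spec$frequencies[1]
    sum(spec$power) * df / var(x)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("welch_psd validates input length", {
  expect_error(welch_psd(rnorm(100)), "shorter than one window")
})

test_that("peak extraction matches an exhaustive scan and breaks ties low", {
  expect_equal(
    peak_frequency(structure(list(frequencies = c(0, 2, 4, 6),
                                  power = matrix(c(0, 1, 5, 2), 1),
                                  n_segments = 1,
                                  n_realizations_averaged = 1L),
                             class = "wc_spectrum"))$f_peak, 4)
  tie <- structure(list(frequencies = c(0, 2, 4, 6, 8),
                        power = matrix(c(0, 1, 5, 1, 5), 1),
                        n_segments = 1, n_realizations_averaged = 1L),
                   class = "wc_spectrum")
  expect_equal(peak_frequency(tie)$f_peak, 4)

  set.seed(42)
  freqs <- seq(0, 500, by = 2)
  for (i in 1:1000) {
    pow <- matrix(runif(length(freqs)), 1)
    spec <- structure(list(frequencies = freqs, power = pow, n_segments = 1,
                           n_realizations_averaged = 1L),
                      class = "wc_spectrum")
    keep <- freqs > 0
    best <- -Inf
    arg <- NA
    for (k in which(keep)) {
      if (pow[1, k] > best) {
        best <- pow[1, k]
        arg <- freqs[k]
      }
    }
    pk <- peak_frequency(spec)
    expect_identical(pk$f_peak, arg)
    expect_identical(pk$p_peak, best)
  }
})

test_that("averaging spectra over realizations is elementwise and linear", {
  set.seed(3)
  specs <- lapply(1:4, function(r) welch_psd(matrix(rnorm(3000), 3)))
  avg <- average_spectra(specs)
  naive <- (specs[[1]]$power + specs[[2]]$power + specs[[3]]$power +
              specs[[4]]$power) / 4
  expect_equal(avg$power, naive, tolerance = 1e-14)
  expect_equal(avg$n_realizations_averaged, 4L)
  # averaging commutes with scaling
  scaled <- average_spectra(lapply(specs, function(s) {
    s$power <- 2 * s$power
    s
  }))
  expect_equal(scaled$power, 2 * avg$power, tolerance = 1e-14)
})

test_that("peak-frequency matrices respect diagonal and noise averaging", {
  set.seed(9)
  n <- 4
  sigmas <- c(1e-7, 1e-5, 1e-3)
  peaks <- expand.grid(sigma = sigmas, site = 1:n, region = 1:n)
  peaks$f_peak_before <- runif(nrow(peaks), 0, 6)
  peaks$f_peak_during <- runif(nrow(peaks), 0, 30)
  res <- peak_frequency_matrix(peaks)
  expect_equal(length(res$by_sigma), 3)
  for (m in res$by_sigma) expect_equal(diag(m), rep(0, n))
  expect_equal(diag(res$averaged), rep(0, n))

  # noise average equals a naive elementwise loop over the off-diagonal
  for (s in 1:n) for (r in 1:n) {
    if (s == r) next
    vals <- vapply(sigmas, function(sg)
      peaks$f_peak_during[peaks$sigma == sg & peaks$site == s &
                            peaks$region == r], numeric(1))
    expect_equal(res$averaged[s, r], mean(vals))
  }

  # single sigma collapses to itself
  one <- peak_frequency_matrix(peaks[peaks$sigma == 1e-5, ])
  expect_equal(one$averaged, one$by_sigma[[1]])

  # oscillatory-before-stimulation entries can be excluded from the average
  peaks2 <- peaks
  peaks2$f_peak_before[peaks2$sigma == 1e-3] <- 20
  res2 <- peak_frequency_matrix(peaks2, exclude_oscillatory = TRUE)
  for (s in 1:n) for (r in 1:n) {
    if (s == r) next
    vals <- vapply(sigmas[1:2], function(sg)
      peaks2$f_peak_during[peaks2$sigma == sg & peaks2$site == s &
                             peaks2$region == r], numeric(1))
    expect_equal(res2$averaged[s, r], mean(vals))
  }

  expect_error(peak_frequency_matrix(peaks[-1, ]), "incomplete grid")
})
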