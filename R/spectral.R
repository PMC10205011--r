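#' Welch power spectral density
#'
#' Estimates the one-sided PSD of each region's series by Welch's method:
#' the series is demeaned as a whole, split into Hann-tapered segments of
#' `window` seconds with `overlap` fractional overlap, and the squared
#' periodograms are averaged. For 1 kHz series and 0.5-s windows the
#' frequency grid has 2 Hz resolution, and a 1-s segment yields 3
#' half-overlapping windows.
#'
#' @param x region x time matrix (or vector) sampled at `fs`.
#' @param fs sampling frequency (Hz, default 1000).
#' @param window window length (s, default 0.5).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @param demean subtract each series' mean first (default `TRUE`).
#' @return Object of class `wc_spectrum`: list with `frequencies` (Hz),
#'   `power` (region x frequency), `n_segments`,
#'   `n_realizations_averaged = 1`.
#' @export
welch_psd <- function(x, fs = 1000, window = 0.5, overlap = 0.5,
                      demean = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- nrow(x)
  T_len <- ncol(x)
  nper <- round(window * fs)
  if (T_len < nper) stop("series shorter than one window")
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, T_len - nper + 1, by = step)
  if (demean) x <- x - rowMeans(x)

  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / nper)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  n_freq <- nper %/% 2 + 1
  freqs <- (0:(n_freq - 1)) * fs / nper

  pow <- matrix(0, n, n_freq)
  for (s in starts) {
    seg <- x[, s:(s + nper - 1), drop = FALSE] *
      matrix(w, n, nper, byrow = TRUE)
    ft <- t(apply(seg, 1, fft))
    if (n == 1) ft <- matrix(ft, nrow = 1)
    p <- Mod(ft[, seq_len(n_freq), drop = FALSE])^2 * scale
    # one-sided: double all bins except DC (and Nyquist when nper is even)
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (nper %% 2 == 0) dbl[n_freq] <- 1
    pow <- pow + sweep(p, 2, dbl, "*")
  }
  pow <- pow / length(starts)
  structure(list(frequencies = freqs, power = pow,
                 n_segments = length(starts), n_realizations_averaged = 1L),
            class = "wc_spectrum")
}

#' Average spectra across realizations
#'
#' Elementwise mean of the power of several [welch_psd()] estimates computed
#' on the same frequency grid (the standard way to stabilize peak estimates
#' before extracting peak frequencies).
#'
#' @param specs list of `wc_spectrum` objects.
#' @return A `wc_spectrum` with averaged power.
#' @export
average_spectra <- function(specs) {
  stopifnot(length(specs) >= 1)
  f0 <- specs[[1]]$frequencies
  for (s in specs)
    if (!isTRUE(all.equal(s$frequencies, f0)))
      stop("spectra must share one frequency grid")
  pow <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  structure(list(frequencies = f0, power = pow,
                 n_segments = specs[[1]]$n_segments,
                 n_realizations_averaged =
                   sum(vapply(specs, `[[`, 1L, "n_realizations_averaged"))),
            class = "wc_spectrum")
}

#' Peak frequency and peak power
#'
#' Per region, the frequency at which the PSD is maximal and the power at
#' that frequency. The DC bin is excluded (after demeaning it is numerically
#' negligible but can dominate degenerate spectra); ties break toward the
#' lowest frequency. An all-zero spectrum gets `f_peak = 0` and is flagged.
#'
#' @param spec a `wc_spectrum`.
#' @return `data.frame` with columns `region`, `f_peak` (Hz), `p_peak`,
#'   `flat` (logical flag for all-zero spectra).
#' @export
peak_frequency <- function(spec) {
  stopifnot(inherits(spec, "wc_spectrum"))
  keep <- spec$frequencies > 0
  freqs <- spec$frequencies[keep]
  pow <- spec$power[, keep, drop = FALSE]
  n <- nrow(pow)
  f_peak <- numeric(n)
  p_peak <- numeric(n)
  flat <- logical(n)
  for (i in seq_len(n)) {
    if (all(pow[i, ] == 0)) {
      flat[i] <- TRUE
      f_peak[i] <- 0
      p_peak[i] <- 0
    } else {
      k <- which.max(pow[i, ])  # first maximum = lowest frequency on ties
      f_peak[i] <- freqs[k]
      p_peak[i] <- pow[i, k]
    }
  }
  data.frame(region = seq_len(n), f_peak = f_peak, p_peak = p_peak,
             flat = flat)
}

#' Site x region peak-frequency matrices and their noise average
#'
#' Assembles, from a tidy per-run peak table, one matrix per noise amplitude
#' whose entry (site, region) is the during-stimulation peak frequency of
#' `region` when `site` is stimulated, plus the matrix averaged across noise
#' amplitudes. Diagonal entries (the stimulated region itself) are set to 0
#' by convention. Optionally, entries whose region was already oscillatory
#' before stimulation (pre-stimulation peak frequency above
#' `oscillatory_threshold`) are excluded from the noise average.
#'
#' @param peaks `data.frame` with columns `sigma`, `site`, `region`,
#'   `f_peak_before`, `f_peak_during` covering a full site x sigma grid.
#' @param exclude_oscillatory drop oscillatory-before-stimulation entries
#'   from the average (default `FALSE`).
#' @param oscillatory_threshold Hz (default 10).
#' @return List with `by_sigma` (named list of site x region matrices) and
#'   `averaged` (site x region matrix averaged over sigma).
#' @export
peak_frequency_matrix <- function(peaks, exclude_oscillatory = FALSE,
                                  oscillatory_threshold = 10) {
  req <- c("sigma", "site", "region", "f_peak_before", "f_peak_during")
  if (!all(req %in% names(peaks)))
    stop("peaks must have columns ", paste(req, collapse = ", "))
  sigmas <- sort(unique(peaks$sigma))
  sites <- sort(unique(peaks$site))
  regions <- sort(unique(peaks$region))
  if (!setequal(sites, regions))
    stop("incomplete grid: sites and regions must coincide")
  n <- length(regions)
  by_sigma <- list()
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (s in sigmas) {
    sub <- peaks[peaks$sigma == s, ]
    if (nrow(sub) != n * n)
      stop("incomplete grid at sigma = ", s)
    m <- matrix(NA_real_, n, n)
    m[cbind(match(sub$site, sites), match(sub$region, regions))] <-
      sub$f_peak_during
    diag(m) <- 0
    by_sigma[[format(s, scientific = TRUE)]] <- m
    use <- matrix(TRUE, n, n)
    if (exclude_oscillatory) {
      osc <- matrix(FALSE, n, n)
      osc[cbind(match(sub$site, sites), match(sub$region, regions))] <-
        sub$f_peak_before > oscillatory_threshold
      use <- !osc
    }
    acc[use] <- acc[use] + m[use]
    cnt[use] <- cnt[use] + 1
  }
  avg <- acc / pmax(cnt, 1)
  avg[cnt == 0] <- NA_real_
  diag(avg) <- 0
  list(by_sigma = by_sigma, averaged = avg)
}
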