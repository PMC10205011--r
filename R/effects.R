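#' Functional connectivity by maximum lagged cross-correlation
#'
#' For every region pair, the Pearson correlation of the two series is
#' computed at every integer-sample lag within `max_lag` seconds (501 lags
#' for the default 0.25 s at 1 kHz), each lag normalized by the overlapping
#' samples' own means and standard deviations, and the maximum over lags is
#' returned. In `signed` mode the maximum of the signed correlations is
#' taken; in `absolute` mode the lag maximizing `|r|` is chosen and the
#' signed value there is returned. The matrix is symmetric by construction
#' (the lag range is symmetric) with unit diagonal. Pairs for which every
#' lag has a zero-variance overlap in either series are set to 0 and
#' flagged.
#'
#' @param segment region x time matrix sampled at `fs` (one 1-s window by
#'   default protocol).
#' @param fs sampling frequency (Hz, default 1000).
#' @param max_lag maximum lag (s, default 0.25); must be shorter than the
#'   window.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return Object of class `fc_matrix`: list with `values`, `lags` (the
#'   maximizing lag in samples, antisymmetric), `flags` (zero-variance
#'   pairs), `mode`, `max_lag`, `window`.
#' @export
functional_connectivity <- function(segment, fs = 1000, max_lag = 0.25,
                                    mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  segment <- as.matrix(segment)
  # per-lag Pearson is invariant to constant offsets; removing the row
  # means up front keeps the windowed sums well conditioned
  segment <- segment - rowMeans(segment)
  lag_samp <- as.integer(round(max_lag * fs))
  if (lag_samp >= ncol(segment))
    stop("max_lag must be shorter than the segment")
  res <- fc_max_xcorr_cpp(segment, lag_samp, mode == "absolute")
  structure(list(values = res$values, lags = res$lags, flags = res$flags,
                 mode = mode, max_lag = max_lag,
                 window = ncol(segment) / fs),
            class = "fc_matrix")
}

.fc_values <- function(x) {
  if (inherits(x, "fc_matrix")) x$values else as.matrix(x)
}

#' Functional effect of stimulation
#'
#' Mean absolute change of the upper-triangle functional connectivity
#' between the during- and before-stimulation segments:
#' `fe = |FC_d - FC_b|`, the bars denoting the average of absolute values
#' over the strictly upper triangle.
#'
#' @param fc_d,fc_b during- and before-stimulation FC (`fc_matrix` objects
#'   or plain matrices of equal dimension).
#' @return Scalar `fe >= 0`.
#' @export
functional_effect <- function(fc_d, fc_b) {
  d <- .fc_values(fc_d)
  b <- .fc_values(fc_b)
  if (!all(dim(d) == dim(b))) stop("dimension mismatch between FC matrices")
  ut <- upper.tri(d)
  mean(abs(d[ut] - b[ut]))
}

#' Structural effect of stimulation
#'
#' Change in structure-function coupling:
#' `se = corr(FC_d, SC) - corr(FC_b, SC)`, each term the Pearson correlation
#' between the strictly-upper-triangle entries of a functional connectivity
#' matrix and of the structural weights (all pairs, including structurally
#' unconnected ones). A zero-variance FC upper triangle makes the
#' corresponding correlation 0, with a warning.
#'
#' @inheritParams functional_effect
#' @param conn a [connectome()] object (or a structural weight matrix).
#' @return Scalar `se` in `[-2, 2]`.
#' @export
structural_effect <- function(fc_d, fc_b, conn) {
  sc <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  d <- .fc_values(fc_d)
  b <- .fc_values(fc_b)
  if (!all(dim(d) == dim(b)) || !all(dim(d) == dim(sc)))
    stop("dimension mismatch between FC and SC matrices")
  ut <- upper.tri(sc)
  .safe_cor(d[ut], sc[ut]) - .safe_cor(b[ut], sc[ut])
}

.safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in upper triangle; correlation set to 0")
    return(0)
  }
  cor(x, y)
}
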