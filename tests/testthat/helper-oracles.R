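# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and its C++ kernels): plain double loops and textbook
# formulas, used to pin down the optimized implementations.

# lagged Pearson correlation, maximized over integer lags, computed pair by
# pair with mean/sd of the overlapping samples at every lag
oracle_xcorr_max <- function(x, y, max_lag, mode = "signed") {
  best <- NULL
  best_crit <- -Inf
  best_lag <- NA_integer_
  T_len <- length(x)
  for (k in -max_lag:max_lag) {
    if (k >= 0) {
      xs <- x[(1 + k):T_len]
      ys <- y[1:(T_len - k)]
    } else {
      xs <- x[1:(T_len + k)]
      ys <- y[(1 - k):T_len]
    }
    no <- length(xs)
    vx <- sum(xs^2) - sum(xs)^2 / no
    vy <- sum(ys^2) - sum(ys)^2 / no
    if (vx <= 1e-14 || vy <= 1e-14) next
    r <- (sum(xs * ys) - sum(xs) * sum(ys) / no) / sqrt(vx * vy)
    crit <- if (mode == "absolute") abs(r) else r
    if (crit > best_crit) {
      best_crit <- crit
      best <- r
      best_lag <- k
    }
  }
  if (is.null(best)) list(r = 0, lag = NA_integer_, flag = TRUE)
  else list(r = best, lag = best_lag, flag = FALSE)
}

# textbook Pearson correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_adj_r2 <- function(x, y) {
  n <- length(x)
  r2 <- oracle_pearson(x, y)^2
  1 - (1 - r2) * (n - 1) / (n - 2)
}

# two-sided p for a correlation through the t distribution
oracle_cor_p <- function(r, n) {
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

# Benjamini-Hochberg step-up, written out directly
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho as Pearson on average ranks
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# single-region Wilson-Cowan fixed point by damped Newton iteration with a
# numerical Jacobian (independent of the integrator)
oracle_fixed_point <- function(params, input = 0) {
  f <- function(v) {
    sE <- 1 / (1 + exp(-params$a_E * (params$c_EE * v[1] - params$c_IE * v[2] +
                                        input - params$theta_E))) -
      1 / (1 + exp(params$a_E * params$theta_E))
    sI <- 1 / (1 + exp(-params$a_I * (params$c_EI * v[1] - params$c_II * v[2] -
                                        params$theta_I))) -
      1 / (1 + exp(params$a_I * params$theta_I))
    c(-v[1] + (params$SE_max - v[1]) * sE,
      -v[2] + (params$SI_max - v[2]) * sI)
  }
  v <- c(0.1, 0.1)
  for (it in 1:200) {
    fv <- f(v)
    if (max(abs(fv)) < 1e-14) break
    h <- 1e-7
    J <- cbind((f(v + c(h, 0)) - fv) / h, (f(v + c(0, h)) - fv) / h)
    step <- solve(J, -fv)
    while (max(abs(step)) > 0.5) step <- step / 2
    v <- v + step
  }
  v
}

# plain-R Euler-Maruyama reference for small deterministic networks:
# full-resolution state trajectory, delays in integration steps
r_reference_sim <- function(weights, delay_steps, params, stim_site = NULL,
                            stim_amp = 1.25, stim_window = c(2, 3),
                            n_steps, record_every = 1) {
  n <- nrow(weights)
  dt <- params$dt
  kE <- 1 / (1 + exp(params$a_E * params$theta_E))
  kI <- 1 / (1 + exp(params$a_I * params$theta_I))
  max_d <- max(delay_steps)
  histE <- matrix(params$init_value, n, n_steps + max_d + 1)
  E <- rep(params$init_value, n)
  I <- rep(params$init_value, n)
  out <- matrix(NA_real_, n, floor(n_steps / record_every))
  col <- 0L
  for (s in 0:(n_steps - 1)) {
    t <- s * dt
    coup <- numeric(n)
    for (i in 1:n) for (j in 1:n) {
      if (i != j && weights[i, j] != 0)
        coup[i] <- coup[i] + weights[i, j] *
          histE[j, s - max(1, delay_steps[i, j]) + max_d + 1]
    }
    xE <- params$c_EE * E - params$c_IE * I + params$c * coup
    if (!is.null(stim_site) && t >= stim_window[1] && t < stim_window[2])
      xE[stim_site] <- xE[stim_site] + stim_amp
    sE <- 1 / (1 + exp(-params$a_E * (xE - params$theta_E))) - kE
    xI <- params$c_EI * E - params$c_II * I
    sI <- 1 / (1 + exp(-params$a_I * (xI - params$theta_I))) - kI
    E <- E + dt / params$tau * (-E + (params$SE_max - E) * sE)
    I <- I + dt / params$tau * (-I + (params$SI_max - I) * sI)
    E <- pmin(pmax(E, 0), 1)
    I <- pmin(pmax(I, 0), 1)
    histE[, s + max_d + 2] <- E
    if ((s + 1) %% record_every == 0) {
      col <- col + 1L
      out[, col] <- E
    }
  }
  out
}
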