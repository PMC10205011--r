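#' Noise-amplitude grid
#'
#' The standard decade-by-mantissa grid: `1e-9, 2e-9, ..., 9e-9, 1e-8, ...`
#' up to `to` (64 values for the default range `[1e-9, 1e-2]`).
#'
#' @param from,to inclusive bounds (powers of ten recommended).
#' @return Strictly increasing numeric vector.
#' @export
sigma_grid <- function(from = 1e-9, to = 1e-2) {
  decades <- seq(floor(log10(from)), ceiling(log10(to)))
  vals <- sort(unique(as.vector(outer(1:9, 10^decades))))
  vals[vals >= from * (1 - 1e-12) & vals <= to * (1 + 1e-12)]
}

#' Sweep / grid specification
#'
#' Defines the experimental grids: global-coupling values, noise amplitudes,
#' stimulation sites, number of noise realizations per cell, and the base
#' seed from which all per-cell random streams are derived.
#'
#' @param c_grid coupling values (default 0.01 to 0.3 in steps of 0.005).
#' @param sigmas noise amplitudes (default [sigma_grid()]).
#' @param sites stimulation sites (`NULL` = all regions).
#' @param n_realizations realizations per grid cell (default 30).
#' @param base_seed integer base seed.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(c_grid = seq(0.01, 0.3, by = 0.005),
                       sigmas = sigma_grid(), sites = NULL,
                       n_realizations = 30, base_seed = 1) {
  stopifnot(length(c_grid) >= 1, all(diff(c_grid) > 0),
            length(sigmas) >= 1, all(diff(sigmas) > 0),
            n_realizations >= 1)
  structure(list(c_grid = c_grid, sigmas = sigmas, sites = sites,
                 n_realizations = n_realizations,
                 base_seed = as.integer(base_seed)),
            class = "sweep_spec")
}

#' Detect the global-coupling bifurcation threshold
#'
#' Given network-mean activity as a function of the coupling grid, the
#' threshold `c*` is the grid value at which the increment of the mean
#' activity between consecutive grid points is largest; the working coupling
#' is the largest grid value strictly below `c*` (one grid step below). If
#' the maximal increment is less than 10 times the median increment the
#' profile has no sharp transition and an error is raised.
#'
#' @param c_grid increasing coupling values.
#' @param e_bar network- and time-averaged activity at each coupling.
#' @return List with `c_star`, `working_c` and the increment vector.
#' @export
detect_threshold <- function(c_grid, e_bar) {
  stopifnot(length(c_grid) == length(e_bar), length(c_grid) >= 3)
  inc <- diff(e_bar)
  if (max(inc) < 10 * median(inc))
    stop("no coupling threshold detected: activity profile has no sharp ",
         "transition (max increment ", signif(max(inc), 3),
         " < 10 x median increment ", signif(median(inc), 3), ")")
  k <- which.max(inc)
  list(c_star = c_grid[k + 1], working_c = c_grid[k], increments = inc)
}

#' Coupling sweep without stimulation
#'
#' Runs 2-second unstimulated simulations over the (coupling, noise) grid,
#' summarizes each cell by the time- and network-averaged activity and the
#' network-averaged peak frequency and peak power of the second second
#' (spectra averaged over realizations before peak extraction), and detects
#' the bifurcation threshold from the activity profile at the reference
#' noise amplitude.
#'
#' @param conn a [connectome()] object.
#' @param spec a [sweep_spec()]; its `sigmas` are the sweep's noise grid and
#'   `n_realizations` the per-cell realization count (1 is usually enough
#'   for threshold detection).
#' @param params a [wc_params()]; `c` and `sigma` are overridden cell-wise.
#' @param reference_sigma noise amplitude at which the threshold is read
#'   off (default 1e-5).
#' @param duration run length (s, default 2; metrics use the 1-2 s segment).
#' @return List with `table` (tidy data.frame: c, sigma, e_bar, f_peak,
#'   p_peak), `c_star`, `working_c`.
#' @export
coupling_sweep <- function(conn, spec = sweep_spec(n_realizations = 1),
                           params = wc_params(), reference_sigma = 1e-5,
                           duration = 2) {
  stopifnot(inherits(conn, "connectome"), inherits(spec, "sweep_spec"))
  rows <- list()
  idx <- 0L
  for (si in seq_along(spec$sigmas)) {
    for (ci in seq_along(spec$c_grid)) {
      p <- params
      p$c <- spec$c_grid[ci]
      p$sigma <- spec$sigmas[si]
      specs <- vector("list", spec$n_realizations)
      e_bar <- 0
      for (r in seq_len(spec$n_realizations)) {
        idx <- idx + 1L
        sim <- simulate_network(conn, p, stim_protocol(site = NULL),
                                duration = duration, seed = spec$base_seed,
                                stream = idx)
        seg <- sim_segment(sim, "before")
        e_bar <- e_bar + mean(seg)
        specs[[r]] <- welch_psd(seg)
      }
      pk <- peak_frequency(average_spectra(specs))
      rows[[length(rows) + 1L]] <- data.frame(
        c = p$c, sigma = p$sigma,
        e_bar = e_bar / spec$n_realizations,
        f_peak = mean(pk$f_peak), p_peak = mean(pk$p_peak))
    }
  }
  tab <- do.call(rbind, rows)
  ref <- spec$sigmas[which.min(abs(log10(spec$sigmas) -
                                   log10(reference_sigma)))]
  prof <- tab[tab$sigma == ref, ]
  prof <- prof[order(prof$c), ]
  thr <- detect_threshold(prof$c, prof$e_bar)
  list(table = tab, c_star = thr$c_star, working_c = thr$working_c,
       reference_sigma = ref)
}

.grid_stream <- function(i_sigma, i_site, i_real, n_sites, n_real) {
  ((i_sigma - 1) * n_sites + (i_site - 1)) * n_real + i_real
}

#' Stimulation grid over noise amplitudes, sites and realizations
#'
#' For every (sigma, site, realization) cell: one 3-second simulation with
#' the standard stimulation protocol, functional connectivity of the
#' before- (1-2 s) and during-stimulation (2-3 s) segments, the functional
#' and structural effects, and Welch spectra of both segments. Spectra are
#' accumulated per (sigma, site) and averaged over realizations before the
#' per-region peak frequencies are extracted. Effect records can be
#' checkpointed to a CSV and are skipped on re-runs if already present, so
#' an interrupted grid resumes where it stopped (peak tables are
#' recomputed).
#'
#' @param conn a [connectome()] object.
#' @param spec a [sweep_spec()] (`c_grid` is ignored here).
#' @param c working global coupling strength.
#' @param params a [wc_params()]; `c` and `sigma` are overridden.
#' @param stim a [stim_protocol()]; its `site` is overridden cell-wise.
#' @param fc_mode passed to [functional_connectivity()].
#' @param checkpoint optional CSV path for resumable effect records.
#' @param verbose print one line per (sigma, site) cell.
#' @return List with `effects` (sigma, site, realization, fe, se),
#'   `ensemble` (per sigma x site means over realizations), and `peaks`
#'   (sigma, site, region, f_peak_before, f_peak_during from
#'   realization-averaged spectra).
#' @export
stimulation_grid <- function(conn, spec, c, params = wc_params(),
                             stim = stim_protocol(), fc_mode = "signed",
                             checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(conn, "connectome"), inherits(spec, "sweep_spec"))
  sites <- if (is.null(spec$sites)) seq_len(conn$n_regions) else spec$sites
  n_real <- spec$n_realizations
  params$c <- c

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read.csv(checkpoint)
    message("resuming: ", nrow(done), " record(s) found in checkpoint")
  }

  eff_rows <- list()
  peak_rows <- list()
  for (si in seq_along(spec$sigmas)) {
    sigma <- spec$sigmas[si]
    for (ki in seq_along(sites)) {
      site <- sites[ki]
      pow_b <- NULL
      pow_d <- NULL
      for (r in seq_len(n_real)) {
        cached <- !is.null(done) &&
          any(done$sigma == sigma & done$site == site & done$realization == r)
        p <- params
        p$sigma <- sigma
        st <- stim
        st$site <- site
        stream <- .grid_stream(si, ki, r, length(sites), n_real)
        sim <- simulate_network(conn, p, st, duration = st$offset,
                                seed = spec$base_seed, stream = stream)
        seg_b <- sim_segment(sim, "before")
        seg_d <- sim_segment(sim, "during")
        sp_b <- welch_psd(seg_b)
        sp_d <- welch_psd(seg_d)
        pow_b <- if (is.null(pow_b)) sp_b$power else pow_b + sp_b$power
        pow_d <- if (is.null(pow_d)) sp_d$power else pow_d + sp_d$power
        if (cached) {
          rec <- done[done$sigma == sigma & done$site == site &
                        done$realization == r, c("sigma", "site",
                                                 "realization", "fe", "se")]
        } else {
          fc_b <- functional_connectivity(seg_b, mode = fc_mode)
          fc_d <- functional_connectivity(seg_d, mode = fc_mode)
          rec <- data.frame(sigma = sigma, site = site, realization = r,
                            fe = functional_effect(fc_d, fc_b),
                            se = structural_effect(fc_d, fc_b, conn))
          if (!is.null(checkpoint)) {
            new_file <- !file.exists(checkpoint)
            write.table(rec, checkpoint, sep = ",", row.names = FALSE,
                        col.names = new_file, append = !new_file)
          }
        }
        eff_rows[[length(eff_rows) + 1L]] <- rec
      }
      tmpl <- welch_psd(matrix(0, 1, ncol(sim_segment(sim, "before"))))
      sp_b <- structure(list(frequencies = tmpl$frequencies,
                             power = pow_b / n_real,
                             n_segments = tmpl$n_segments,
                             n_realizations_averaged = n_real),
                        class = "wc_spectrum")
      sp_d <- sp_b
      sp_d$power <- pow_d / n_real
      pk_b <- peak_frequency(sp_b)
      pk_d <- peak_frequency(sp_d)
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        sigma = sigma, site = site, region = pk_b$region,
        f_peak_before = pk_b$f_peak, f_peak_during = pk_d$f_peak)
      if (verbose)
        message(sprintf("sigma=%.1e site=%d done", sigma, site))
    }
  }
  effects <- do.call(rbind, eff_rows)
  peaks <- do.call(rbind, peak_rows)
  agg <- aggregate(cbind(fe, se) ~ sigma + site, data = effects, FUN = mean)
  names(agg)[names(agg) == "fe"] <- "fe_mean"
  names(agg)[names(agg) == "se"] <- "se_mean"
  list(effects = effects, ensemble = agg, peaks = peaks)
}

#' Association between stimulation effects and structural degree
#'
#' Per (sigma, effect family, realization) cell: the Pearson correlation
#' between the per-site effect and the sites' structural degree, the
#' two-sided p-value, and the adjusted coefficient of determination of the
#' ordinary least-squares line `effect = a + b * degree`,
#' `R2_adj = 1 - (1 - R2)(n - 1)/(n - 2)`. Benjamini-Hochberg FDR-adjusted
#' q-values are computed jointly across all (sigma, realization) cells
#' within each effect family. Cells with zero variance in effects or
#' degrees are recorded as missing and flagged. Ensemble means and standard
#' deviations of `r` and `R2_adj` over realizations are reported per sigma.
#'
#' @param effects effect records with columns `sigma`, `site`,
#'   `realization`, `fe`, `se` (as from [stimulation_grid()]).
#' @param degrees per-region degree vector from [structural_degree()].
#' @return List with `cells` (sigma, effect, realization, r, r2_adj, p, q,
#'   n_sites, degenerate) and `ensemble` (per sigma x effect mean/sd of r
#'   and R2_adj).
#' @export
degree_association <- function(effects, degrees) {
  req <- c("sigma", "site", "realization", "fe", "se")
  if (!all(req %in% names(effects)))
    stop("effects must have columns ", paste(req, collapse = ", "))
  long <- rbind(
    data.frame(sigma = effects$sigma, realization = effects$realization,
               site = effects$site, effect = "functional",
               value = effects$fe),
    data.frame(sigma = effects$sigma, realization = effects$realization,
               site = effects$site, effect = "structural",
               value = effects$se))
  cells <- lapply(split(long, list(long$effect, long$sigma,
                                   long$realization), drop = TRUE),
                  function(cell) {
    x <- degrees[cell$site]
    y <- cell$value
    n <- length(y)
    if (n < 3) stop("need at least 3 sites per (sigma, realization) cell")
    out <- data.frame(sigma = cell$sigma[1], effect = cell$effect[1],
                      realization = cell$realization[1], r = NA_real_,
                      r2_adj = NA_real_, p = NA_real_, n_sites = n,
                      degenerate = FALSE)
    if (sd(x) == 0 || sd(y) == 0) {
      out$degenerate <- TRUE
      return(out)
    }
    ct <- cor.test(x, y)
    out$r <- unname(ct$estimate)
    out$p <- ct$p.value
    out$r2_adj <- 1 - (1 - out$r^2) * (n - 1) / (n - 2)
    out
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  cells$q <- NA_real_
  for (ef in unique(cells$effect)) {
    k <- cells$effect == ef & !cells$degenerate
    cells$q[k] <- p.adjust(cells$p[k], method = "BH")
  }
  ok <- cells[!cells$degenerate, ]
  ensemble <- aggregate(cbind(r, r2_adj) ~ sigma + effect, data = ok,
                        FUN = mean)
  names(ensemble)[3:4] <- c("r_mean", "r2_adj_mean")
  sds <- aggregate(cbind(r, r2_adj) ~ sigma + effect, data = ok, FUN = sd)
  ensemble$r_sd <- sds$r
  ensemble$r2_adj_sd <- sds$r2_adj
  list(cells = cells, ensemble = ensemble)
}

#' Similarity between the noise-averaged peak-frequency matrix and the
#' structural connectivity
#'
#' Spearman rank correlation between the off-diagonal entries of the
#' site x region peak-frequency matrix (averaged across noise amplitudes)
#' and the structural weights, with both orderings of each unordered pair
#' included (plain matrix vectorization) and average ranks for ties. The
#' p-value uses the t approximation.
#'
#' @param freq_matrix square matrix (e.g. `averaged` from
#'   [peak_frequency_matrix()]).
#' @param conn a [connectome()] object (or weight matrix).
#' @return List with `rho`, `p`, `n` (number of off-diagonal entries);
#'   `rho = NA` with a warning for constant input.
#' @export
structure_frequency_similarity <- function(freq_matrix, conn) {
  sc <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  freq_matrix <- as.matrix(freq_matrix)
  if (!all(dim(freq_matrix) == dim(sc)))
    stop("matrices must have the same shape")
  off <- row(sc) != col(sc)
  x <- freq_matrix[off]
  y <- sc[off]
  keep <- !is.na(x)  # entries excluded from the noise average are dropped
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("fewer than 3 usable off-diagonal entries")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, n = n)
}

#' Cognitive-system summaries of stimulation effects
#'
#' Realization-averaged functional and structural effects per stimulation
#' site, summarized per cognitive system and noise amplitude (mean and
#' standard deviation over member sites), plus the per-site coordinates in
#' the structure-function landscape.
#'
#' @param effects effect records (columns `sigma`, `site`, `realization`,
#'   `fe`, `se`).
#' @param conn a [connectome()] object supplying the system partition.
#' @return List with `summary` (system, sigma, fe_mean, fe_sd, se_mean,
#'   se_sd, n_sites) and `landscape` (site, system, sigma, fe, se).
#' @export
system_summary <- function(effects, conn) {
  stopifnot(inherits(conn, "connectome"))
  if (any(effects$site < 1 | effects$site > conn$n_regions))
    stop("effect record references a site outside the connectome")
  per_site <- aggregate(cbind(fe, se) ~ sigma + site, data = effects,
                        FUN = mean)
  per_site$system <- conn$systems[per_site$site]
  if (anyNA(per_site$system)) stop("every site must have a system label")
  landscape <- per_site[, c("site", "system", "sigma", "fe", "se")]
  mean_tab <- aggregate(cbind(fe, se) ~ system + sigma, data = per_site,
                        FUN = mean)
  sd_tab <- aggregate(cbind(fe, se) ~ system + sigma, data = per_site,
                      FUN = function(v) if (length(v) > 1) sd(v) else 0)
  n_tab <- aggregate(site ~ system + sigma, data = per_site, FUN = length)
  summary <- data.frame(system = mean_tab$system, sigma = mean_tab$sigma,
                        fe_mean = mean_tab$fe, fe_sd = sd_tab$fe,
                        se_mean = mean_tab$se, se_sd = sd_tab$se,
                        n_sites = n_tab$site)
  list(summary = summary, landscape = landscape)
}
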