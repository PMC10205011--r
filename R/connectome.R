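#' @useDynLib stimnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate cor cor.test dist fft median p.adjust pt
#'   runif rlnorm sd
#' @importFrom utils read.csv write.table
NULL

SYSTEM_LEVELS <- c("SA", "HOC", "MDM", "subcortical")

#' Construct a structural connectome
#'
#' Bundles a weighted, undirected structural connectivity matrix with the
#' Euclidean distances between region centers, region labels and a
#' coarse-grained cognitive-system partition (sensory/association `SA`,
#' higher-order cognitive `HOC`, medial default mode `MDM`, and
#' `subcortical`).
#'
#' Both matrices must be symmetric with zero diagonal; asymmetries up to an
#' absolute tolerance of `1e-8` are resolved by averaging, anything larger is
#' an error. Weights must be non-negative and off-diagonal distances strictly
#' positive. A disconnected weight graph triggers a warning (many analyses
#' assume connectedness) but is not fatal.
#'
#' @param weights square numeric matrix of non-negative connection strengths.
#' @param distances square numeric matrix of inter-center distances (mm).
#' @param labels character vector of region names (defaults to `region_i`).
#' @param systems character vector of per-region system assignments, each one
#'   of `SA`, `HOC`, `MDM`, `subcortical`.
#' @return An object of class `connectome`: a list with elements `weights`,
#'   `distances`, `labels`, `systems`, `n_regions`.
#' @export
connectome <- function(weights, distances, labels = NULL, systems = NULL) {
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  n <- nrow(weights)
  if (ncol(weights) != n || nrow(distances) != n || ncol(distances) != n)
    stop("dimension mismatch: weights and distances must be square matrices of equal size")
  weights <- .symmetrize(weights, "weights")
  distances <- .symmetrize(distances, "distances")
  if (any(abs(diag(weights)) > 0) || any(abs(diag(distances)) > 0))
    stop("weights and distances must have zero diagonal")
  if (any(weights < 0))
    stop("negative weight in connectivity matrix")
  if (any(distances[upper.tri(distances)] <= 0))
    stop("off-diagonal distances must be strictly positive")
  if (is.null(labels)) labels <- sprintf("region_%d", seq_len(n))
  if (is.null(systems)) {
    systems <- rep("SA", n)
  } else {
    systems <- as.character(systems)
    bad <- setdiff(unique(systems), SYSTEM_LEVELS)
    if (length(bad))
      stop("unknown system label: ", paste(bad, collapse = ", "))
  }
  if (length(labels) != n || length(systems) != n)
    stop("labels and systems must have length n_regions")
  dimnames(weights) <- dimnames(distances) <- list(labels, labels)
  obj <- structure(
    list(weights = weights, distances = distances, labels = labels,
         systems = systems, n_regions = n),
    class = "connectome")
  if (!.is_connected(weights))
    warning("the graph induced by nonzero weights is disconnected")
  obj
}

.symmetrize <- function(m, what, tol = 1e-8) {
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    stop(sprintf("%s matrix is asymmetric beyond tolerance (max |A - t(A)| = %g)",
                 what, asym))
  (m + t(m)) / 2
}

.is_connected <- function(weights) {
  n <- nrow(weights)
  if (n <= 1) return(TRUE)
  adj <- weights > 0
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' @export
print.connectome <- function(x, ...) {
  dens <- mean(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %d regions, density %.2f\n", x$n_regions, dens))
  cat("  systems:", paste(sprintf("%s=%d", names(table(x$systems)),
                                  table(x$systems)), collapse = " "), "\n")
  invisible(x)
}

#' Read a connectome from plain CSV files
#'
#' Matrices are headerless square numeric CSVs; the regions file has three
#' headerless columns `index,label,system`. Asymmetries within `1e-8` are
#' symmetrized by averaging.
#'
#' @param weights_path,distances_path paths to headerless square CSV matrices.
#' @param regions_path path to the 3-column regions CSV.
#' @return A [connectome()] object.
#' @export
load_connectome <- function(weights_path, distances_path, regions_path) {
  for (p in c(weights_path, distances_path, regions_path))
    if (!file.exists(p)) stop("file not found: ", p)
  w <- as.matrix(read.csv(weights_path, header = FALSE))
  d <- as.matrix(read.csv(distances_path, header = FALSE))
  dimnames(w) <- dimnames(d) <- NULL
  reg <- read.csv(regions_path, header = FALSE,
                  col.names = c("index", "label", "system"),
                  colClasses = c("integer", "character", "character"))
  reg <- reg[order(reg$index), ]
  if (nrow(reg) != nrow(w))
    stop("dimension mismatch: regions file has ", nrow(reg),
         " rows but matrices are ", nrow(w), "x", ncol(w))
  connectome(w, d, labels = reg$label, systems = reg$system)
}

#' Write a connectome as plain CSV files
#'
#' Inverse of [load_connectome()]; numeric values are written with full
#' (17 significant digit) precision so that a load/save round trip preserves
#' the matrices bit-exactly.
#'
#' @param conn a [connectome()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_connectome <- function(conn, dir) {
  stopifnot(inherits(conn, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("weights.csv", "distances.csv", "regions.csv"))
  .write_matrix(conn$weights, paths[1])
  .write_matrix(conn$distances, paths[2])
  reg <- data.frame(index = seq_len(conn$n_regions), label = conn$labels,
                    system = conn$systems)
  write.table(reg, paths[3], sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(paths)
}

.write_matrix <- function(m, path) {
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
}

#' Generate a synthetic structural connectome
#'
#' Emulates the statistical structure of a group-level human connectome at a
#' coarse (82-region) parcellation: region centers in a 3D box of side
#' `box_size` mm, Euclidean inter-center distances, edge placement favoring
#' short distances up to the target density, connection weights decaying
#' with distance with multiplicative log-normal dispersion, and a designated
#' hub set (assigned to the subcortical system and placed centrally, as
#' subcortical nuclei are) whose incident weights are multiplied by
#' `hub_boost`, producing a heavy-tailed weighted-degree distribution.
#' Non-hub regions are split evenly at random among the SA, HOC and MDM
#' systems. If the sampled edge set leaves the graph disconnected, minimal
#' distance edges are added between components (and a message is emitted).
#'
#' @param n_regions number of regions (default 82).
#' @param n_hubs number of hub (subcortical) regions (default 14).
#' @param density fraction of region pairs connected, in (0, 1].
#' @param seed integer seed; identical seeds give identical connectomes.
#' @param weight_scale overall weight scale. The default is calibrated so
#'   that, at the default density, the global-coupling bifurcation threshold
#'   of the Wilson-Cowan network falls inside the standard coupling grid
#'   (0.01-0.3) near 0.1.
#' @param hub_boost multiplicative weight boost for edges incident to hubs.
#' @param box_size side of the 3D box containing region centers (mm).
#' @param lambda_sel distance scale (mm) of the edge-selection preference.
#' @param lambda_w distance scale (mm) of the weight decay.
#' @return A [connectome()] object.
#' @export
generate_synthetic_connectome <- function(n_regions = 82, n_hubs = 14,
                                          density = 0.3, seed = 1,
                                          weight_scale = 4,
                                          hub_boost = 3, box_size = 150,
                                          lambda_sel = 60, lambda_w = 60) {
  stopifnot(n_regions >= 2, n_hubs >= 0, n_hubs < n_regions,
            density > 0, density <= 1, weight_scale > 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  centers <- matrix(runif(n_regions * 3, 0, box_size), ncol = 3)
  D <- as.matrix(dist(centers))

  # hubs: the n_hubs regions closest to the box center
  ctr <- rep(box_size / 2, 3)
  d_ctr <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
  hubs <- order(d_ctr)[seq_len(n_hubs)]

  ut <- which(upper.tri(D))
  m_target <- max(n_regions - 1, round(density * length(ut)))
  pref <- exp(-D[ut] / lambda_sel)
  chosen <- sample(length(ut), m_target, prob = pref)
  sel <- ut[chosen]

  W <- matrix(0, n_regions, n_regions)
  w_edge <- weight_scale * exp(-D[sel] / lambda_w) *
    rlnorm(length(sel), meanlog = 0, sdlog = 0.4)
  is_hub <- logical(n_regions)
  is_hub[hubs] <- TRUE
  ri <- row(D)[sel]; ci <- col(D)[sel]
  w_edge[is_hub[ri] | is_hub[ci]] <- w_edge[is_hub[ri] | is_hub[ci]] * hub_boost
  W[sel] <- w_edge
  W <- W + t(W)

  # force connectivity: join components by their closest region pair
  comp <- .components(W > 0)
  n_added <- 0L
  while (max(comp) > 1L) {
    a <- which(comp == 1L)
    b <- which(comp != 1L)
    sub <- D[a, b, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- a[k[1]]; j <- b[k[2]]
    w <- weight_scale * exp(-D[i, j] / lambda_w)
    if (is_hub[i] || is_hub[j]) w <- w * hub_boost
    W[i, j] <- W[j, i] <- w
    n_added <- n_added + 1L
    comp <- .components(W > 0)
  }
  if (n_added > 0L)
    message("added ", n_added, " edge(s) to connect components")

  systems <- rep(NA_character_, n_regions)
  systems[hubs] <- "subcortical"
  others <- sample(setdiff(seq_len(n_regions), hubs))
  cort <- c("SA", "HOC", "MDM")
  systems[others] <- rep(cort, length.out = length(others))
  labels <- sprintf("%s_%02d", ifelse(is_hub, "sub", "ctx"),
                    seq_len(n_regions))

  connectome(W, D, labels = labels, systems = systems)
}

.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    k <- k + 1L
    stack <- start
    comp[start] <- k
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Structural degree of each region
#'
#' Weighted mode returns the weighted strength (row sums of the connectivity
#' matrix); binary mode counts nonzero off-diagonal connections.
#'
#' @param conn a [connectome()] object.
#' @param mode `"weighted"` (default) or `"binary"`.
#' @return Named numeric vector of length `n_regions`, with a `mode`
#'   attribute.
#' @export
structural_degree <- function(conn, mode = c("weighted", "binary")) {
  stopifnot(inherits(conn, "connectome"))
  mode <- match.arg(mode)
  w <- conn$weights
  diag(w) <- 0
  vals <- if (mode == "weighted") rowSums(w) else rowSums(w > 0)
  names(vals) <- conn$labels
  attr(vals, "mode") <- mode
  vals
}
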