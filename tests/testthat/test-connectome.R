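test_that("connectome constructor enforces the matrix invariants", {
  w <- matrix(c(0, 1, 1, 0), 2)
  d <- matrix(c(0, 30, 30, 0), 2)
  cn <- connectome(w, d)
  expect_s3_class(cn, "connectome")
  expect_equal(cn$n_regions, 2)
  expect_equal(unname(cn$weights), w)

  # asymmetry within 1e-8 is averaged away
  w2 <- matrix(c(0, 1, 0.999999995, 0), 2)
  cn2 <- connectome(w2, d)
  expect_equal(unname(cn2$weights[1, 2]), unname(cn2$weights[2, 1]))
  expect_equal(unname(cn2$weights[1, 2]), 0.9999999975)

  expect_error(connectome(matrix(c(0, 1, 0.9, 0), 2), d), "asymmetric")
  expect_error(connectome(matrix(c(0, -0.1, -0.1, 0), 2), d),
               "negative weight")
  expect_error(connectome(w, matrix(0, 2, 2)), "strictly positive")
  expect_error(connectome(w, matrix(0, 3, 3)), "dimension mismatch")
  expect_error(connectome(w, d, systems = c("SA", "cerebellum")),
               "unknown system label")
  expect_warning(
    connectome(matrix(0, 3, 3) , matrix(30, 3, 3) - diag(30, 3)),
    "disconnected")
})

test_that("connectome CSV round trip is bit-exact", {
  cn <- generate_synthetic_connectome(n_regions = 12, n_hubs = 3,
                                      density = 0.5, seed = 5)
  dir <- tempfile("conn")
  write_connectome(cn, dir)
  cn2 <- load_connectome(file.path(dir, "weights.csv"),
                         file.path(dir, "distances.csv"),
                         file.path(dir, "regions.csv"))
  expect_identical(cn2$weights, cn$weights)
  expect_identical(cn2$distances, cn$distances)
  expect_identical(cn2$labels, cn$labels)
  expect_identical(cn2$systems, cn$systems)
})

test_that("structural degree matches weighted and binary definitions", {
  w <- matrix(c(0, 2, 0, 2, 0, 3, 0, 3, 0), 3)
  d <- matrix(30, 3, 3) - diag(30, 3)
  cn <- connectome(w, d)
  expect_equal(as.vector(structural_degree(cn, "weighted")), c(2, 5, 3))
  expect_equal(as.vector(structural_degree(cn, "binary")), c(1, 2, 1))

  cn0 <- suppressWarnings(connectome(matrix(0, 3, 3), d))
  expect_equal(as.vector(structural_degree(cn0, "weighted")), c(0, 0, 0))
})

test_that("synthetic connectome is reproducible and satisfies its contract", {
  a <- generate_synthetic_connectome(seed = 7)
  b <- generate_synthetic_connectome(seed = 7)
  expect_identical(a$weights, b$weights)
  expect_identical(a$systems, b$systems)

  expect_equal(a$n_regions, 82)
  expect_equal(sum(a$systems == "subcortical"), 14)
  expect_true(all(a$weights >= 0))
  expect_equal(unname(diag(a$weights)), rep(0, 82))
  expect_equal(a$weights, t(a$weights))
  expect_true(stimnet:::.is_connected(a$weights))

  # hubs carry higher weighted degree by construction
  deg <- structural_degree(a)
  expect_gt(mean(deg[a$systems == "subcortical"]),
            mean(deg[a$systems != "subcortical"]))

  # realized density is close to the target
  dens <- mean(a$weights[upper.tri(a$weights)] > 0)
  expect_gt(dens, 0.25)
  expect_lt(dens, 0.35)
})

test_that("generated distances are Euclidean (triangle inequality)", {
  cn <- generate_synthetic_connectome(n_regions = 20, n_hubs = 4, seed = 3)
  D <- cn$distances
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
})

test_that("weighted-degree distribution is positively skewed with hubs", {
  skews <- vapply(1:10, function(s) {
    cn <- generate_synthetic_connectome(seed = s)
    deg <- structural_degree(cn)
    mean((deg - mean(deg))^3) / sd(deg)^3
  }, numeric(1))
  expect_gt(mean(skews), 0)
})

test_that("low-density generation is repaired to a connected graph", {
  expect_message(
    cn <- generate_synthetic_connectome(n_regions = 30, n_hubs = 3,
                                        density = 0.04, seed = 8),
    "connect")
  expect_true(stimnet:::.is_connected(cn$weights))
})
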