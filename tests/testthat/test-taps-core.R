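test_that("candidate selection finds one medoid per separated blob", {
  set.seed(1)
  blob_a <- matrix(rnorm(100, sd = 0.05), 50, 2)
  blob_b <- matrix(rnorm(100, sd = 0.05), 50, 2) + 5
  cands <- select_candidates(rbind(blob_a, blob_b), 2L,
                             density_radius = 0.5)
  expect_equal(nrow(cands), 2L)
  d_a <- min(sqrt(rowSums(sweep(cands, 2, c(0, 0))^2)))
  d_b <- min(sqrt(rowSums(sweep(cands, 2, c(5, 5))^2)))
  expect_lt(d_a, 0.3)
  expect_lt(d_b, 0.3)
})

test_that("identical samples collapse to one candidate with a warning", {
  samples <- matrix(1, 20, 2)
  expect_warning(cands <- select_candidates(samples, 5L, 0.1), "fewer")
  expect_equal(nrow(cands), 1L)
})

test_that("the first medoid of a Gaussian cloud sits near its mean", {
  set.seed(12)
  for (rep in 1:5) {
    cloud <- matrix(rnorm(2000), 1000, 2)
    # exhaustive neighbour-count oracle for the first pick
    D <- unname(as.matrix(dist(cloud)))
    counts <- rowSums(D <= 0.8)
    first_oracle <- which.max(counts)
    cands <- select_candidates(cloud, 3L, 0.8)
    expect_equal(cands[1, ], cloud[first_oracle, ])
    expect_lt(sqrt(sum(cands[1, ]^2)), 0.5)   # within 0.5 sigma of the mean
  }
})

test_that("selection rejects undersized pools and bad radii", {
  expect_error(select_candidates(matrix(0, 3, 2), 5L, 0.1),
               "below n_target")
  expect_error(select_candidates(matrix(rnorm(20), 10, 2), 2L, -1),
               "positive")
})

test_that("tsp reorder recovers sorted order on shuffled collinear chains", {
  set.seed(3)
  for (rep in 1:10) {
    n_int <- sample(3:9, 1)
    xs <- sort(runif(n_int, 0.1, 0.9))
    shuffled <- matrix(xs[sample(n_int)], ncol = 1)
    out <- tsp_reorder(shuffled, conformation(0), conformation(1))
    got <- vapply(out, conf_flatten, numeric(1))
    expect_equal(got, c(0, xs, 1))
  }
})

test_that("tsp reorder leaves an already optimal order unchanged", {
  pts <- matrix(c(0.2, 0.4, 0.6, 0.8), ncol = 1)
  out <- tsp_reorder(pts, conformation(0), conformation(1))
  expect_equal(vapply(out, conf_flatten, numeric(1)),
               c(0, 0.2, 0.4, 0.6, 0.8, 1))
})

test_that("heuristic reorder matches brute force on random 2D instances", {
  set.seed(9)
  for (rep in 1:10) {
    n_int <- 7L
    interior <- matrix(runif(2 * n_int), n_int, 2)
    start <- conformation(c(0, 0))
    end <- conformation(c(1, 1))
    all_confs <- c(list(start), lapply(seq_len(n_int), function(i)
      conformation(interior[i, ])), list(end))
    D <- pairwise_distances(all_confs)
    ref <- brute_force_tour(D)
    out <- tsp_reorder(interior, start, end)
    expect_equal(tour_length(out), ref$length, tolerance = 1e-12)
  }
})

test_that("2-opt fallback stays close to the exact optimum", {
  set.seed(14)
  for (rep in 1:5) {
    interior <- matrix(runif(20), 10, 2)
    start <- conformation(c(0, 0)); end <- conformation(c(1, 1))
    exact <- tsp_reorder(interior, start, end, exact_max = 12L)
    heur <- tsp_reorder(interior, start, end, exact_max = 0L)
    expect_lte(tour_length(heur), 1.05 * tour_length(exact))
  }
})

test_that("duplicate candidates under the metric are rejected", {
  pts <- matrix(c(0.5, 0.5, 0.7), ncol = 1)
  expect_error(tsp_reorder(pts, conformation(0), conformation(1)),
               "duplicate")
})

test_that("reorder never lengthens the incoming order", {
  set.seed(21)
  for (rep in 1:10) {
    interior <- matrix(runif(12), 6, 2)
    start <- conformation(c(0, 0)); end <- conformation(c(1, 1))
    incoming <- c(list(start), lapply(seq_len(6), function(i)
      conformation(interior[i, ])), list(end))
    out <- tsp_reorder(interior, start, end)
    expect_lte(tour_length(out), tour_length(incoming) + 1e-12)
  }
})

test_that("reparametrize splits wide gaps at the midpoint", {
  p <- taps_path(matrix(c(0, 1, 3), ncol = 1))   # gaps 1 and 2
  cfg <- taps_config(target_resolution = 1, d_min_factor = 0.5,
                     d_max_factor = 1.5)
  out <- reparametrize(p, cfg)
  expect_equal(as.numeric(path_node_matrix_test(out)), c(0, 1, 2, 3))
})

test_that("reparametrize deletes the cheaper node at tight gaps", {
  p <- taps_path(matrix(c(0, 0.50, 0.51, 1), ncol = 1))
  cfg <- taps_config(target_resolution = 1 / 3, d_min_factor = 0.5,
                     d_max_factor = 1.6)
  out <- reparametrize(p, cfg)
  X <- as.numeric(path_node_matrix_test(out))
  expect_equal(length(X), 3L)
  expect_equal(X[c(1, 3)], c(0, 1))
  expect_true(X[2] %in% c(0.50, 0.51))
  gaps <- abs(diff(X))
  expect_true(all(gaps >= 0.5 / 3 & gaps <= 1.6 / 3))
})

test_that("endpoints survive reparametrization whatever the bounds", {
  p <- taps_path(matrix(c(0, 1), ncol = 1))
  cfg <- taps_config(target_resolution = 10, d_min_factor = 0.5,
                     d_max_factor = 1.5)
  out <- reparametrize(p, cfg)   # gap far below d_min, nothing deletable
  expect_equal(path_length(out), 2L)
  expect_equal(as.numeric(path_node_matrix_test(out)), c(0, 1))
})

test_that("a full iteration on a flat landscape keeps the straight path", {
  pot <- flat_potential(2L)
  nodes <- cbind(seq(0, 2, length.out = 9), rep(0, 9))
  init <- taps_path(nodes)
  cfg <- taps_config(k_s = 100, samples_per_node = 150L, seed = 5L,
                     beta = 4, diffusion = 0.02, dt = 2e-3,
                     record_every = 10L)
  out <- suppressWarnings(taps_iteration(pot, init, cfg))
  zb <- path_z_distance(out, init)
  # within sampling noise of the input: |z-bar| below half a gap squared
  expect_lt(abs(zb), 0.5 * (2 / 8)^2)
  X <- path_node_matrix_test(out)
  expect_lt(max(abs(X[, 2])), 0.35)
  # endpoints bit-identical
  expect_identical(X[1, ], nodes[1, ])
  expect_identical(X[nrow(X), ], nodes[9, ])
})

test_that("one iteration lowers the path energy on Mueller-Brown", {
  pot <- mueller_brown()
  a <- c(-0.5582236, 1.4417258)
  b <- c(0.6234994, 0.0280378)
  alpha <- seq(0, 1, length.out = 15L)
  init <- taps_path(outer(1 - alpha, a) + outer(alpha, b))
  cfg <- taps_config(k_s = 150, samples_per_node = 200L, seed = 3L,
                     beta = 4, diffusion = 0.01, dt = 1e-3,
                     record_every = 10L)
  out <- suppressWarnings(taps_iteration(pot, init, cfg))
  line_integral <- function(p) {
    X <- path_node_matrix_test(p)
    E <- pot$energy(X)
    seg <- sqrt(rowSums(diff(X)^2))
    sum((E[-1] + E[-length(E)]) / 2 * seg)
  }
  expect_lt(line_integral(out), line_integral(init))
})

test_that("invalid iteration configs are rejected", {
  expect_error(taps_config(samples_per_node = 0L), "samples_per_node")
  expect_error(taps_config(d_min_factor = 1.2), "d_min_factor")
  pot <- flat_potential(2L)
  p2 <- taps_path(cbind(c(0, 1), c(0, 0)))
  cfg <- taps_config()
  expect_error(taps_iteration(pot, p2, cfg), "interior")
})

test_that("optimization honours max_iterations and reports honestly", {
  pot <- flat_potential(2L)
  nodes <- cbind(seq(0, 2, length.out = 7), rep(0, 7))
  cfg <- taps_config(k_s = 100, samples_per_node = 100L, seed = 2L,
                     max_iterations = 1L, convergence_tol = 1e-12,
                     beta = 4, diffusion = 0.02, dt = 2e-3,
                     record_every = 10L)
  res <- suppressWarnings(taps_optimize(pot, taps_path(nodes), cfg))
  expect_s3_class(res, "taps_result")
  expect_false(res$converged)
  expect_equal(res$iterations, 1L)
  expect_equal(nrow(res$z_bar_history), 1L)
  expect_equal(res$accumulated_samples, 5L * 100L)
})

test_that("optimization is reproducible and conserves endpoints exactly", {
  pot <- mueller_brown()
  a <- c(-0.5582236, 1.4417258)
  b <- c(0.6234994, 0.0280378)
  alpha <- seq(0, 1, length.out = 11L)
  init <- taps_path(outer(1 - alpha, a) + outer(alpha, b))
  cfg <- taps_config(k_s = 150, samples_per_node = 120L, seed = 42L,
                     max_iterations = 3L, beta = 4, diffusion = 0.01,
                     dt = 1e-3, record_every = 10L)
  r1 <- suppressWarnings(taps_optimize(pot, init, cfg,
                                       archive_paths = TRUE))
  r2 <- suppressWarnings(taps_optimize(pot, init, cfg,
                                       archive_paths = TRUE))
  expect_identical(r1$z_bar_history, r2$z_bar_history)
  expect_identical(path_node_matrix_test(r1$final_path),
                   path_node_matrix_test(r2$final_path))
  for (p in r1$iteration_paths) {
    X <- path_node_matrix_test(p)
    expect_identical(X[1, ], a)
    expect_identical(X[nrow(X), ], b)
  }
})

test_that("classical MDS embeds plane point sets exactly", {
  set.seed(6)
  nodes <- matrix(rnorm(20), 10, 2)
  p <- taps_path(nodes)
  emb <- mds_project(p, dim = 2L)
  D_in <- pairwise_distances(p$nodes)
  D_out <- unname(as.matrix(dist(emb$coords[[1]])))
  expect_equal(D_out, D_in, tolerance = 1e-8)
})

test_that("collinear nodes embed onto a line (second coordinate ~ 0)", {
  nodes <- cbind(seq(0, 3, length.out = 8), seq(0, 6, length.out = 8))
  emb <- mds_project(taps_path(nodes))
  spread <- diff(range(emb$coords[[1]][, 1]))
  expect_lt(max(abs(emb$coords[[1]][, 2])), 1e-6 * spread)
})

test_that("MDS eigen-decomposition matches a direct spectral oracle", {
  set.seed(10)
  nodes <- matrix(rnorm(35), 7, 5)
  p <- taps_path(nodes)
  emb <- mds_project(p, dim = 2L)
  D <- pairwise_distances(p$nodes)
  # Torgerson double-centering by hand
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D^2 %*% J
  ev <- eigen(B, symmetric = TRUE)
  ref <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  D_pkg <- unname(as.matrix(dist(emb$coords[[1]])))
  D_ref <- unname(as.matrix(dist(ref)))
  expect_equal(D_pkg, D_ref, tolerance = 1e-8)
})

test_that("MDS splits pooled coordinates back into per-path blocks", {
  p1 <- taps_path(matrix(rnorm(10), 5, 2))
  p2 <- taps_path(matrix(rnorm(14), 7, 2))
  emb <- mds_project(list(p1, p2))
  expect_length(emb$coords, 2L)
  expect_equal(nrow(emb$coords[[1]]), 5L)
  expect_equal(nrow(emb$coords[[2]]), 7L)
})
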