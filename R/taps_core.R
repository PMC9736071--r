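#' Configuration of the TAPS optimization loop
#'
#' @param k_s Stiffness of the PCV-s restraint used for perpendicular
#'   node sampling (energy per s^2; s in node-index units).
#' @param samples_per_node Recorded samples per interior node and
#'   iteration (> 0); the underlying step count is
#'   `samples_per_node * record_every`.
#' @param target_resolution Desired mean inter-node gap (length units).
#'   `NULL` (default) uses the initial path's mean gap.
#' @param d_min_factor,d_max_factor Deletion/insertion thresholds as
#'   multiples of `target_resolution` (`d_min_factor < 1 < d_max_factor`).
#' @param convergence_tol Threshold on the change z-bar(current, previous)
#'   below which an iteration counts toward convergence (squared-distance
#'   units).  `NULL` (default) uses 1% of the initial mean squared gap.
#' @param convergence_window Consecutive below-tolerance iterations
#'   required to declare convergence.
#' @param max_iterations Iteration cap; reaching it returns an
#'   unconverged result, not an error.
#' @param seed Master seed; per-node sampling seeds are derived
#'   deterministically from (seed, iteration, node) so the node order
#'   never affects reproducibility.
#' @param n_target Number of interior candidates kept per iteration
#'   (`NULL`: current interior node count).
#' @param density_radius Suppression radius of the density-peak candidate
#'   selection (`NULL`: half the target resolution).
#' @param beta,diffusion,dt,record_every Sampler settings for the
#'   per-node restrained runs (see [simulation_settings()]).
#' @param z_max Radius (in z units, i.e. squared distance) of the tube
#'   within which perpendicular sampling moves freely; beyond it a
#'   half-harmonic wall pushes the walker back toward the path.  The
#'   default `NULL` resolves to `(target_resolution / 2)^2`: sideways
#'   exploration up to about half an inter-node gap, the regime in which
#'   the constant-s slabs are still well separated at path bends.  `Inf`
#'   disables the wall.
#' @param k_z Tube-wall stiffness; `NULL` resolves to `8 / (beta *
#'   z_max^2)` (a wall of several k_B T one tube-radius beyond `z_max`).
#' @return An object of class `"taps_config"`.
#' @export
taps_config <- function(k_s = 100, samples_per_node = 200L,
                        target_resolution = NULL, d_min_factor = 0.5,
                        d_max_factor = 1.5, convergence_tol = NULL,
                        convergence_window = 5L, max_iterations = 50L,
                        seed = 1L, n_target = NULL, density_radius = NULL,
                        beta = 1, diffusion = 0.01, dt = 5e-3,
                        record_every = 10L, z_max = NULL, k_z = NULL) {
  stopifnot(k_s > 0, d_min_factor < 1, d_max_factor > 1,
            max_iterations >= 1, convergence_window >= 1)
  if (samples_per_node < 1) stop("samples_per_node must be >= 1")
  structure(list(k_s = k_s, samples_per_node = as.integer(samples_per_node),
                 target_resolution = target_resolution,
                 d_min_factor = d_min_factor, d_max_factor = d_max_factor,
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), n_target = n_target,
                 density_radius = density_radius, beta = beta,
                 diffusion = diffusion, dt = dt,
                 record_every = as.integer(record_every),
                 z_max = z_max, k_z = k_z),
            class = "taps_config")
}

# Deterministic per-(iteration, node) seed below 2^31, independent of the
# order nodes are processed in.
derive_seed <- function(seed, iteration, node) {
  as.integer((as.double(seed) * 100003 + iteration * 1009 + node * 7919) %%
               2147483647)
}

# Fill data-dependent config defaults from the initial path.
resolve_config <- function(config, path) {
  gaps <- path_gaps(path)
  if (is.null(config$target_resolution))
    config$target_resolution <- mean(gaps)
  if (is.null(config$convergence_tol))
    config$convergence_tol <- 0.01 * mean(gaps^2)
  if (is.null(config$density_radius))
    config$density_radius <- 0.5 * config$target_resolution
  if (is.null(config$z_max))
    config$z_max <- (config$target_resolution / 2)^2
  if (is.null(config$k_z))
    config$k_z <- if (is.finite(config$z_max))
      8 / (config$beta * config$z_max^2) else 0
  config
}

#' Select candidate nodes from pooled perpendicular samples
#'
#' Greedy density-peak medoids: repeatedly pick the sample with the most
#' neighbours within `density_radius`, then suppress all samples within
#' that radius of the pick.  Density peaks in the restrained ensembles
#' approximate the local free-energy minima of the perpendicular
#' hyperplanes, which is where the nodes of the minimum free-energy path
#' should sit.  Ties are broken by the lowest sample index, making the
#' selection deterministic.
#'
#' @param samples Matrix of pooled samples (one configuration per row).
#' @param n_target Number of candidates requested.
#' @param density_radius Neighbourhood/suppression radius (length units).
#' @param min_count_frac Stop picking once the best remaining neighbour
#'   count falls below this fraction of the first pick's count: the
#'   remaining samples are sparse excursion tails, and promoting them to
#'   path nodes would drag the path into barely-sampled territory.
#' @return Matrix of selected candidates (<= `n_target` rows; fewer, with
#'   a warning, when suppression or the density floor exhausts the pool).
#' @export
select_candidates <- function(samples, n_target, density_radius,
                              min_count_frac = 0.1) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < n_target)
    stop("pooled sample count ", nrow(samples), " is below n_target ",
         n_target)
  if (density_radius <= 0) stop("density_radius must be positive")
  picks <- select_candidates_cpp(samples, as.integer(n_target),
                                 density_radius, min_count_frac)
  if (length(picks) < n_target)
    warning("only ", length(picks), " of ", n_target, " candidates ",
            "above the density floor; continuing with fewer")
  samples[picks, , drop = FALSE]
}

#' Reorder candidate nodes as a shortest open tour
#'
#' Finds the open Hamiltonian path from `start` to `end` through all
#' candidates that minimizes the total metric length.  Instances with at
#' most `exact_max` interior nodes are solved exactly by Held-Karp
#' dynamic programming; larger ones by a nearest-neighbour tour refined
#' with 2-opt until no improving swap remains.  Ties are broken by
#' lexicographic node index, so the result is deterministic.
#'
#' @param candidates List of conformations or matrix (one per row) of the
#'   interior candidates.
#' @param start,end Endpoint conformations (returned unchanged in
#'   positions 1 and N).
#' @param metric A [metric_spec()].
#' @param exact_max Largest interior count solved exactly (default 12).
#' @return List of conformations: `start`, reordered candidates, `end`.
#' @export
tsp_reorder <- function(candidates, start, end,
                        metric = metric_spec("euclidean"),
                        exact_max = 12L) {
  cand <- normalize_nodes(candidates)
  all_nodes <- c(list(as_conformation(start)), cand,
                 list(as_conformation(end)))
  n <- length(all_nodes)
  m <- n - 2L                       # interior count
  if (m == 0L) return(all_nodes)
  D <- pairwise_distances(all_nodes, metric)
  dup <- which(D + diag(Inf, n) < 1e-12, arr.ind = TRUE)
  if (nrow(dup))
    stop("duplicate nodes under the metric: pairs ",
         paste(apply(dup[dup[, 1] < dup[, 2], , drop = FALSE], 1,
                     paste, collapse = "/"), collapse = ", "))
  order_int <- if (m <= exact_max) held_karp_open(D) else two_opt_open(D)
  all_nodes[c(1L, order_int, n)]
}

# Exact open-path DP: D indexed with start = 1, interior 2..n-1, end = n.
# Returns the optimal interior visiting order (indices into D).
held_karp_open <- function(D) {
  n <- nrow(D)
  m <- n - 2L
  interior <- seq.int(2L, n - 1L)
  nsub <- bitwShiftL(1L, m)
  C <- matrix(Inf, nsub, m)        # C[S+1, j]: best cost start->S ending at j
  P <- matrix(0L, nsub, m)         # predecessor for reconstruction
  for (j in seq_len(m))
    C[bitwShiftL(1L, j - 1L) + 1L, j] <- D[1L, interior[j]]
  for (S in seq_len(nsub - 1L)) {
    row <- C[S + 1L, ]
    if (all(!is.finite(row))) next
    for (j in seq_len(m)) {
      cj <- row[j]
      if (!is.finite(cj)) next
      if (!bitwAnd(S, bitwShiftL(1L, j - 1L))) next
      for (k in seq_len(m)) {
        if (bitwAnd(S, bitwShiftL(1L, k - 1L))) next
        S2 <- bitwOr(S, bitwShiftL(1L, k - 1L))
        val <- cj + D[interior[j], interior[k]]
        if (val < C[S2 + 1L, k] - 1e-15) {
          C[S2 + 1L, k] <- val
          P[S2 + 1L, k] <- j
        }
      }
    }
  }
  full <- nsub - 1L
  totals <- C[full + 1L, ] + D[interior, n]
  j <- which.min(totals)
  ord <- integer(m)
  S <- full
  for (pos in rev(seq_len(m))) {
    ord[pos] <- j
    pj <- P[S + 1L, j]
    S <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  interior[ord]
}

# Nearest-neighbour seed + first-improvement 2-opt for open paths.
two_opt_open <- function(D) {
  n <- nrow(D)
  interior <- seq.int(2L, n - 1L)
  # nearest-neighbour from the start
  left <- interior
  ord <- integer(0)
  cur <- 1L
  while (length(left)) {
    nxt <- left[which.min(D[cur, left])]
    ord <- c(ord, nxt)
    left <- setdiff(left, nxt)
    cur <- nxt
  }
  tour <- c(1L, ord, n)
  tour_len <- function(tt) sum(D[cbind(tt[-length(tt)], tt[-1L])])
  best <- tour_len(tour)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 2:(n - 2L)) {
      for (j in (i + 1L):(n - 1L)) {
        delta <- D[tour[i - 1L], tour[j]] + D[tour[i], tour[j + 1L]] -
          D[tour[i - 1L], tour[i]] - D[tour[j], tour[j + 1L]]
        if (delta < -1e-12) {
          tour[i:j] <- rev(tour[i:j])
          best <- best + delta
          improved <- TRUE
        }
      }
    }
  }
  tour[-c(1L, n)]
}

# Metric midpoint of two nodes: coordinate average; for the RMSD metric
# the second node is first superposed onto the first.
node_midpoint <- function(a, b, metric) {
  a <- as_conformation(a); b <- as_conformation(b)
  if (!is_euclidean(metric))
    b <- kabsch_superpose(b, a, metric$align_idx)$aligned
  conformation((a$coords + b$coords) / 2, a$labels, a$box)
}

#' Reparametrize a path to its target geometric resolution
#'
#' Maintains the geometric resolution of the path by inserting the
#' metric midpoint into any gap wider than
#' `d_max_factor * target_resolution` and deleting interior nodes
#' flanking gaps narrower than `d_min_factor * target_resolution`
#' (removing the node whose removal least increases the total path
#' length).  Endpoints are never deleted.  If deletion reopens an
#' oversized gap the insertion pass re-runs, up to 10 rounds, after
#' which a resolution-conflict error suggests changing the bounds.
#'
#' @param path A [taps_path()].
#' @param config A [taps_config()] (its `target_resolution`,
#'   `d_min_factor`, `d_max_factor` are used).
#' @return A new [taps_path()] with all gaps inside the configured bounds
#'   (as far as the fixed endpoints allow) and lambda recomputed.
#' @export
reparametrize <- function(path, config) {
  config <- resolve_config(config, path)
  d_max <- config$d_max_factor * config$target_resolution
  d_min <- config$d_min_factor * config$target_resolution
  nodes <- path$nodes
  metric <- path$metric
  for (round in seq_len(10L)) {
    changed <- FALSE
    # insertion pass
    repeat {
      gaps <- consecutive_gaps(nodes, metric)
      wide <- which(gaps > d_max)
      if (!length(wide)) break
      i <- wide[1L]
      mid <- node_midpoint(nodes[[i]], nodes[[i + 1L]], metric)
      nodes <- append(nodes, list(mid), after = i)
      changed <- TRUE
    }
    # deletion pass: only interior nodes flanking an undersized gap
    repeat {
      if (length(nodes) <= 2L) break
      gaps <- consecutive_gaps(nodes, metric)
      narrow <- which(gaps < d_min)
      if (!length(narrow)) break
      g <- narrow[which.min(gaps[narrow])]
      cand <- intersect(c(g, g + 1L), seq.int(2L, length(nodes) - 1L))
      if (!length(cand)) break      # gap flanked by the two endpoints only
      cost <- vapply(cand, function(i) {
        distance(nodes[[i - 1L]], nodes[[i + 1L]], metric) -
          distance(nodes[[i - 1L]], nodes[[i]], metric) -
          distance(nodes[[i]], nodes[[i + 1L]], metric)
      }, numeric(1))
      nodes <- nodes[-cand[which.min(cost)]]
      changed <- TRUE
    }
    gaps <- consecutive_gaps(nodes, metric)
    if (!any(gaps > d_max)) break
    if (round == 10L)
      stop("resolution conflict: insertion/deletion kept oscillating for ",
           "10 rounds; widen [d_min_factor, d_max_factor] or change ",
           "target_resolution")
  }
  taps_path(nodes, metric, path$endpoints_fixed)
}

consecutive_gaps <- function(nodes, metric) {
  N <- length(nodes)
  vapply(seq_len(N - 1L), function(i)
    distance(nodes[[i]], nodes[[i + 1L]], metric), numeric(1))
}

#' One TAPS iteration
#'
#' Runs restrained perpendicular sampling at every interior node (with
#' per-node seeds derived from `(config$seed, iteration, node)`), pools
#' the samples, selects density-peak candidates, reorders them with the
#' travelling-salesman scheme between the original endpoints, and
#' reparametrizes the result.  A node whose sampling diverges is skipped
#' with a warning and its old position kept as its own candidate.
#'
#' @param pot A `"taps_potential"`.
#' @param path Current [taps_path()] (euclidean metric).
#' @param config A [taps_config()].
#' @param iteration Iteration number (enters seed derivation).
#' @return The updated [taps_path()].
#' @export
taps_iteration <- function(pot, path, config, iteration = 1L) {
  config <- resolve_config(config, path)
  N <- path_length(path)
  if (N < 3L) stop("path needs at least one interior node to iterate")
  n_equil <- max(1L, ceiling(0.1 * config$samples_per_node))
  pools <- list()
  kept_old <- list()
  for (node in seq.int(2L, N - 1L)) {
    st <- simulation_settings(
      beta = config$beta, diffusion = config$diffusion, dt = config$dt,
      n_steps = config$samples_per_node * config$record_every,
      seed = derive_seed(config$seed, iteration, node),
      record_every = config$record_every)
    traj <- tryCatch(
      suppressWarnings(
        restrained_sample_perpendicular(pot, path, node, config$k_s, st,
                                        k_z = config$k_z,
                                        z_max = config$z_max)),
      taps_diverged = function(e) {
        warning("sampling diverged at node ", node,
                "; keeping its current position as candidate")
        NULL
      })
    if (is.null(traj)) {
      kept_old[[length(kept_old) + 1L]] <- conf_flatten(path$nodes[[node]])
    } else {
      pools[[length(pools) + 1L]] <-
        traj$frames[-seq_len(n_equil), , drop = FALSE]
    }
  }
  samples <- do.call(rbind, pools)
  # cap the pooled sample count (quadratic-time density counting)
  max_pool <- 20000L
  if (!is.null(samples) && nrow(samples) > max_pool)
    samples <- samples[seq(1L, nrow(samples),
                           length.out = max_pool), , drop = FALSE]
  n_target <- if (is.null(config$n_target)) N - 2L else config$n_target
  n_from_pool <- max(0L, n_target - length(kept_old))
  cands <- if (n_from_pool > 0L)
    select_candidates(samples, n_from_pool, config$density_radius)
  else
    matrix(numeric(0), 0, ncol(samples))
  if (length(kept_old))
    cands <- rbind(cands, do.call(rbind, kept_old))
  new_path <- tsp_reorder(cands, path$nodes[[1L]], path$nodes[[N]],
                          path$metric)
  reparametrize(taps_path(new_path, path$metric, path$endpoints_fixed),
                config)
}

#' Full TAPS path optimization
#'
#' Iterates [taps_iteration()], recording after each iteration the mean
#' path distance z-bar of the new path from the previous iterate and
#' from the initial path.  Convergence is declared when
#' z-bar(current, previous) stays below `convergence_tol` for
#' `convergence_window` consecutive iterations.  Reaching
#' `max_iterations` without convergence returns a result flagged
#' `converged = FALSE` (not an error).
#'
#' @param pot A `"taps_potential"`.
#' @param initial_path Starting [taps_path()] whose endpoints are the two
#'   target states.
#' @param config A [taps_config()].
#' @param archive_paths Keep every iterate in the result (`FALSE` by
#'   default; memory grows linearly with iterations).
#' @return A `"taps_result"`: `final_path`, `z_bar_history` (data frame
#'   `iteration`, `z_prev`, `z_init`), `iteration_paths` (list or NULL),
#'   `converged`, `iterations`, `accumulated_samples`, and the resolved
#'   `config`.
#' @export
taps_optimize <- function(pot, initial_path, config,
                          archive_paths = FALSE) {
  config <- resolve_config(config, initial_path)
  path <- initial_path
  z_prev <- z_init <- numeric(0)
  paths <- if (archive_paths) list(initial_path) else NULL
  streak <- 0L
  converged <- FALSE
  acc <- 0L
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    prev <- path
    path <- taps_iteration(pot, path, config, iteration = iter)
    acc <- acc + (path_length(prev) - 2L) * config$samples_per_node
    z_prev[iter] <- path_z_distance(path, prev)
    z_init[iter] <- path_z_distance(path, initial_path)
    if (archive_paths) paths[[length(paths) + 1L]] <- path
    # signed comparison: z-bar of two coinciding discrete paths sits
    # slightly below zero (log of overlapping node kernels), so staying
    # under the tolerance is the "no longer moving" condition
    streak <- if (z_prev[iter] < config$convergence_tol)
      streak + 1L else 0L
    if (streak >= config$convergence_window) {
      converged <- TRUE
      break
    }
  }
  structure(list(final_path = path,
                 z_bar_history = data.frame(iteration = seq_len(iter),
                                            z_prev = z_prev,
                                            z_init = z_init),
                 iteration_paths = paths, converged = converged,
                 iterations = iter, accumulated_samples = acc,
                 config = config),
            class = "taps_result")
}

#' @export
print.taps_result <- function(x, ...) {
  cat("<taps_result> ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged",
      "; final path ", path_length(x$final_path), " nodes; ",
      x$accumulated_samples, " accumulated samples\n", sep = "")
  invisible(x)
}

#' Project paths into a low-dimensional space by classical MDS
#'
#' Pools the nodes of all supplied paths, computes their pairwise metric
#' distances, and embeds them with classical (Torgerson) multidimensional
#' scaling: double-centering of the squared-distance matrix followed by
#' its top eigenpairs.  When the nodes genuinely lie in a
#' `dim`-dimensional Euclidean space the embedded distances reproduce the
#' input distances exactly.  Used to visualize how the path moves across
#' iterations.
#'
#' @param paths A [taps_path()] or list of paths (sharing one metric).
#' @param metric A [metric_spec()] (default: first path's metric).
#' @param dim Embedding dimension (2 or 3).
#' @return List with `coords` (one matrix of embedded node coordinates
#'   per path), `eigenvalues`, and `negative_fraction` (|sum of negative
#'   eigenvalues| / sum |eigenvalues|; a warning is raised above 10%,
#'   indicating strongly non-Euclidean distances).
#' @export
mds_project <- function(paths, metric = NULL, dim = 2L) {
  if (inherits(paths, "taps_path")) paths <- list(paths)
  stopifnot(length(paths) >= 1L, dim %in% c(2L, 3L))
  if (is.null(metric)) metric <- paths[[1L]]$metric
  nodes <- unlist(lapply(paths, `[[`, "nodes"), recursive = FALSE)
  D <- pairwise_distances(nodes, metric)
  fit <- stats::cmdscale(D, k = dim, eig = TRUE)
  ev <- fit$eig
  neg <- abs(sum(ev[ev < 0])) / sum(abs(ev))
  if (is.finite(neg) && neg > 0.1)
    warning("MDS distances are strongly non-Euclidean (",
            round(100 * neg, 1), "% negative eigenvalue mass)")
  X <- fit$points
  if (ncol(X) < dim)                       # degenerate (e.g. collinear)
    X <- cbind(X, matrix(0, nrow(X), dim - ncol(X)))
  counts <- vapply(paths, path_length, integer(1))
  idx <- split(seq_len(sum(counts)), rep(seq_along(paths), counts))
  list(coords = lapply(idx, function(i) X[i, , drop = FALSE]),
       eigenvalues = ev, negative_fraction = neg)
}
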