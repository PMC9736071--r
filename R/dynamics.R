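#' Simulation settings for the overdamped Langevin sampler
#'
#' The sampler integrates Brownian (overdamped Langevin) dynamics with
#' the Euler-Maruyama scheme
#'
#'   x_{t+1} = x_t - diffusion * beta * grad(U + U_bias) * dt
#'             + sqrt(2 * diffusion * dt) * xi,
#'
#' with xi standard normal per coordinate.  Identical seeds reproduce
#' trajectories bit-for-bit.  With `beta = 1` all energies are in k_B T.
#'
#' @param beta Inverse temperature (inverse energy units).
#' @param diffusion Diffusion coefficient.
#' @param dt Time step.  `dt * diffusion * beta * stiffness` must stay
#'   below 2 for the stiffest bundled mode; [simulate()] enforces this
#'   against the potential's stiffness estimate.
#' @param n_steps Number of integration steps.
#' @param seed RNG seed (integer).
#' @param record_every Record one frame every this many steps (frame 0 is
#'   always recorded, giving `floor(n_steps / record_every) + 1` frames).
#' @return An object of class `"sim_settings"`.
#' @export
simulation_settings <- function(beta = 1, diffusion = 0.01, dt = 5e-3,
                                n_steps = 10000L, seed = 1L,
                                record_every = 10L) {
  stopifnot(beta > 0, diffusion > 0, dt > 0, n_steps >= 1,
            record_every >= 1)
  structure(list(beta = beta, diffusion = diffusion, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "sim_settings")
}

settings_with <- function(settings, ...) {
  mod <- list(...)
  for (nm in names(mod)) settings[[nm]] <- mod[[nm]]
  simulation_settings(settings$beta, settings$diffusion, settings$dt,
                      settings$n_steps, settings$seed,
                      settings$record_every)
}

#' Bias potentials for the sampler
#'
#' * `bias_s_restraint(path, k, center, k_z, z_max)`: harmonic restraint
#'   k/2 (s(x) - center)^2 on the path collective variable s, with the
#'   analytic chain-rule gradient of s through the Gaussian node weights.
#'   Restrains sampling to the hyperplane perpendicular to the path at
#'   s = center.  An optional half-harmonic tube wall
#'   k_z/2 (z - z_max)^2 for z > z_max keeps the walker from spilling
#'   into the fanned-out side of the constant-s slab at tight path
#'   bends; z stays free inside the tube (`k_z = 0` disables the wall
#'   entirely).
#' * `bias_coordinate_umbrella(k, center, coord)`: harmonic umbrella
#'   k/2 (x[coord] - center)^2 on one coordinate component.
#' * `bias_moving_target(target, k, schedule_steps, d0_start)`: the
#'   targeted-dynamics restraint k/2 (|x - target| - d0(t))^2 with d0
#'   shrinking linearly from `d0_start` to 0 over `schedule_steps`.
#'
#' @param path A euclidean-metric [taps_path()].
#' @param k Restraint stiffness (> 0).
#' @param center Restraint center (s units or coordinate units).
#' @param k_z Tube-wall stiffness (energy per z^2; 0 disables).
#' @param z_max Tube radius in z units (squared distance).
#' @param coord 1-based coordinate index for the coordinate umbrella.
#' @param target Target configuration (conformation or numeric vector).
#' @param schedule_steps Steps over which the target distance shrinks.
#' @param d0_start Initial restraint distance (defaults to the start
#'   configuration's distance to the target, filled in by [simulate()]).
#' @return A bias specification of class `"taps_bias"`.
#' @name biases
NULL

#' @rdname biases
#' @export
bias_s_restraint <- function(path, k, center, k_z = 0, z_max = Inf) {
  if (k <= 0) stop("restraint stiffness k must be positive")
  if (k_z < 0) stop("tube-wall stiffness k_z must be non-negative")
  if (!is_euclidean(path$metric))
    stop("PCV-s restrained sampling requires a euclidean-metric path")
  structure(list(type = "s_restraint", path = path, k = k, center = center,
                 k_z = k_z, z_max = z_max),
            class = "taps_bias")
}

#' @rdname biases
#' @export
bias_coordinate_umbrella <- function(k, center, coord = 1L) {
  if (k <= 0) stop("umbrella stiffness k must be positive")
  structure(list(type = "coordinate", k = k, center = center,
                 coord = as.integer(coord)), class = "taps_bias")
}

#' @rdname biases
#' @export
bias_moving_target <- function(target, k, schedule_steps, d0_start = NULL) {
  if (k <= 0) stop("restraint stiffness k must be positive")
  structure(list(type = "moving_target", target = as_conformation(target),
                 k = k, schedule_steps = as.integer(schedule_steps),
                 d0_start = d0_start), class = "taps_bias")
}

#' Run overdamped Langevin dynamics
#'
#' Integrates the configuration under the potential plus an optional bias
#' and records frames (and the (s, z) projection onto the bias path, when
#' one is involved or `cv_path` is given).
#'
#' @param pot A `"taps_potential"`.
#' @param x0 Starting configuration (conformation or numeric vector).
#' @param settings A [simulation_settings()].
#' @param bias Optional `"taps_bias"`.
#' @param cv_path Optional [taps_path()]; when given, the (s, z) series
#'   with respect to it is recorded even without a path bias.
#' @return A `"taps_trajectory"`: list with `frames` (matrix, one recorded
#'   frame per row), `cv` (data frame `step`, `s`, `z`, or `NULL`),
#'   `settings`, `potential` (name), and `dim`.
#' @export
simulate <- function(pot, x0, settings, bias = NULL, cv_path = NULL) {
  stopifnot(inherits(pot, "taps_potential"),
            inherits(settings, "sim_settings"))
  x0v <- if (inherits(x0, "conformation")) conf_flatten(x0) else as.numeric(x0)
  if (length(x0v) != pot$dim)
    stop("x0 has dimension ", length(x0v), ", potential expects ", pot$dim)

  stiff <- pot$stiffness
  if (!is.null(bias) && bias$type %in% c("s_restraint", "coordinate")) {
    # the restraint adds curvature; |ds/dx| is roughly 1/gap, so the
    # restraint contributes about k / gap^2 to the stiffness
    bias_stiff <- if (bias$type == "coordinate") bias$k else
      bias$k / mean(path_gaps(bias$path))^2 +
        (if (bias$k_z > 0 && is.finite(bias$z_max))
           4 * bias$k_z * bias$z_max else 0)
    stiff <- max(stiff, bias_stiff, na.rm = TRUE)
  }
  if (is.finite(stiff) && settings$dt * settings$diffusion * settings$beta *
      stiff >= 2)
    stop("unstable integration: dt * diffusion * beta * stiffness = ",
         format(settings$dt * settings$diffusion * settings$beta * stiff),
         " >= 2; reduce dt")

  nodes <- matrix(numeric(0), 0, 0)
  lambda <- 0
  bias_id <- 0L; bias_k <- 0; bias_center <- 0; bias_dim <- 0L
  target <- numeric(length(x0v)); d0_start <- 0; schedule_steps <- 0L
  k_z <- 0; z_max <- Inf
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "taps_bias"))
    if (bias$type == "s_restraint") {
      bias_id <- 1L
      nodes <- path_node_matrix(bias$path)
      lambda <- bias$path$lambda
      bias_k <- bias$k; bias_center <- bias$center
      k_z <- bias$k_z
      if (is.finite(bias$z_max)) z_max <- bias$z_max else k_z <- 0
    } else if (bias$type == "moving_target") {
      bias_id <- 2L
      target <- conf_flatten(bias$target)
      if (length(target) != length(x0v))
        stop("target dimension does not match x0")
      d0_start <- bias$d0_start
      if (is.null(d0_start)) d0_start <- sqrt(sum((x0v - target)^2))
      bias_k <- bias$k; schedule_steps <- bias$schedule_steps
    } else if (bias$type == "coordinate") {
      bias_id <- 3L
      bias_k <- bias$k; bias_center <- bias$center
      bias_dim <- bias$coord - 1L
      if (bias$coord > length(x0v)) stop("umbrella coordinate out of range")
    }
  }
  if (!is.null(cv_path) && bias_id != 1L) {
    nodes <- path_node_matrix(cv_path)
    lambda <- cv_path$lambda
  }

  set.seed(settings$seed)
  if (pot$native_id >= 0L) {
    res <- simulate_cpp(pot$native_id, as.numeric(pot$params), x0v,
                        settings$beta, settings$diffusion, settings$dt,
                        settings$n_steps, settings$record_every,
                        bias_id, nodes, lambda, bias_k, bias_center,
                        bias_dim, target, d0_start, schedule_steps,
                        k_z, z_max)
  } else {
    res <- simulate_r(pot, x0v, settings, bias_id, nodes, lambda, bias_k,
                      bias_center, bias_dim, target, d0_start,
                      schedule_steps, k_z, z_max)
  }
  if (res$err_step >= 0)
    stop(structure(class = c("taps_diverged", "error", "condition"),
                   list(message = paste0("simulation diverged (non-finite ",
                                         "state) at step ", res$err_step),
                        call = sys.call(), step = res$err_step)))
  frames <- res$frames
  cv <- NULL
  if (nrow(nodes) > 0) {
    steps <- seq(0L, settings$n_steps, by = settings$record_every)
    cv <- data.frame(step = steps, s = res$cv[, 1], z = res$cv[, 2])
  }
  structure(list(frames = frames, cv = cv, settings = settings,
                 potential = pot$name, dim = length(x0v)),
            class = "taps_trajectory")
}

# Reference pure-R integrator (custom potentials); mirrors simulate_cpp.
simulate_r <- function(pot, x0, settings, bias_id, nodes, lambda, bias_k,
                       bias_center, bias_dim, target, d0_start,
                       schedule_steps, k_z = 0, z_max = Inf) {
  d <- length(x0)
  n_rec <- settings$n_steps %/% settings$record_every + 1L
  frames <- matrix(NA_real_, n_rec, d)
  cv <- matrix(NA_real_, if (nrow(nodes) > 0) n_rec else 0, 2)
  proj <- function(x) {
    e <- lambda * rowSums(sweep(nodes, 2, x)^2)
    emin <- min(e); w <- exp(-(e - emin)); W <- sum(w)
    list(s = sum(seq_along(w) * w) / W, z = (emin - log(W)) / lambda, w = w,
         W = W)
  }
  mob <- settings$diffusion * settings$beta * settings$dt
  noise <- sqrt(2 * settings$diffusion * settings$dt)
  x <- x0
  frames[1, ] <- x
  if (nrow(nodes) > 0) { p <- proj(x); cv[1, ] <- c(p$s, p$z) }
  ri <- 2L
  err_step <- -1L
  for (t in seq_len(settings$n_steps)) {
    g <- pot$gradient(x)
    if (bias_id == 1L) {
      p <- proj(x)
      coef <- (seq_len(nrow(nodes)) - p$s) * p$w
      gs <- as.numeric(2 * lambda / p$W * colSums(coef * sweep(nodes, 2, x)))
      g <- g + bias_k * (p$s - bias_center) * gs
      if (k_z > 0 && p$z > z_max) {
        gz <- as.numeric(2 / p$W * colSums(p$w * sweep(nodes, 2, x, "-")))
        g <- g - k_z * (p$z - z_max) * gz
      }
    } else if (bias_id == 2L) {
      dist <- sqrt(sum((x - target)^2))
      d0 <- d0_start * (1 - min(1, t / schedule_steps))
      if (dist > 1e-12) g <- g + bias_k * (dist - d0) * (x - target) / dist
    } else if (bias_id == 3L) {
      g[bias_dim + 1L] <- g[bias_dim + 1L] + bias_k * (x[bias_dim + 1L] -
                                                         bias_center)
    }
    x <- x - mob * g + noise * stats::rnorm(d)
    if (any(!is.finite(x))) { err_step <- t; break }
    if (t %% settings$record_every == 0L) {
      frames[ri, ] <- x
      if (nrow(nodes) > 0) { p <- proj(x); cv[ri, ] <- c(p$s, p$z) }
      ri <- ri + 1L
    }
  }
  list(frames = frames, cv = cv, n_recorded = ri - 1L, err_step = err_step)
}

#' @export
print.taps_trajectory <- function(x, ...) {
  cat("<taps_trajectory> ", nrow(x$frames), " frames in R^", x$dim,
      if (!is.null(x$cv)) ", with (s, z) series", "\n", sep = "")
  invisible(x)
}

#' Restrained sampling in the hyperplane perpendicular to a path
#'
#' Samples the potential under a harmonic restraint k_s/2 (s(x) - i)^2
#' holding the path collective variable s at node index i, so the walker
#' explores the hyperplane perpendicular to the path through node i.
#' Only s is restrained; motion along z (off-path) is free, which is what
#' lets the path nodes relax toward the minimum free-energy path.
#'
#' @param pot A `"taps_potential"`.
#' @param path A euclidean-metric [taps_path()].
#' @param node_index Node whose hyperplane is sampled (1..N).
#' @param k_s Restraint stiffness in energy per s^2 (s in node-index
#'   units).
#' @param settings A [simulation_settings()].
#' @param k_z,z_max Optional tube wall on z (see [bias_s_restraint()]);
#'   the default leaves z unrestrained.
#' @return A `"taps_trajectory"` with the (s, z) series populated.  A
#'   warning is raised if the mean recorded |s - node_index| exceeds 0.5,
#'   indicating the restraint is too soft for the landscape.
#' @export
restrained_sample_perpendicular <- function(pot, path, node_index, k_s,
                                            settings, k_z = 0,
                                            z_max = Inf) {
  N <- path_length(path)
  if (node_index < 1 || node_index > N)
    stop("node_index must be in 1..", N)
  if (k_s <= 0) stop("restraint stiffness k_s must be positive")
  x0 <- path$nodes[[node_index]]
  traj <- simulate(pot, x0, settings,
                   bias = bias_s_restraint(path, k_s, node_index,
                                           k_z = k_z, z_max = z_max))
  drift <- mean(abs(traj$cv$s - node_index))
  if (drift >= 0.5)
    warning("perpendicular sampling at node ", node_index,
            " drifted in s (mean |s - i| = ", format(drift, digits = 3),
            "); consider a stiffer k_s")
  traj
}

#' Generate an initial path by targeted dynamics
#'
#' Runs biased dynamics with a moving distance-to-target restraint
#' k/2 (d(x, target) - d0(t))^2, with d0 shrinking linearly from the
#' start-target distance to zero over `schedule_steps`, then resamples
#' the recorded frames uniformly in d0 to produce an initial path.  The
#' returned path's endpoints are exactly the given start and target.
#'
#' @param pot A `"taps_potential"`.
#' @param start,target Endpoint configurations (start != target).
#' @param k_tmd Restraint stiffness.
#' @param schedule_steps Steps over which d0 reaches zero (the run
#'   continues for `settings$n_steps` >= `schedule_steps`, letting the
#'   final frames equilibrate at d0 = 0).
#' @param settings A [simulation_settings()].
#' @param n_record Number of path nodes to return (>= 2).
#' @param eps_target Maximum allowed final distance from the target
#'   (default 5% of the initial distance); exceeded => error.
#' @return A [taps_path()] with `n_record` nodes.
#' @export
targeted_path <- function(pot, start, target, k_tmd, schedule_steps,
                          settings, n_record = 20L, eps_target = NULL) {
  sv <- if (inherits(start, "conformation")) conf_flatten(start) else
    as.numeric(start)
  tv <- if (inherits(target, "conformation")) conf_flatten(target) else
    as.numeric(target)
  d0 <- sqrt(sum((sv - tv)^2))
  if (d0 < 1e-12) stop("start and target coincide")
  if (n_record < 2L) stop("n_record must be >= 2")
  if (is.null(eps_target)) eps_target <- 0.05 * d0
  if (settings$n_steps < schedule_steps)
    settings <- settings_with(settings, n_steps = schedule_steps)
  traj <- simulate(pot, sv, settings,
                   bias = bias_moving_target(tv, k_tmd, schedule_steps, d0))
  final_d <- sqrt(sum((traj$frames[nrow(traj$frames), ] - tv)^2))
  if (final_d > eps_target)
    stop("targeted dynamics did not reach the target: final distance ",
         format(final_d, digits = 4), " > eps_target = ",
         format(eps_target, digits = 4))
  steps <- seq(0L, settings$n_steps, by = settings$record_every)
  sched <- d0 * pmax(0, 1 - steps / schedule_steps)
  wanted <- seq(d0, 0, length.out = n_record)
  idx <- vapply(wanted, function(d) which.min(abs(sched - d)), integer(1))
  nodes <- traj$frames[idx, , drop = FALSE]
  nodes[1L, ] <- sv
  nodes[n_record, ] <- tv
  # drop accidental duplicate interior frames (short schedules)
  keep <- c(TRUE, rowSums((nodes[-1L, , drop = FALSE] -
                             nodes[-n_record, , drop = FALSE])^2) > 1e-20)
  taps_path(nodes[keep, , drop = FALSE])
}

#' Umbrella sampling run at one window along PCV-s
#'
#' Samples under a harmonic umbrella k_umb/2 (s(x) - s_center)^2, started
#' from the path node nearest to `s_center`, and records the s series.
#'
#' @param pot A `"taps_potential"`.
#' @param path A euclidean-metric [taps_path()].
#' @param s_center Window center in node-index units (1..N).
#' @param k_umb Umbrella stiffness.
#' @param settings A [simulation_settings()].
#' @return A `"taps_trajectory"` with the (s, z) series populated.
#' @export
umbrella_run <- function(pot, path, s_center, k_umb, settings) {
  N <- path_length(path)
  if (s_center < 1 || s_center > N)
    stop("s_center must be in [1, ", N, "]")
  x0 <- path$nodes[[round(min(max(s_center, 1), N))]]
  simulate(pot, x0, settings,
           bias = bias_s_restraint(path, k_umb, s_center))
}

#' Verify the analytic PCV-s gradient against finite differences
#'
#' Draws random configurations around the path and compares the analytic
#' chain-rule gradient of s with central finite differences.  Returns the
#' maximum relative mismatch (and errors if it exceeds `tol`).
#'
#' @param path A euclidean-metric [taps_path()].
#' @param n Number of random test points.
#' @param h Finite-difference step.
#' @param tol Maximum allowed relative mismatch.
#' @param seed RNG seed.
#' @return Maximum relative error (invisibly raises on failure).
#' @export
verify_s_gradient <- function(path, n = 100L, h = 1e-6, tol = 1e-4,
                              seed = 1L) {
  M <- path_node_matrix(path)
  set.seed(seed)
  spread <- max(apply(M, 2, function(col) diff(range(col))), 1)
  worst <- 0
  for (i in seq_len(n)) {
    x <- M[sample(nrow(M), 1L), ] + stats::rnorm(ncol(M), sd = 0.2 * spread)
    ga <- pcv_s_gradient(x, path)
    gn <- vapply(seq_along(x), function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (pcv_project(xp, path)$s - pcv_project(xm, path)$s) / (2 * h)
    }, numeric(1))
    rel <- sqrt(sum((ga - gn)^2)) / max(sqrt(sum(gn^2)), 1e-10)
    worst <- max(worst, rel)
  }
  if (worst > tol)
    stop("analytic PCV-s gradient mismatches finite differences: ",
         "max relative error ", format(worst, digits = 4), " > ", tol)
  worst
}
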