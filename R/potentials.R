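#' Analytic model potentials
#'
#' Bundled energy surfaces used for desk-scale validation of the path
#' search.  All energies are in units of k_B T at the reference inverse
#' temperature beta = 1; the sampler's `beta` rescales them.  Each
#' potential provides `energy(x)` and `gradient(x)` (accepting a single
#' point or a matrix of points in rows), its dimension, and a stiffness
#' estimate (largest Hessian eigenvalue scale) used to check integrator
#' stability.
#'
#' Bundled surfaces:
#' * `flat_potential(dim)`: U = 0, for null tests of free diffusion.
#' * `harmonic_potential(k, dim)`: U = k/2 |x|^2.
#' * `double_well_1d(height, offset)`: quartic double well
#'   U = height (x^2 - 1)^2 + (offset/2)(1 + tanh(4x)); wells near
#'   x = -1 and x = +1.  The tanh step is flat at both wells, so the
#'   well at +1 is raised by `offset` with curvatures untouched and the
#'   Boltzmann free-energy difference equals the configured offset to
#'   within a fraction of a percent.
#' * `two_basin_potential(dim, height, offset, k_perp)`: the same double
#'   well along the first coordinate plus harmonic confinement (k_perp)
#'   of the remaining coordinates — a minimal n-dimensional two-state
#'   landscape with an interposed barrier.
#' * `mueller_brown(scale)`: the standard four-Gaussian Mueller-Brown
#'   surface (coefficients A = (-200,-100,-170,15), a = (-1,-1,-6.5,0.7),
#'   b = (0,0,11,0.6), c = (-10,-10,-6.5,0.7), centers (1,0), (0,0.5),
#'   (-0.5,1.5), (-1,1)), multiplied by `scale`.
#' * `three_hole_potential(scale)`: two deep holes at (+-1, 0) connected
#'   by an upper channel through a shallow intermediate.
#'
#' @param dim Spatial dimension.
#' @param k,height,offset,k_perp,scale Shape parameters, see above.
#' @return An object of class `"taps_potential"`.
#' @name potentials
NULL

new_native_potential <- function(name, id, params, dim, stiffness) {
  force(id); force(params); force(dim)
  pot <- list(
    name = name, dim = dim, params = params, native_id = id,
    stiffness = stiffness,
    energy = function(x) {
      X <- as_points_matrix(x, dim)
      e <- potential_eval_cpp(id, params, X)$energy
      if (nrow(X) == 1L) e[[1L]] else e
    },
    gradient = function(x) {
      X <- as_points_matrix(x, dim)
      g <- potential_eval_cpp(id, params, X)$gradient
      if (nrow(X) == 1L) as.numeric(g) else g
    })
  structure(pot, class = "taps_potential")
}

as_points_matrix <- function(x, dim) {
  if (inherits(x, "conformation")) x <- conf_flatten(x)
  if (is.null(dim(x))) {
    if (length(x) != dim)
      stop("point has dimension ", length(x), ", potential expects ", dim)
    return(matrix(as.numeric(x), 1L))
  }
  x <- as.matrix(x)
  if (ncol(x) != dim)
    stop("points have dimension ", ncol(x), ", potential expects ", dim)
  storage.mode(x) <- "double"
  x
}

#' @rdname potentials
#' @export
flat_potential <- function(dim = 2L) {
  new_native_potential("flat", 0L, numeric(0), as.integer(dim), 0)
}

#' @rdname potentials
#' @export
harmonic_potential <- function(k = 1, dim = 1L) {
  stopifnot(k > 0)
  new_native_potential("harmonic", 1L, c(k = k), as.integer(dim), k)
}

#' @rdname potentials
#' @export
double_well_1d <- function(height = 3, offset = 0) {
  two_basin_potential(dim = 1L, height = height, offset = offset)
}

#' @rdname potentials
#' @export
two_basin_potential <- function(dim = 2L, height = 3, offset = 0,
                                k_perp = 2) {
  stopifnot(height > 0, dim >= 1L)
  new_native_potential(
    "two_basin", 2L, c(height = height, offset = offset, k_perp = k_perp),
    as.integer(dim), max(8 * height, k_perp))
}

#' @rdname potentials
#' @export
mueller_brown <- function(scale = 1) {
  stopifnot(scale > 0)
  # largest Hessian eigenvalue near the deep minima is ~2.4e3 * scale
  new_native_potential("mueller_brown", 3L, c(scale = scale), 2L,
                       3000 * scale)
}

#' @rdname potentials
#' @export
three_hole_potential <- function(scale = 1) {
  stopifnot(scale > 0)
  new_native_potential("three_hole", 4L, c(scale = scale), 2L, 40 * scale)
}

#' Define a custom potential
#'
#' Wraps user-supplied energy and gradient functions into the potential
#' interface.  Custom potentials run through the pure-R integrator, which
#' is considerably slower than the compiled path used by the bundled
#' surfaces; they are intended for small exploratory landscapes.
#'
#' @param energy Function of a length-`dim` numeric vector returning a
#'   scalar energy (k_B T units at beta = 1).
#' @param gradient Function returning the length-`dim` gradient.
#' @param dim Spatial dimension.
#' @param stiffness Optional largest-curvature estimate for the
#'   integrator stability check (`NA` disables the check).
#' @param name Display name.
#' @return A `"taps_potential"`.
#' @export
make_potential <- function(energy, gradient, dim, stiffness = NA_real_,
                           name = "custom") {
  stopifnot(is.function(energy), is.function(gradient), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), params = NULL,
                 native_id = -1L, stiffness = stiffness,
                 energy = energy, gradient = gradient),
            class = "taps_potential")
}

#' @export
print.taps_potential <- function(x, ...) {
  cat("<taps_potential> ", x$name, " (dim ", x$dim, ")\n", sep = "")
  invisible(x)
}

#' Locate local minima of a 2D potential on a dense grid
#'
#' Evaluates the potential on a regular grid, flags grid points lower
#' than their 8 neighbours, and polishes each hit with BFGS.  Serves as
#' the independent locator of basins used to seed and verify path
#' searches.
#'
#' @param pot A 2D `"taps_potential"`.
#' @param xlim,ylim Ranges of the grid.
#' @param n Grid points per axis.
#' @param e_max Discard grid minima above this energy (default keeps all).
#' @return Data frame with columns `x`, `y`, `energy`, sorted by energy.
#' @export
locate_minima_grid <- function(pot, xlim, ylim, n = 401L, e_max = Inf) {
  stopifnot(pot$dim == 2L)
  gx <- seq(xlim[1], xlim[2], length.out = n)
  gy <- seq(ylim[1], ylim[2], length.out = n)
  G <- as.matrix(expand.grid(x = gx, y = gy))
  E <- matrix(pot$energy(G), n, n)
  hits <- list()
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      e <- E[i, j]
      if (e < e_max &&
          e < min(E[(i - 1L):(i + 1L), (j - 1L):(j + 1L)][-5L])) {
        hits[[length(hits) + 1L]] <- c(gx[i], gy[j])
      }
    }
  }
  if (!length(hits)) return(data.frame(x = numeric(0), y = numeric(0),
                                       energy = numeric(0)))
  refined <- lapply(hits, function(p) {
    fit <- stats::optim(p, fn = function(q) pot$energy(q),
                        gr = function(q) pot$gradient(q), method = "BFGS",
                        control = list(reltol = 1e-14))
    c(fit$par, fit$value)
  })
  out <- do.call(rbind, refined)
  out <- data.frame(x = out[, 1], y = out[, 2], energy = out[, 3])
  # merge duplicates that refined into the same basin
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j > i && keep[j] &&
          sqrt(sum((out[i, 1:2] - out[j, 1:2])^2)) < 1e-4) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$energy), , drop = FALSE]
}
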