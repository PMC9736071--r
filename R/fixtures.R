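#' Zero-temperature string method (reference MFEP oracle)
#'
#' Relaxes a densely discretized path by steepest descent under the
#' analytic gradient, redistributing the nodes to equal arclength after
#' every step (the standard simplified string method).  At zero
#' temperature the converged string is the minimum-energy path, which on
#' the toy surfaces coincides with the minimum free-energy path the
#' sampled search should find; it therefore serves as the independent
#' reference that path-search results are compared against.
#'
#' @param pot A `"taps_potential"`.
#' @param a,b Endpoint configurations (numeric vectors); they are relaxed
#'   too, so starting them at (or near) minima keeps them there.
#' @param n_nodes String discretization (default 101).
#' @param step Steepest-descent step size (must satisfy
#'   `step * stiffness < 2`).
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the largest perpendicular gradient
#'   component over interior nodes.
#' @return List with `nodes` (n_nodes x d matrix), `energy` (per node),
#'   `converged`, `iterations`, `max_perp_grad`.
#' @export
string_mfep <- function(pot, a, b, n_nodes = 101L, step = NULL,
                        max_iter = 200000L, tol = 1e-3) {
  a <- as.numeric(a); b <- as.numeric(b)
  d <- pot$dim
  stopifnot(length(a) == d, length(b) == d)
  if (is.null(step))
    step <- if (is.finite(pot$stiffness) && pot$stiffness > 0)
      0.5 / pot$stiffness else 1e-3
  alpha <- seq(0, 1, length.out = n_nodes)
  X <- outer(1 - alpha, a) + outer(alpha, b)
  perp_residual <- function(X, G) {
    # unit tangents by central differences
    T_ <- rbind(X[2L, ] - X[1L, ],
                X[3:n_nodes, , drop = FALSE] -
                  X[1:(n_nodes - 2L), , drop = FALSE],
                X[n_nodes, ] - X[n_nodes - 1L, ])
    T_ <- T_ / pmax(sqrt(rowSums(T_^2)), 1e-300)
    Gp <- G - T_ * rowSums(G * T_)
    max(abs(Gp[2:(n_nodes - 1L), , drop = FALSE]))
  }
  res <- Inf
  it <- 0L
  check_every <- 200L
  while (it < max_iter) {
    it <- it + 1L
    G <- pot$gradient(X)
    X <- X - step * G
    # equal-arclength redistribution (linear interpolation)
    seg <- sqrt(rowSums((X[-1L, , drop = FALSE] -
                           X[-n_nodes, , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    want <- seq(0, cum[n_nodes], length.out = n_nodes)
    for (j in seq_len(d))
      X[, j] <- stats::approx(cum, X[, j], xout = want, ties = "ordered")$y
    if (it %% check_every == 0L) {
      res <- perp_residual(X, pot$gradient(X))
      if (res < tol) break
    }
  }
  if (!is.finite(res) || res >= tol)
    res <- perp_residual(X, pot$gradient(X))
  list(nodes = X, energy = pot$energy(X), converged = res < tol,
       iterations = it, max_perp_grad = res)
}

#' Exact minimum-energy path by flowline integration (2D oracle)
#'
#' Builds the reference minimum-energy path to high accuracy: from each
#' saddle, the two steepest-descent flowlines x' = -grad U / |grad U|
#' are integrated (RK4, fixed arclength step) down to the minima they
#' connect; every point of such a flowline lies exactly on the
#' minimum-energy path by construction.  The segments are chained from
#' `from` to `to` through any intermediate minima and resampled to
#' `n_nodes` equal-arclength nodes.  A coarse [string_mfep()] run
#' followed by [refine_saddle()] provides the saddle list.
#'
#' @param pot A native 2D `"taps_potential"`.
#' @param minima Matrix of minima (one per row, e.g. from
#'   [locate_minima_grid()]).
#' @param saddles List of refined saddles (each with an `x` field).
#' @param from,to Row indices in `minima` of the two end states.
#' @param n_nodes Nodes of the returned resampled path.
#' @param ds Arclength integration step of the dense flowlines.
#' @return List with `nodes` (n_nodes x 2), `energy`, `max_perp_grad`
#'   (largest perpendicular gradient over interior nodes, the
#'   convergence measure), `saddle_order` (row indices of `saddles`
#'   in path order), and `dense` (the concatenated flowline polyline).
#' @export
mep_flowline_oracle <- function(pot, minima, saddles, from = 1L, to = 2L,
                                n_nodes = 12001L, ds = 5e-5) {
  stopifnot(pot$dim == 2L, pot$native_id >= 0L)
  M <- as.matrix(minima[, 1:2])
  hess <- function(x, h = 1e-5) {
    H <- vapply(1:2, function(j) {
      e <- c(0, 0); e[j] <- h
      (pot$gradient(x + e) - pot$gradient(x - e)) / (2 * h)
    }, numeric(2))
    (H + t(H)) / 2
  }
  descend <- function(x0) {
    fl <- flowline_descent_cpp(pot$native_id, as.numeric(pot$params),
                               x0, ds, 200000L, M, 10 * ds)
    if (fl$reached == 0L)
      stop("flowline failed to reach a minimum from (",
           paste(format(x0, digits = 4), collapse = ", "), ")")
    list(points = fl$points[seq_len(fl$n), , drop = FALSE],
         min = fl$reached)
  }
  # both downhill branches of each saddle
  edges <- lapply(saddles, function(sd) {
    H <- hess(sd$x)
    ev <- eigen(H, symmetric = TRUE)
    if (ev$values[2] >= 0)
      stop("stationary point at (",
           paste(format(sd$x, digits = 4), collapse = ", "),
           ") is not a saddle (no negative curvature)")
    v <- ev$vectors[, 2L]
    bra <- descend(sd$x + 5 * ds * v)
    brb <- descend(sd$x - 5 * ds * v)
    list(saddle = sd$x, a = bra, b = brb, mins = c(bra$min, brb$min))
  })
  # chain the saddle segments from `from` to `to`
  chain <- list()
  cur <- from
  used <- rep(FALSE, length(edges))
  saddle_order <- integer(0)
  while (cur != to) {
    nxt <- NULL
    for (k in seq_along(edges)) {
      if (used[k] || !(cur %in% edges[[k]]$mins)) next
      e <- edges[[k]]
      other <- if (e$mins[1] == cur) e$mins[2] else e$mins[1]
      first <- if (e$mins[1] == cur) e$a else e$b
      second <- if (e$mins[1] == cur) e$b else e$a
      seg <- rbind(M[cur, ],
                   first$points[rev(seq_len(nrow(first$points))), ],
                   e$saddle, second$points, M[other, ])
      chain[[length(chain) + 1L]] <- seg
      saddle_order <- c(saddle_order, k)
      used[k] <- TRUE
      nxt <- other
      break
    }
    if (is.null(nxt))
      stop("saddle segments do not connect minimum ", cur, " to ", to)
    cur <- nxt
  }
  dense <- do.call(rbind, chain)
  gap <- sqrt(rowSums(diff(dense)^2))
  dense <- dense[c(TRUE, gap > 1e-10), , drop = FALSE]
  cum <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  want <- seq(0, max(cum), length.out = n_nodes)
  X <- cbind(stats::approx(cum, dense[, 1], xout = want)$y,
             stats::approx(cum, dense[, 2], xout = want)$y)
  G <- pot$gradient(X)
  T_ <- rbind(X[2L, ] - X[1L, ],
              X[3:n_nodes, , drop = FALSE] -
                X[1:(n_nodes - 2L), , drop = FALSE],
              X[n_nodes, ] - X[n_nodes - 1L, ])
  T_ <- T_ / pmax(sqrt(rowSums(T_^2)), 1e-300)
  Gp <- G - T_ * rowSums(G * T_)
  list(nodes = X, energy = pot$energy(X),
       max_perp_grad = max(abs(Gp[2:(n_nodes - 1L), , drop = FALSE])),
       saddle_order = saddle_order, dense = dense)
}

#' Refine a saddle point from a nearby guess
#'
#' Minimizes |grad U|^2 with BFGS; started close to a saddle (e.g. from
#' the maximum-energy node of a converged string) this converges to the
#' stationary point itself.
#'
#' @param pot A `"taps_potential"`.
#' @param guess Starting point.
#' @return List with `x` (the stationary point), `energy`, `grad_norm`.
#' @export
refine_saddle <- function(pot, guess) {
  obj <- function(q) sum(pot$gradient(q)^2)
  fit <- stats::optim(as.numeric(guess), obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 1000L))
  list(x = fit$par, energy = pot$energy(fit$par),
       grad_norm = sqrt(fit$value))
}

#' Free-energy difference between two basins by direct Boltzmann
#' integration (1D oracle)
#'
#' For a 1D potential, integrates exp(-beta U) over each basin (split at
#' `divider`) and returns -1/beta log(Z_b / Z_a): the exact free-energy
#' difference the umbrella/WHAM machinery should recover.
#'
#' @param pot A 1D `"taps_potential"`.
#' @param beta Inverse temperature.
#' @param divider Basin boundary (default 0).
#' @param lim Integration half-width (default 5).
#' @return Scalar free-energy difference (basin above `divider` minus
#'   basin below).
#' @export
boltzmann_delta_g_1d <- function(pot, beta = 1, divider = 0, lim = 5) {
  stopifnot(pot$dim == 1L)
  dens <- function(x) exp(-beta * vapply(x, function(v) pot$energy(v),
                                         numeric(1)))
  za <- stats::integrate(dens, -lim, divider, rel.tol = 1e-10)$value
  zb <- stats::integrate(dens, divider, lim, rel.tol = 1e-10)$value
  -log(zb / za) / beta
}

#' Generate a validation fixture bundle
#'
#' Produces, entirely in code, a small self-contained study system with
#' its independent oracle:
#'
#' * `"mueller_brown_mfep"`: the Mueller-Brown surface, its two deep
#'   minima (dense-grid search + BFGS refinement), the string-method
#'   reference MFEP between them, the energy profile along it, and the
#'   refined highest saddle.
#' * `"double_well"`: the 1D quartic double well with a configured well
#'   offset, its two minima, and the exact Boltzmann-integration
#'   free-energy difference.
#' * `"two_basin_nd"`: the n-dimensional two-basin landscape (double
#'   well along the first axis, harmonic confinement elsewhere); the
#'   perpendicular modes are identical in both basins, so the oracle
#'   free-energy difference reduces to the 1D Boltzmann value.
#' * `"pdb_toy"`: a synthetic 5-residue mini-protein PDB file (written
#'   to `dir`) with known atom ordering, for exercising the PDB reader
#'   and selection logic without any external structure.
#'
#' Bundles are bit-reproducible for a given seed.
#'
#' @param kind One of `"mueller_brown_mfep"`, `"double_well"`,
#'   `"two_basin_nd"`, `"pdb_toy"`.
#' @param seed Integer seed.
#' @param dir Output directory for file-based fixtures (default
#'   `tempdir()`).
#' @param offset Well offset in k_B T for the two-basin kinds (default 2).
#' @param dim Dimension for `"two_basin_nd"` (default 2).
#' @return A list bundle; contents depend on `kind` (always includes
#'   `kind`, `seed`, and for potential-based kinds `potential`,
#'   `endpoints`, and oracle fields).
#' @export
make_fixture <- function(kind, seed = 1L, dir = tempdir(), offset = 2,
                         dim = 2L) {
  set.seed(seed)
  switch(
    kind,
    mueller_brown_mfep = {
      pot <- mueller_brown()
      minima <- locate_minima_grid(pot, c(-1.7, 1.3), c(-0.5, 2.3),
                                   n = 401L)
      lo <- as.numeric(minima[1L, 1:2])       # deepest
      hi <- as.numeric(minima[2L, 1:2])       # second deepest
      # a coarse relaxed string fixes the path topology and supplies
      # saddle guesses (its energy maxima); the final oracle comes from
      # exact flowline integration through the refined saddles
      coarse <- string_mfep(pot, lo, hi, n_nodes = 101L,
                            max_iter = 30000L, tol = 1)
      e <- coarse$energy
      n <- length(e)
      guess_idx <- which(vapply(2:(n - 1L), function(i)
        e[i] > e[i - 1L] && e[i] >= e[i + 1L], logical(1))) + 1L
      saddles <- lapply(guess_idx, function(i)
        refine_saddle(pot, coarse$nodes[i, ]))
      keep <- !duplicated(round(t(vapply(saddles, `[[`, numeric(2), "x")),
                                 4))
      saddles <- saddles[keep]
      oracle <- mep_flowline_oracle(pot, minima, saddles, from = 1L,
                                    to = 2L)
      imax <- which.max(oracle$energy)
      saddle <- refine_saddle(pot, oracle$nodes[imax, ])
      list(kind = kind, seed = seed, potential = pot, minima = minima,
           endpoints = list(a = lo, b = hi), oracle_path = oracle$nodes,
           oracle_energy = oracle$energy,
           oracle_converged = oracle$max_perp_grad < 1e-3,
           oracle_max_perp_grad = oracle$max_perp_grad,
           saddle = saddle, all_saddles = saddles)
    },
    double_well = {
      pot <- double_well_1d(height = 3, offset = offset)
      xa <- stats::optimize(function(x) pot$energy(x), c(-2, 0))$minimum
      xb <- stats::optimize(function(x) pot$energy(x), c(0, 2))$minimum
      list(kind = kind, seed = seed, potential = pot,
           endpoints = list(a = xa, b = xb),
           oracle_delta_g = boltzmann_delta_g_1d(pot),
           oracle_barrier = pot$energy(0) -
             min(pot$energy(xa), pot$energy(xb)))
    },
    two_basin_nd = {
      pot <- two_basin_potential(dim = dim, height = 3, offset = offset,
                                 k_perp = 2)
      pot1d <- double_well_1d(height = 3, offset = offset)
      xa <- stats::optimize(function(x) pot1d$energy(x), c(-2, 0))$minimum
      xb <- stats::optimize(function(x) pot1d$energy(x), c(0, 2))$minimum
      list(kind = kind, seed = seed, potential = pot,
           endpoints = list(a = c(xa, rep(0, dim - 1L)),
                            b = c(xb, rep(0, dim - 1L))),
           oracle_delta_g = boltzmann_delta_g_1d(pot1d))
    },
    pdb_toy = {
      file <- file.path(dir, sprintf("toy_synthetic_%d.pdb", seed))
      write_toy_pdb(file, seed)
      list(kind = kind, seed = seed, file = file)
    },
    stop("unknown fixture kind ", sQuote(kind), "; expected one of ",
         "mueller_brown_mfep, double_well, two_basin_nd, pdb_toy"))
}

# Synthetic 5-residue glycine-like chain with N/CA/C/O plus one CB and a
# hydrogen, including an altLoc pair on residue 3's CA.  Purely artificial
# coordinates (helix-ish spiral) -- a stand-in structure for reader tests.
write_toy_pdb <- function(file, seed = 1L) {
  set.seed(seed)
  lines <- c("HEADER    SYNTHETIC TOY STRUCTURE")
  serial <- 0L
  resnames <- c("ALA", "GLY", "SER", "ALA", "GLY")
  fmt <- function(serial, name, alt, res, resno, x, y, z, occ, elem) {
    sprintf("ATOM  %5d %-4s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, res, resno, x, y, z, occ, 0, elem)
  }
  for (r in 1:5) {
    base <- c(cos(r * 1.7), sin(r * 1.7), 1.5 * r) + stats::rnorm(3, 0, 0.05)
    atoms <- list(c(" N", "N"), c(" CA", "C"), c(" C", "C"), c(" O", "O"),
                  c(" CB", "C"), c(" HA", "H"))
    offs <- rbind(c(-0.5, 0, 0), c(0, 0, 0), c(0.5, 0.3, 0.2),
                  c(0.8, 0.9, 0.1), c(-0.2, 1.0, 0.4), c(0.1, -0.8, 0.3))
    for (ai in seq_along(atoms)) {
      if (atoms[[ai]][1] == " CB" && resnames[r] == "GLY") next
      p <- base + offs[ai, ]
      if (r == 3L && atoms[[ai]][1] == " CA") {
        serial <- serial + 1L
        lines <- c(lines, fmt(serial, "CA", "A", resnames[r], r,
                              p[1], p[2], p[3], 0.7, "C"))
        serial <- serial + 1L
        lines <- c(lines, fmt(serial, "CA", "B", resnames[r], r,
                              p[1] + 0.3, p[2], p[3], 0.3, "C"))
      } else {
        serial <- serial + 1L
        lines <- c(lines, fmt(serial, trimws(atoms[[ai]][1]), " ",
                              resnames[r], r, p[1], p[2], p[3], 1,
                              atoms[[ai]][2]))
      }
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}
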