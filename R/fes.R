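#' Umbrella window
#'
#' One harmonic-restraint window along the reaction coordinate: center,
#' stiffness, and the sampled s series (with an optional equilibration
#' discard applied to the head of the series).
#'
#' @param s_center Window center.
#' @param k_umb Umbrella stiffness (energy per s^2).
#' @param s_series Numeric vector of sampled s values.
#' @param n_equil_discard Samples dropped from the start of the series.
#' @return An object of class `"umbrella_window"`.
#' @export
umbrella_window <- function(s_center, k_umb, s_series,
                            n_equil_discard = 0L) {
  s_series <- as.numeric(s_series)
  n_equil_discard <- as.integer(n_equil_discard)
  if (n_equil_discard >= length(s_series))
    stop("equilibration discard removes the whole series")
  kept <- if (n_equil_discard > 0L) s_series[-seq_len(n_equil_discard)]
  else s_series
  if (!all(is.finite(kept))) stop("s series contains non-finite values")
  structure(list(s_center = s_center, k_umb = k_umb, s_series = kept,
                 n_equil_discard = n_equil_discard),
            class = "umbrella_window")
}

#' Build an umbrella schedule along a path
#'
#' Window centers from 1 to N in steps of `gap` on PCV-s, with the last
#' center at exactly N (so the final spacing may be shorter than `gap`).
#'
#' @param path A [taps_path()] (or an integer N).
#' @param gap Center spacing in node-index units (default 0.5).
#' @return Numeric vector of window centers.
#' @export
build_schedule <- function(path, gap = 0.5) {
  N <- if (inherits(path, "taps_path")) path_length(path) else
    as.integer(path)
  if (gap <= 0) stop("gap must be positive")
  if (N < 2L) stop("path must have at least 2 nodes")
  if (gap >= N - 1) stop("gap = ", gap, " is too coarse for a path with ",
                         N, " nodes (need gap < N - 1)")
  centers <- seq(1, N, by = gap)
  if (centers[length(centers)] < N) centers <- c(centers, N)
  centers
}

#' Check histogram overlap between adjacent umbrella windows
#'
#' Sufficient overlap between neighbouring windows is required for WHAM
#' to stitch the biased histograms into one profile.  The overlap of an
#' adjacent pair is the shared mass of their normalized histograms on a
#' common bin grid (sum over bins of the smaller of the two
#' frequencies).  Pairs below `threshold` fail, and a midpoint center is
#' proposed as an extra window.
#'
#' @param windows List of [umbrella_window()]s, sorted by center.
#' @param threshold Minimum acceptable overlap fraction (default 0.05).
#' @param n_bins Bins of the common grid per pair (default 50).
#' @return List with `pairs` (data frame: `center_lo`, `center_hi`,
#'   `overlap`, `pass`), `pass` (all pairs ok), and `proposed_centers`
#'   (midpoints of failing pairs).
#' @export
check_overlap <- function(windows, threshold = 0.05, n_bins = 50L) {
  if (length(windows) < 2L) stop("need at least 2 windows")
  centers <- vapply(windows, `[[`, numeric(1), "s_center")
  if (is.unsorted(centers)) stop("windows must be sorted by s_center")
  m <- length(windows) - 1L
  overlap <- numeric(m)
  for (i in seq_len(m)) {
    a <- windows[[i]]$s_series
    b <- windows[[i + 1L]]$s_series
    rng <- range(a, b)
    if (diff(rng) == 0) {
      overlap[i] <- 1
      next
    }
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    ha <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                                all.inside = TRUE), n_bins) / length(a)
    hb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                                all.inside = TRUE), n_bins) / length(b)
    overlap[i] <- sum(pmin(ha, hb))
  }
  pass <- overlap >= threshold
  list(pairs = data.frame(center_lo = centers[-length(centers)],
                          center_hi = centers[-1L], overlap = overlap,
                          pass = pass),
       pass = all(pass),
       proposed_centers = (centers[-length(centers)] + centers[-1L])[!pass] / 2)
}

#' Weighted histogram analysis (WHAM)
#'
#' Combines the biased histograms of harmonic umbrella windows into the
#' unbiased free-energy profile along s by self-consistent iteration of
#' the standard WHAM equations over the bin probabilities p_b and the
#' per-window free-energy constants f_k, until the largest change in any
#' f_k falls below `tol`.  Bins with no counts in any window are masked
#' (dropped), never imputed; a run of three or more empty interior bins
#' separating populated regions aborts with a disconnected-histogram
#' error.
#'
#' @param windows List of [umbrella_window()]s.
#' @param beta Inverse temperature (profiles are in k_B T when beta = 1).
#' @param n_bins Number of histogram bins (`NULL`: 10 bins per unit of s,
#'   at least 10).
#' @param tol Convergence tolerance on the window constants.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   last residual.
#' @return A `"fes_profile"`: `s_grid` (kept bin centers), `f` (free
#'   energy, min shifted to 0), `p` (normalized probability), `counts`,
#'   `bin_width`, `beta`, `f_windows`, `wham_iterations`,
#'   `wham_residual`; `minima`/`maxima` are filled by [find_states()].
#' @export
wham <- function(windows, beta = 1, n_bins = NULL, tol = 1e-7,
                 max_iter = 1e5) {
  stopifnot(length(windows) >= 1L)
  s_all <- unlist(lapply(windows, `[[`, "s_series"))
  rng <- range(s_all)
  if (is.null(n_bins))
    n_bins <- max(10L, ceiling(diff(rng) * 10))
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1L)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  dw <- diff(breaks[1:2])
  K <- length(windows)
  H <- t(vapply(windows, function(w)
    tabulate(findInterval(w$s_series, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), n_bins), numeric(n_bins)))
  total <- colSums(H)
  populated <- total > 0

  # empty-bin bookkeeping: trim the flanks, reject interior gaps
  first <- which(populated)[1L]
  last <- rev(which(populated))[1L]
  inner <- populated[first:last]
  if (any(!inner)) {
    r <- rle(inner)
    runs <- which(!r$values & r$lengths >= 3L)
    if (length(runs)) {
      ends <- cumsum(r$lengths)
      i0 <- first + ends[runs[1L]] - r$lengths[runs[1L]]
      i1 <- first + ends[runs[1L]] - 1L
      stop("disconnected histograms: no samples in s = [",
           format(centers[i0], digits = 4), ", ",
           format(centers[i1], digits = 4),
           "]; add umbrella windows covering this gap")
    }
  }
  keep <- which(populated)
  Hk <- H[, keep, drop = FALSE]
  ctk <- centers[keep]
  Nk <- rowSums(Hk)
  kvec <- vapply(windows, `[[`, numeric(1), "k_umb")
  cvec <- vapply(windows, `[[`, numeric(1), "s_center")
  U <- 0.5 * outer(kvec, ctk, function(k, s) k) *
    outer(cvec, ctk, function(c, s) (s - c)^2)
  bU <- beta * U                      # K x B
  lognk <- log(Nk)

  f <- numeric(K)
  resid <- Inf
  iters <- 0L
  logcounts <- log(colSums(Hk))
  for (it in seq_len(max_iter)) {
    iters <- it
    A <- (lognk + beta * f) - bU      # K x B, log of denominator terms
    amax <- apply(A, 2, max)
    logdenom <- amax + log(colSums(exp(sweep(A, 2, amax))))
    logp <- logcounts - logdenom
    B2 <- sweep(-bU, 2, logp, "+")    # K x B, log integrand for f update
    bmax <- apply(B2, 1, max)
    fnew <- -(bmax + log(rowSums(exp(B2 - bmax)))) / beta
    fnew <- fnew - fnew[1L]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol) break
  }
  if (resid >= tol)
    stop("WHAM failed to converge within ", max_iter,
         " iterations (last residual ", format(resid, digits = 4), ")")
  p <- exp(logp)
  p <- p / sum(p * dw)
  fe <- -log(p) / beta
  fe <- fe - min(fe)
  structure(list(s_grid = ctk, f = fe, p = p, counts = total[keep],
                 bin_width = dw, beta = beta, f_windows = f,
                 wham_iterations = iters, wham_residual = resid,
                 minima = NULL, maxima = NULL),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat("<fes_profile> ", length(x$s_grid), " bins over s = [",
      format(min(x$s_grid), digits = 4), ", ",
      format(max(x$s_grid), digits = 4), "], max f = ",
      format(max(x$f), digits = 4), " kT\n", sep = "")
  if (!is.null(x$minima)) {
    cat("  minima (IS):", paste(sprintf("s=%.2f f=%.2f", x$minima$s,
                                        x$minima$f), collapse = "; "), "\n")
    if (nrow(x$maxima))
      cat("  maxima (TS):", paste(sprintf("s=%.2f f=%.2f", x$maxima$s,
                                          x$maxima$f), collapse = "; "),
          "\n")
  }
  invisible(x)
}

# Topographic prominence of interior extremum i of profile y (maxima:
# height above the highest of the two key saddles toward higher peaks).
prominence_1d <- function(y, i) {
  n <- length(y)
  left <- if (i > 1L) {
    higher <- which(y[seq_len(i - 1L)] > y[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(y[lo:(i - 1L)])
  } else -Inf
  right <- if (i < n) {
    ahead <- seq.int(i + 1L, n)
    higher <- ahead[y[ahead] > y[i]]
    hi <- if (length(higher)) min(higher) - 1L else n
    min(y[(i + 1L):hi])
  } else -Inf
  y[i] - max(left, right)
}

#' Identify transition and intermediate states on a free-energy profile
#'
#' Finds interior local maxima (transition states, TS) and minima
#' (intermediate states, IS) of the profile whose topographic prominence
#' reaches `prominence`.  The two profile endpoints are always included
#' as states (they are the designated end states of the transition).
#' Alternation of minima and maxima along s is enforced by discarding the
#' lower-prominence violator of any same-kind adjacent pair.
#'
#' @param profile A `"fes_profile"` from [wham()].
#' @param prominence Minimum prominence in energy units (default 0.5,
#'   i.e. half a k_B T at beta = 1).
#' @return The profile with `minima` and `maxima` data frames (`s`, `f`)
#'   filled in.
#' @export
find_states <- function(profile, prominence = 0.5) {
  y <- profile$f
  s <- profile$s_grid
  n <- length(y)
  stopifnot(n >= 2L, all(is.finite(y)))
  interior <- if (n >= 3L) 2:(n - 1L) else integer(0)
  is_max <- vapply(interior, function(i) y[i] > y[i - 1L] && y[i] >= y[i + 1L],
                   logical(1))
  is_min <- vapply(interior, function(i) y[i] < y[i - 1L] && y[i] <= y[i + 1L],
                   logical(1))
  maxima <- interior[is_max]
  minima <- interior[is_min]
  prom_max <- vapply(maxima, function(i) prominence_1d(y, i), numeric(1))
  prom_min <- vapply(minima, function(i) prominence_1d(-y, i), numeric(1))
  maxima <- maxima[prom_max >= prominence]
  prom_max <- prom_max[prom_max >= prominence]
  minima <- minima[prom_min >= prominence]
  prom_min <- prom_min[prom_min >= prominence]

  # enforce alternation among the interior extrema: drop the
  # lower-prominence member of any same-kind adjacent pair
  ext <- data.frame(idx = c(minima, maxima),
                    kind = c(rep("min", length(minima)),
                             rep("max", length(maxima))),
                    prom = c(prom_min, prom_max))
  ext <- ext[order(ext$idx), , drop = FALSE]
  if (nrow(ext) > 1L) repeat {
    same <- which(ext$kind[-1L] == ext$kind[-nrow(ext)])
    if (!length(same)) break
    i <- same[1L]
    drop <- if (ext$prom[i] < ext$prom[i + 1L]) i else i + 1L
    ext <- ext[-drop, , drop = FALSE]
  }
  # the profile endpoints are the designated end states of the
  # transition and always enter the state list (as minima)
  min_idx <- sort(unique(c(1L, ext$idx[ext$kind == "min"], n)))
  max_idx <- ext$idx[ext$kind == "max"]
  profile$minima <- data.frame(s = s[min_idx], f = y[min_idx])
  profile$maxima <- data.frame(s = s[max_idx], f = y[max_idx])
  profile
}

#' Free-energy difference between two states on a profile
#'
#' Returns f(state_b) - f(state_a) in the profile's energy units; with
#' state_a the starting basin, a negative value means state_b is the more
#' stable state.  Both s values must match identified minima (within one
#' bin width); run [find_states()] first.
#'
#' @param profile A `"fes_profile"` with minima identified.
#' @param state_a,state_b s values of the two states.
#' @return Scalar free-energy difference.
#' @export
delta_g <- function(profile, state_a, state_b) {
  if (is.null(profile$minima))
    stop("profile has no identified states; run find_states() first")
  match_min <- function(sv) {
    d <- abs(profile$minima$s - sv)
    i <- which.min(d)
    if (d[i] > max(profile$bin_width, 1e-9) * 1.5)
      stop("s = ", sv, " does not correspond to an identified minimum ",
           "(nearest at s = ", format(profile$minima$s[i], digits = 4), ")")
    i
  }
  ia <- match_min(state_a)
  ib <- match_min(state_b)
  profile$minima$f[ib] - profile$minima$f[ia]
}

#' Run a series of umbrella windows along a path
#'
#' Convenience driver: one [umbrella_run()] per center (seeded
#' deterministically from `settings$seed` and the window index), each
#' converted to an [umbrella_window()] with the first
#' `discard_fraction` of samples dropped as equilibration.
#'
#' @param pot A `"taps_potential"`.
#' @param path A euclidean-metric [taps_path()].
#' @param centers Window centers (e.g. from [build_schedule()]).
#' @param k_umb Umbrella stiffness.
#' @param settings Per-window [simulation_settings()].
#' @param discard_fraction Fraction of each series discarded from the
#'   head (default 0.1).
#' @return List of [umbrella_window()]s.
#' @export
run_umbrella_series <- function(pot, path, centers, k_umb, settings,
                                discard_fraction = 0.1) {
  lapply(seq_along(centers), function(i) {
    st <- settings_with(settings,
                        seed = derive_seed(settings$seed, 0L, i))
    traj <- umbrella_run(pot, path, centers[i], k_umb, st)
    umbrella_window(centers[i], k_umb, traj$cv$s,
                    n_equil_discard = floor(discard_fraction *
                                              length(traj$cv$s)))
  })
}

#' Write a free-energy profile as a tab-separated table plus states JSON
#'
#' @param profile A `"fes_profile"`.
#' @param file Output TSV filename (`s`, `f`, `counts`); the states are
#'   written next to it as `<file>.states.json` when identified.
#' @export
write_profile <- function(profile, file) {
  utils::write.table(data.frame(s = profile$s_grid, f = profile$f,
                                counts = profile$counts),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(profile$minima)) {
    jsonlite::write_json(
      list(minima = profile$minima, maxima = profile$maxima,
           beta = profile$beta),
      paste0(file, ".states.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
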