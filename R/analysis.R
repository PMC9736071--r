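#' Contact specification
#'
#' A contact between two atom groups is counted in a frame when the
#' minimum distance over all cross-group atom pairs is at or below the
#' cutoff.  This is a pure distance criterion (no angle term), matching
#' how residue-atom polar contacts and salt bridges are commonly tallied
#' from trajectories.
#'
#' @param group_a,group_b Atom index lists (1-based).  Identical groups
#'   are allowed but flagged, since self-contacts are usually a spec
#'   mistake.
#' @param cutoff Distance cutoff (> 0), in the coordinate length unit
#'   (Angstrom for molecular data).
#' @return An object of class `"contact_spec"`.
#' @export
contact_spec <- function(group_a, group_b, cutoff) {
  group_a <- as.integer(group_a)
  group_b <- as.integer(group_b)
  if (!length(group_a) || !length(group_b))
    stop("contact groups must be non-empty")
  if (any(group_a < 1L) || any(group_b < 1L))
    stop("atom indices are 1-based and must be positive")
  if (cutoff <= 0) stop("cutoff must be positive")
  identical_pair <- setequal(group_a, group_b)
  if (identical_pair && length(intersect(group_a, group_b)))
    warning("group_a and group_b are identical; contact is self-referential")
  structure(list(group_a = group_a, group_b = group_b, cutoff = cutoff,
                 identical_pair = identical_pair),
            class = "contact_spec")
}

# Iterate over trajectory frames as conformations.  Accepts a
# taps_trajectory (flattened rows; needs n_points from dim attribute), a
# list of conformations, or a list of coordinate matrices.
traj_frames <- function(traj, ncol_hint = 3L) {
  if (inherits(traj, "taps_trajectory")) {
    k <- ncol_hint
    return(lapply(seq_len(nrow(traj$frames)), function(i)
      conf_unflatten(traj$frames[i, ], k)))
  }
  if (is.list(traj)) return(lapply(traj, as_conformation))
  stop("unsupported trajectory representation")
}

#' Contact-formation percentage over a trajectory
#'
#' Fraction of frames in which the minimum distance between any atom of
#' `group_a` and any atom of `group_b` is at or below the cutoff,
#' reported as a percentage.
#'
#' @param traj List of conformations (or a `"taps_trajectory"` of 3D
#'   frames).
#' @param spec A [contact_spec()].
#' @return Percentage in `[0, 100]`.
#' @export
contact_fraction <- function(traj, spec) {
  stopifnot(inherits(spec, "contact_spec"))
  frames <- traj_frames(traj)
  formed <- vapply(seq_along(frames), function(fi) {
    X <- frames[[fi]]$coords
    n <- nrow(X)
    if (max(spec$group_a, spec$group_b) > n)
      stop("contact group index out of range in frame ", fi, " (",
           n, " atoms; indices are 1-based)")
    A <- X[spec$group_a, , drop = FALSE]
    B <- X[spec$group_b, , drop = FALSE]
    d2min <- min(vapply(seq_len(nrow(A)), function(i)
      min(rowSums(sweep(B, 2, A[i, ])^2)), numeric(1)))
    sqrt(d2min) <= spec$cutoff
  }, logical(1))
  100 * mean(formed)
}

#' Mean and standard deviation of a per-frame RMSD series
#'
#' Computes the RMSD of every frame to a reference structure under the
#' given align-set/compute-set metric and returns the series mean and
#' population standard deviation (the spread statistic usually quoted
#' alongside a trajectory-average RMSD).
#'
#' @param traj List of conformations (or a `"taps_trajectory"`).
#' @param reference Reference conformation.
#' @param metric An `"rmsd"`-kind [metric_spec()].
#' @return List with `mean`, `sd`, and the per-frame `series`.
#' @export
rmsd_series_stats <- function(traj, reference, metric) {
  if (!identical(metric$kind, "rmsd"))
    stop("rmsd_series_stats requires an rmsd-kind metric")
  reference <- as_conformation(reference)
  frames <- traj_frames(traj, ncol_hint = ncol(reference$coords))
  series <- vapply(seq_along(frames), function(fi) {
    tryCatch(distance(frames[[fi]], reference, metric),
             error = function(e) stop("RMSD failed at frame ", fi, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  n <- length(series)
  list(mean = mean(series),
       sd = if (n > 1L) sqrt(mean((series - mean(series))^2)) else 0,
       series = series)
}
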