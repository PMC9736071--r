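#' Create a conformation
#'
#' A conformation is one configuration of the system: a single point in
#' R^k in toy mode (one coordinate row), or an n_atoms x 3 coordinate set
#' in molecular mode.  Optional atom labels carry identity information for
#' molecular structures; toy-mode conformations typically have none.
#'
#' @param coords Numeric matrix (points in rows, one column per spatial
#'   dimension) or a numeric vector, interpreted as a single point.
#' @param labels Optional character vector of atom identifiers, one per
#'   coordinate row.
#' @param box Optional periodic cell description (kept as metadata only;
#'   no minimum-image convention is applied).
#' @return An object of class `"conformation"`.
#' @examples
#' conformation(c(0, 0))                    # a point in the plane
#' conformation(matrix(rnorm(15), 5, 3))    # a 5-atom structure
#' @export
conformation <- function(coords, labels = NULL, box = NULL) {
  if (is.null(dim(coords))) coords <- matrix(as.numeric(coords), nrow = 1)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L || ncol(coords) < 1L)
    stop("conformation coordinates must be non-empty")
  if (any(!is.finite(coords)))
    stop("conformation coordinates must all be finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(coords))
      stop("atom labels must match the number of coordinate rows (",
           length(labels), " labels for ", nrow(coords), " atoms)")
  }
  structure(list(coords = coords, labels = labels, box = box),
            class = "conformation")
}

as_conformation <- function(x) {
  if (inherits(x, "conformation")) x else conformation(x)
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", nrow(x$coords), " point(s) in R^", ncol(x$coords),
      if (!is.null(x$labels)) " (labelled)", "\n", sep = "")
  invisible(x)
}

# Flatten a conformation to a plain vector (row-major: point 1 first).
conf_flatten <- function(x) as.numeric(t(as_conformation(x)$coords))

conf_unflatten <- function(v, ncol) {
  conformation(matrix(v, ncol = ncol, byrow = TRUE))
}

#' Distance metric specification
#'
#' Describes how the distance between two conformations is measured.
#' `"euclidean"` is the plain L2 norm of the coordinate difference (used
#' in toy mode, where conformations are points on an analytic surface).
#' `"rmsd"` first superposes the mobile conformation onto the reference
#' using only the atoms in `align_idx` (Kabsch), then takes the
#' root-mean-square deviation over the atoms in `compute_idx`.  Keeping
#' the two sets distinct follows the common practice of aligning on a
#' rigid scaffold while measuring deviation over the mobile region of
#' interest.
#'
#' @param kind `"euclidean"` or `"rmsd"`.
#' @param align_idx Integer indices (1-based, strictly increasing) of the
#'   atoms used for superposition.  Ignored for `"euclidean"`.
#' @param compute_idx Integer indices of the atoms entering the RMSD.
#'   Defaults to `align_idx` when omitted.  Ignored for `"euclidean"`.
#' @return An object of class `"metric_spec"`.
#' @export
metric_spec <- function(kind = c("euclidean", "rmsd"), align_idx = NULL,
                        compute_idx = NULL) {
  kind <- match.arg(kind)
  if (kind == "rmsd") {
    if (is.null(compute_idx)) compute_idx <- align_idx
    for (nm in c("align_idx", "compute_idx")) {
      idx <- get(nm)
      if (is.null(idx) || length(idx) == 0L)
        stop("rmsd metric requires a non-empty ", nm)
      idx <- as.integer(idx)
      if (any(idx < 1L) || is.unsorted(idx, strictly = TRUE))
        stop(nm, " must be strictly increasing positive indices (1-based)")
      assign(nm, idx)
    }
  } else {
    align_idx <- compute_idx <- NULL
  }
  structure(list(kind = kind, align_idx = align_idx,
                 compute_idx = compute_idx),
            class = "metric_spec")
}

is_euclidean <- function(metric) identical(metric$kind, "euclidean")

check_idx_range <- function(idx, n, what) {
  if (any(idx > n))
    stop(what, " contains indices beyond the ", n, " available atoms")
  idx
}

#' Kabsch superposition
#'
#' Finds the proper rotation and translation that minimize the RMSD
#' between the `align_idx` atoms of `mobile` and `reference`, and applies
#' it to all atoms of `mobile`.  The rotation is obtained from the SVD of
#' the cross-covariance matrix with the usual sign correction on the
#' smallest singular direction, so reflections are never returned.
#'
#' @param mobile,reference Conformations with equal atom counts over
#'   `align_idx`.
#' @param align_idx Atom indices used for the superposition (default: all
#'   atoms).  At least 3 non-collinear atoms are required for a unique
#'   rotation in 3D.
#' @return A list with `rotation` (k x k, determinant +1), `translation`
#'   (so that aligned coordinates are `coords %*% t(rotation) + translation`),
#'   `aligned` (the transformed mobile conformation) and `rmsd` over the
#'   alignment atoms.
#' @export
kabsch_superpose <- function(mobile, reference, align_idx = NULL) {
  mobile <- as_conformation(mobile)
  reference <- as_conformation(reference)
  A <- mobile$coords
  B <- reference$coords
  if (ncol(A) != ncol(B))
    stop("mobile and reference have different spatial dimensions (",
         ncol(A), " vs ", ncol(B), ")")
  if (is.null(align_idx)) align_idx <- seq_len(min(nrow(A), nrow(B)))
  align_idx <- as.integer(align_idx)
  check_idx_range(align_idx, nrow(A), "align_idx (mobile)")
  check_idx_range(align_idx, nrow(B), "align_idx (reference)")
  if (length(align_idx) < 3L)
    stop("degenerate alignment: need at least 3 alignment atoms, got ",
         length(align_idx))
  Am <- A[align_idx, , drop = FALSE]
  Bm <- B[align_idx, , drop = FALSE]
  ca <- colMeans(Am)
  cb <- colMeans(Bm)
  X <- sweep(Am, 2, ca)
  Y <- sweep(Bm, 2, cb)
  # collinear (or coincident) alignment sets leave the rotation about the
  # common axis undetermined
  sx <- svd(X, nu = 0, nv = 0)$d
  if (sx[2] <= max(sx[1], 1) * 1e-10)
    stop("degenerate alignment: alignment atoms are collinear ",
         "(rotation not uniquely determined)")
  sv <- svd(crossprod(X, Y))   # H = X^T Y
  k <- ncol(A)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  if (sgn == 0) sgn <- 1
  D <- diag(c(rep(1, k - 1), sgn), k)
  R <- sv$v %*% D %*% t(sv$u)
  translation <- as.numeric(cb - R %*% ca)
  aligned_coords <- A %*% t(R) + matrix(translation, nrow(A), k, byrow = TRUE)
  dev <- sqrt(mean(rowSums((aligned_coords[align_idx, , drop = FALSE] - Bm)^2)))
  list(rotation = R, translation = translation,
       aligned = conformation(aligned_coords, mobile$labels, mobile$box),
       rmsd = dev)
}

#' Distance between two conformations
#'
#' Euclidean kind: L2 norm of the flattened coordinate difference.
#' RMSD kind: superpose `a` onto `b` using the metric's alignment atoms
#' only, then root-mean-square deviation over the compute atoms.  The
#' result is symmetric in its arguments and invariant to rigid motions of
#' either argument for the RMSD kind.
#'
#' @param a,b Conformations (or coordinate matrices/vectors).
#' @param metric A [metric_spec()].
#' @return Non-negative scalar in coordinate length units.
#' @export
distance <- function(a, b, metric = metric_spec("euclidean")) {
  a <- as_conformation(a)
  b <- as_conformation(b)
  if (is_euclidean(metric)) {
    if (!all(dim(a$coords) == dim(b$coords)))
      stop("incompatible dimensions: ", nrow(a$coords), "x", ncol(a$coords),
           " vs ", nrow(b$coords), "x", ncol(b$coords))
    return(sqrt(sum((a$coords - b$coords)^2)))
  }
  n <- nrow(a$coords)
  if (nrow(b$coords) != n)
    stop("incompatible atom counts for rmsd metric: ", n, " vs ",
         nrow(b$coords))
  ai <- check_idx_range(metric$align_idx, n, "align_idx")
  ci <- check_idx_range(metric$compute_idx, n, "compute_idx")
  fit <- kabsch_superpose(a, b, ai)
  Aa <- fit$aligned$coords[ci, , drop = FALSE]
  Bb <- b$coords[ci, , drop = FALSE]
  sqrt(mean(rowSums((Aa - Bb)^2)))
}

#' All pairwise distances between conformations
#'
#' @param confs List of conformations (>= 2).
#' @param metric A [metric_spec()].
#' @return Symmetric matrix with zero diagonal; entry (i, j) is
#'   `distance(confs[[i]], confs[[j]], metric)`.
#' @export
pairwise_distances <- function(confs, metric = metric_spec("euclidean")) {
  if (length(confs) < 2L)
    stop("pairwise_distances needs at least 2 conformations")
  confs <- lapply(confs, as_conformation)
  n <- length(confs)
  if (is_euclidean(metric)) {
    dims <- vapply(confs, function(x) length(conf_flatten(x)), integer(1))
    if (length(unique(dims)) != 1L)
      stop("conformations have incompatible dimensions: ",
           paste(unique(dims), collapse = ", "))
    M <- do.call(rbind, lapply(confs, conf_flatten))
    return(unname(as.matrix(stats::dist(M))))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- tryCatch(
        distance(confs[[i]], confs[[j]], metric),
        error = function(e) stop("distance failed for pair (", i, ", ", j,
                                 "): ", conditionMessage(e), call. = FALSE))
    }
  }
  D
}
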