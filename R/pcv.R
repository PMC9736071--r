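#' Path smoothing constant lambda
#'
#' lambda sets the width of the Gaussian kernels in the path collective
#' variables.  It is computed from the inter-node spacing of the path as
#'
#'   lambda = 2.3 (N - 1) / sum_i d_{i,i+1}^2
#'
#' i.e. about 2.3 over the mean squared gap, so that neighbouring node
#' kernels overlap appreciably but distant nodes contribute little.
#' lambda carries inverse squared-distance units.
#'
#' @param path_nodes List of conformations (the path nodes, in order), or
#'   a numeric matrix with one node per row (euclidean metric).
#' @param metric A [metric_spec()].
#' @return Positive scalar.
#' @export
compute_lambda <- function(path_nodes, metric = metric_spec("euclidean")) {
  nodes <- normalize_nodes(path_nodes)
  N <- length(nodes)
  if (N < 2L) stop("a path needs at least 2 nodes")
  gaps <- vapply(seq_len(N - 1L), function(i)
    distance(nodes[[i]], nodes[[i + 1L]], metric), numeric(1))
  bad <- which(gaps < 1e-12)
  if (length(bad))
    stop("degenerate path: nodes ", bad[1], " and ", bad[1] + 1L,
         " coincide (zero consecutive gap)")
  2.3 * (N - 1L) / sum(gaps^2)
}

normalize_nodes <- function(nodes) {
  if (is.matrix(nodes))
    nodes <- lapply(seq_len(nrow(nodes)), function(i) nodes[i, ])
  lapply(nodes, as_conformation)
}

#' Construct a path
#'
#' A path is an ordered list of nodes (conformations) connecting two
#' endpoint states, together with the metric used to measure distances
#' between configurations and the smoothing constant lambda.  lambda is
#' always (re)computed from the nodes at construction, so it can never go
#' stale; any operation that modifies a path must rebuild it through this
#' constructor.
#'
#' @param nodes List of conformations, or a matrix with one node per row
#'   (each row a point in R^d, euclidean metric).
#' @param metric A [metric_spec()].
#' @param endpoints_fixed Logical; the first and last node are the
#'   designated endpoint states and are preserved by all path operations.
#' @return An object of class `"taps_path"` with fields `nodes`, `metric`,
#'   `lambda`, `endpoints_fixed`.
#' @export
taps_path <- function(nodes, metric = metric_spec("euclidean"),
                      endpoints_fixed = TRUE) {
  nodes <- normalize_nodes(nodes)
  lambda <- compute_lambda(nodes, metric)
  structure(list(nodes = nodes, metric = metric, lambda = lambda,
                 endpoints_fixed = isTRUE(endpoints_fixed)),
            class = "taps_path")
}

#' @export
print.taps_path <- function(x, ...) {
  cat("<taps_path> ", length(x$nodes), " nodes, metric ", x$metric$kind,
      ", lambda = ", format(x$lambda, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Number of nodes in a path
#' @param path A [taps_path()].
#' @export
path_length <- function(path) length(path$nodes)

# Path nodes as an N x D matrix of flattened coordinates.  Only meaningful
# under the euclidean metric (used by the sampler and fast projections).
path_node_matrix <- function(path) {
  do.call(rbind, lapply(path$nodes, conf_flatten))
}

# Consecutive inter-node distances.
path_gaps <- function(path) {
  N <- path_length(path)
  vapply(seq_len(N - 1L), function(i)
    distance(path$nodes[[i]], path$nodes[[i + 1L]], path$metric), numeric(1))
}

# Squared distances from configuration x to every node.
node_sq_distances <- function(x, path) {
  if (is_euclidean(path$metric)) {
    v <- conf_flatten(x)
    M <- path_node_matrix(path)
    if (length(v) != ncol(M))
      stop("configuration dimension ", length(v),
           " incompatible with path node dimension ", ncol(M))
    return(rowSums(sweep(M, 2, v)^2))
  }
  vapply(path$nodes, function(n) distance(x, n, path$metric)^2, numeric(1))
}

#' Project a configuration onto a path (PCV-s, PCV-z)
#'
#' The path collective variables of configuration x with respect to a
#' discretized path with N nodes are
#'
#'   s = sum_i i e^(-lambda d_{x,i}^2) / sum_i e^(-lambda d_{x,i}^2)
#'   z = -(1/lambda) ln sum_i e^(-lambda d_{x,i}^2)
#'
#' with both sums over i = 1..N.  s locates the projection of x along the
#' path in node-index units (1 at the first node, N at the last); z
#' measures the departure from the path and carries squared-distance
#' units (for large lambda, z approaches the squared distance to the
#' nearest node).  The exponential sums are stabilised by subtracting the
#' smallest exponent before exponentiation, so projections far from the
#' path never underflow to 0/0.
#'
#' @param x A conformation.
#' @param path A [taps_path()].
#' @return List with components `s` and `z` (class `"pcv_projection"`).
#' @export
pcv_project <- function(x, path) {
  d2 <- node_sq_distances(x, path)
  e <- path$lambda * d2
  emin <- min(e)
  w <- exp(-(e - emin))
  W <- sum(w)
  s <- sum(seq_along(w) * w) / W
  z <- (emin - log(W)) / path$lambda
  structure(list(s = s, z = z), class = "pcv_projection")
}

#' Analytic gradient of PCV-s with respect to the configuration
#'
#' Chain rule through the Gaussian weights of the s definition:
#'   ds/dx = (2 lambda / W) sum_i (i - s) w_i (node_i - x).
#' Only available for the euclidean metric (toy mode), where it supplies
#' the restraint force for perpendicular node sampling and umbrella runs.
#'
#' @param x A conformation (point in R^d).
#' @param path A [taps_path()] with euclidean metric.
#' @return Numeric vector of length d.
#' @export
pcv_s_gradient <- function(x, path) {
  if (!is_euclidean(path$metric))
    stop("analytic PCV-s gradient requires the euclidean metric")
  v <- conf_flatten(x)
  M <- path_node_matrix(path)
  d2 <- rowSums(sweep(M, 2, v)^2)
  e <- path$lambda * d2
  emin <- min(e)
  w <- exp(-(e - emin))
  W <- sum(w)
  s <- sum(seq_along(w) * w) / W
  coef <- (seq_along(w) - s) * w
  as.numeric(2 * path$lambda / W * colSums(coef * sweep(M, 2, v)))
}

#' Mean path distance z-bar between two paths
#'
#' The distance of a path from a reference path is the average PCV-z of
#' its nodes projected onto the reference:
#'
#'   z-bar = (1/N) sum_i z(node_i ; reference path)
#'
#' Used as the convergence monitor of the path optimization: successive
#' iterates whose z-bar differences fall below a tolerance indicate a
#' stationary path.  Any reference may be used (the previous iterate, the
#' initial path, or an oracle path).
#'
#' @param path_a The path whose nodes are projected.
#' @param ref_path The reference path (its lambda and metric are used).
#' @return Scalar in squared-distance units.
#' @export
path_z_distance <- function(path_a, ref_path) {
  if (!identical(path_a$metric$kind, ref_path$metric$kind))
    stop("paths use different metric kinds (", path_a$metric$kind, " vs ",
         ref_path$metric$kind, ")")
  z <- vapply(path_a$nodes, function(n) pcv_project(n, ref_path)$z,
              numeric(1))
  mean(z)
}

#' Export a CV time series as a tab-separated table
#'
#' Writes one header line (`step  s  z`) followed by one row per recorded
#' frame.
#'
#' @param cv Data frame with columns `step`, `s`, `z` (as produced by
#'   [simulate()] with a path bias).
#' @param file Output filename.
#' @export
write_cv_table <- function(cv, file) {
  utils::write.table(cv, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a CV table written by [write_cv_table()]
#' @param file Input filename.
#' @return Data frame with the stored columns.
#' @export
read_cv_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}
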