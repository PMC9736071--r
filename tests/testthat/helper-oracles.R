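# Independent oracles used by the tests.  These deliberately take
# different algorithmic routes from the package implementation.

# Horn's quaternion method for optimal superposition: the best rotation
# is recovered from the top eigenvector of the 4x4 key matrix built from
# the cross-covariance of the centered coordinate sets.  Returns the
# minimal RMSD over the given atoms (proper rotations only).
quaternion_rmsd <- function(A, B) {
  stopifnot(ncol(A) == 3, ncol(B) == 3, nrow(A) == nrow(B))
  ca <- colMeans(A); cb <- colMeans(B)
  X <- sweep(A, 2, ca); Y <- sweep(B, 2, cb)
  S <- t(X) %*% Y
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[1,3]+S[3,1],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],        S[2,2]-S[1,1]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[1,3]+S[3,1],        S[2,3]+S[3,2],        S[3,3]-S[1,1]-S[2,2]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Quaternion -> rotation matrix (for constructing test rigid motions).
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() quat_rotation(rnorm(4))

# Direct unstabilised evaluation of the path collective variables; valid
# whenever the exponents stay in double range (the tests keep
# lambda * d^2 moderate).
pcv_direct <- function(x, nodes_matrix, lambda) {
  d2 <- rowSums(sweep(nodes_matrix, 2, x)^2)
  w <- exp(-lambda * d2)
  list(s = sum(seq_along(w) * w) / sum(w), z = -log(sum(w)) / lambda)
}

# All permutations of 1..n as an n! x n matrix (recursive block build).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- seq.int((i - 1L) * nrow(sub) + 1L, i * nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

# Exhaustive open-tour optimum for small travelling-salesman instances:
# all permutations of the interior indices, endpoints fixed.
brute_force_tour <- function(D) {
  n <- nrow(D)
  interior <- seq.int(2L, n - 1L)
  P <- matrix(interior[all_perms(length(interior))], ncol = length(interior))
  tours <- cbind(1L, P, n)
  from <- tours[, -ncol(tours), drop = FALSE]
  to <- tours[, -1L, drop = FALSE]
  lens <- rowSums(matrix(D[cbind(as.vector(from), as.vector(to))],
                         nrow(tours)))
  list(order = tours[which.min(lens), ], length = min(lens))
}

tour_length <- function(confs, metric = metric_spec("euclidean")) {
  D <- pairwise_distances(confs, metric)
  sum(D[cbind(seq_len(nrow(D) - 1L), seq_len(nrow(D) - 1L) + 1L)])
}

# Straight equally spaced 1D path as a quick fixture.
straight_path_1d <- function(from = 0, to = 2, n = 9L) {
  taps_path(matrix(seq(from, to, length.out = n), ncol = 1))
}

# Node coordinates of a path as a plain matrix (one node per row).
path_node_matrix_test <- function(p) {
  do.call(rbind, lapply(p$nodes, conf_flatten))
}

path_gaps_test <- function(p) {
  X <- path_node_matrix_test(p)
  sqrt(rowSums((X[-1L, , drop = FALSE] - X[-nrow(X), , drop = FALSE])^2))
}
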