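#' Column-normalized adjacency matrix
#'
#' Builds W' = W D^{-1} where W is the weighted adjacency matrix of the
#' network and D the diagonal matrix of its column sums, so that every
#' column of W' sums to 1 (column-stochastic). Node order is lexicographic,
#' making the matrix (and everything downstream) bit-stable across runs.
#'
#' @param net connected `umg_network` with no isolated nodes.
#' @return Sparse `dgCMatrix` with rownames/colnames = node identifiers.
#' @export
column_normalize <- function(net) {
  stopifnot(inherits(net, "umg_network"))
  nodes <- network_nodes(net)
  perm <- match(nodes, igraph::V(net$graph)$name)
  W <- igraph::as_adjacency_matrix(net$graph, attr = "weight", sparse = TRUE)
  W <- W[perm, perm, drop = FALSE]
  dimnames(W) <- list(nodes, nodes)
  d <- Matrix::colSums(W)
  if (any(d == 0)) stop("zero column sum: network has isolated nodes")
  Wp <- W %*% Matrix::Diagonal(x = 1 / d)
  dimnames(Wp) <- list(nodes, nodes)
  methods::as(Wp, "CsparseMatrix")
}

#' Align a seed score matrix to a normalized adjacency
#'
#' Restricts a gene x sample score matrix to the network's node order,
#' filling genes present in the network but absent from the matrix with
#' zeros. Genes present in the matrix but not in the network are dropped
#' and returned as a sidecar attribute `dropped_genes` (propagation is
#' defined only on the network).
#'
#' @param scores gene x sample numeric matrix (rownames = genes).
#' @param Wp normalized adjacency from [column_normalize()].
#' @return Matrix with rows exactly `rownames(Wp)`, in order.
#' @export
align_seeds <- function(scores, Wp) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  nodes <- rownames(Wp)
  out <- matrix(0, length(nodes), ncol(scores),
                dimnames = list(nodes, colnames(scores)))
  common <- intersect(nodes, rownames(scores))
  out[common, ] <- scores[common, , drop = FALSE]
  attr(out, "dropped_genes") <- setdiff(rownames(scores), nodes)
  out
}

#' Iterative network propagation (random walk with restart)
#'
#' Iterates S(t+1) = alpha W' S(t) + (1 - alpha) S(0) until the maximum
#' per-column L1 change drops below `tolerance` or `max_iterations` is
#' reached. Samples (columns) propagate independently; the matrix form is a
#' convenience. With W' column-stochastic and alpha < 1 the iteration is a
#' contraction (spectral radius of alpha W' is at most alpha), so
#' convergence within roughly log(tolerance)/log(alpha) iterations is
#' guaranteed.
#'
#' @param Wp column-stochastic normalized adjacency.
#' @param S0 seed matrix aligned to `rownames(Wp)` (see [align_seeds()]);
#'   entries must be finite and non-negative.
#' @param alpha mixing parameter in [0.5, 1); the walker follows an edge
#'   with probability alpha and restarts at the seed distribution with
#'   probability 1 - alpha. Default 0.8.
#' @param tolerance convergence tolerance on the max per-column L1 change
#'   (default 1e-8).
#' @param max_iterations iteration cap (default 350).
#' @return list with `scores` (final matrix), `iterations` used, and
#'   `converged` flag.
#' @export
propagate_iterative <- function(Wp, S0, alpha = 0.8, tolerance = 1e-8,
                                max_iterations = 350) {
  check_alpha(alpha)
  if (!all(is.finite(S0))) stop("seed matrix contains non-finite values")
  if (any(S0 < 0)) stop("seed matrix contains negative values")
  stopifnot(nrow(S0) == nrow(Wp))
  S <- S0
  restart <- (1 - alpha) * S0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    Snew <- as.matrix(alpha * (Wp %*% S)) + restart
    delta <- max(colSums(abs(Snew - S)))
    S <- Snew
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  dimnames(S) <- dimnames(S0)
  list(scores = S, iterations = iter, converged = converged)
}

#' Closed-form stationary propagation scores
#'
#' Solves the stationary system S = (1 - alpha) (I - alpha W')^{-1} S(0)
#' directly with a dense solve. Because the spectral radius of alpha W' is
#' below 1, the resolvent exists and is entrywise non-negative, so
#' non-negative seeds give non-negative scores. Used as the verification
#' oracle for the iterative solver; guarded to small networks where a dense
#' solve is cheap.
#'
#' @inheritParams propagate_iterative
#' @param max_nodes guard on network size for the dense solve (default 5000).
#' @return Final score matrix, same shape as `S0`.
#' @export
propagate_closed_form <- function(Wp, S0, alpha = 0.8, max_nodes = 5000) {
  check_alpha(alpha)
  n <- nrow(Wp)
  if (n > max_nodes) {
    stop(sprintf("closed-form solve guarded to <= %d nodes (got %d)",
                 max_nodes, n))
  }
  if (!all(is.finite(S0))) stop("seed matrix contains non-finite values")
  if (any(S0 < 0)) stop("seed matrix contains negative values")
  A <- diag(n) - alpha * as.matrix(Wp)
  S <- solve(A, (1 - alpha) * S0)
  dimnames(S) <- dimnames(S0)
  # numerical underflow can leave tiny negatives; the exact solution is >= 0
  S[S < 0 & S > -1e-12] <- 0
  stopifnot(all(S >= 0))
  S
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0.5 || alpha >= 1) {
    stop("alpha must lie in [0.5, 1); convergence requires alpha < 1")
  }
  invisible(alpha)
}

#' Propagate a network's restriction of the mutation matrix
#'
#' Convenience wrapper: column-normalizes the network, aligns the seed
#' matrix to its nodes, and runs the iterative solver.
#'
#' @param net connected `umg_network`.
#' @param scores gene x sample quantized score matrix.
#' @inheritParams propagate_iterative
#' @return list with `initial` (aligned seeds), `final` (propagated scores),
#'   `iterations`, `converged`, `dropped_genes`.
#' @export
propagate_network <- function(net, scores, alpha = 0.8, tolerance = 1e-8,
                              max_iterations = 350) {
  Wp <- column_normalize(net)
  S0 <- align_seeds(scores, Wp)
  res <- propagate_iterative(Wp, S0, alpha, tolerance, max_iterations)
  list(initial = S0, final = res$scores, iterations = res$iterations,
       converged = res$converged,
       dropped_genes = attr(S0, "dropped_genes"))
}
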