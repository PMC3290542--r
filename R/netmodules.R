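# Structural module dissection by Markov clustering (MCL) followed by
# iterative removal of degree-one nodes.

as_adjacency <- function(network, weighted = TRUE) {
  nodes <- network$nodes$gene
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- network$edges
  if (nrow(e) > 0) {
    w <- if (weighted) e$weight else 1
    A[cbind(match(e$from, nodes), match(e$to, nodes))] <- w
    A[cbind(match(e$to, nodes), match(e$from, nodes))] <- w
  }
  A
}

#' Markov clustering of a weighted network
#'
#' Canonical MCL: self-loops set to each node's maximum incident edge
#' weight, column normalization of the weighted adjacency, then repeated
#' expansion (matrix squaring), inflation (entry-wise power
#' \code{inflation}, the granularity knob, followed by renormalization)
#' and pruning of entries below \code{prune_eps}, until the matrix changes
#' by less than \code{tol} or \code{max_iter} is reached (a warning is
#' emitted on non-convergence and the current clustering returned).
#' Clusters are read off the attractor structure of the limit matrix; a
#' node attracted by several attractor systems goes to the one containing
#' the lexicographically smallest attractor, so runs are deterministic.
#'
#' @param network a \code{\link{weighted_network}} (or a square numeric
#'   adjacency matrix with dimnames).
#' @param inflation granularity parameter, default 1.5.
#' @param prune_eps entries below this are zeroed each iteration.
#' @param max_iter,tol iteration control.
#' @param weighted use edge weights (\code{FALSE} binarizes).
#' @return list of character vectors (clusters), covering every node
#'   exactly once, ordered by size descending then by first member.
#' @export
mcl <- function(network, inflation = 1.5, prune_eps = 1e-5,
                max_iter = 100, tol = 1e-6, weighted = TRUE) {
  A <- if (is.matrix(network)) network else as_adjacency(network, weighted)
  n <- nrow(A)
  assert_that(n > 0, "network is empty")
  nodes <- rownames(A)
  if (n == 1) return(list(nodes))
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1  # isolated nodes become their own attractor
  diag(A) <- loop
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M          # expand
    M2 <- M2^inflation     # inflate
    M2 <- normalize(M2)
    M2[M2 < prune_eps] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warning("MCL did not converge in ", max_iter,
                          " iterations; returning current clustering")
  interpret_mcl(M, nodes, prune_eps)
}

interpret_mcl <- function(M, nodes, eps) {
  n <- length(nodes)
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n) # degenerate
  # attractor systems: connected components among attractors
  sub <- (M[attractors, attractors, drop = FALSE] > eps) |
    t(M[attractors, attractors, drop = FALSE] > eps)
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # assign each node to the system of the smallest attractor it feeds
  cluster_of <- integer(n)
  for (j in seq_len(n)) {
    feeds <- attractors[M[attractors, j] > eps]
    if (length(feeds) == 0) feeds <- attractors[which.max(M[attractors, j])]
    cluster_of[j] <- comp[match(min(feeds), attractors)]
  }
  out <- lapply(split(nodes, cluster_of), sort)
  names(out) <- NULL
  out[order(-vapply(out, length, integer(1)),
            vapply(out, `[`, character(1), 1))]
}

#' Prune degree-one nodes from a cluster
#'
#' Repeatedly deletes nodes with exactly one edge inside the cluster, then
#' drops isolated nodes; what survives is the 2-core of the cluster's
#' induced subgraph. Clusters falling below \code{min_size} are discarded.
#'
#' @param cluster character vector of node IDs.
#' @param network the \code{\link{weighted_network}} the cluster lives in.
#' @param min_size minimum surviving module size (default 3).
#' @return Sorted character vector of surviving nodes, or \code{NULL}.
#' @export
prune_degree_one <- function(cluster, network, min_size = 3) {
  e <- network$edges
  e <- e[e$from %in% cluster & e$to %in% cluster, c("from", "to")]
  keep <- cluster
  repeat {
    deg <- table(factor(c(e$from, e$to), levels = keep))
    ones <- names(deg)[deg == 1]
    if (length(ones) == 0) break
    keep <- setdiff(keep, ones)
    e <- e[e$from %in% keep & e$to %in% keep, ]
  }
  deg <- table(factor(c(e$from, e$to), levels = keep))
  keep <- names(deg)[deg > 0]
  if (length(keep) < min_size) NULL else sort(keep)
}

#' Dissect a network into pruned structural modules
#'
#' Runs \code{\link{mcl}} and prunes each cluster with
#' \code{\link{prune_degree_one}}; surviving modules are returned largest
#' first.
#'
#' @param network a \code{\link{weighted_network}}.
#' @inheritParams mcl
#' @inheritParams prune_degree_one
#' @return list of class \code{module_set}: \code{modules} (named list of
#'   gene vectors, \code{M1} is the largest), \code{clusters} (the raw MCL
#'   clustering before pruning).
#' @export
dissect_modules <- function(network, inflation = 1.5, min_size = 3,
                            weighted = TRUE, ...) {
  if (nrow(network$nodes) == 0) {
    return(structure(list(modules = list(), clusters = list()),
                     class = "module_set"))
  }
  clusters <- mcl(network, inflation = inflation, weighted = weighted, ...)
  pruned <- Filter(Negate(is.null),
                   lapply(clusters, prune_degree_one, network = network,
                          min_size = min_size))
  pruned <- pruned[order(-vapply(pruned, length, integer(1)),
                         vapply(pruned, `[`, character(1), 1))]
  names(pruned) <- if (length(pruned)) paste0("M", seq_along(pruned))
  structure(list(modules = pruned, clusters = clusters),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules (sizes %s)\n", length(x$modules),
              paste(vapply(x$modules, length, integer(1)), collapse = ", ")))
  invisible(x)
}
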