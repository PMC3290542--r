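# Condition-responsive network (ARN) construction.
#
# Nodes are DEGs carrying their signed differential-expression weights;
# candidate edges are interactome interactions between DEGs. Each edge is
# scored by an explicit reconstruction of a confidence x co-expression x
# node-significance weighting (the three quantities a weighted edge
# encodes here), and only edges beating an empirical null of random
# interactome edges at P <= 0.1 are retained.

#' Pearson expression correlation between two genes
#'
#' Computed across all samples of the study. A zero-variance gene yields a
#' correlation of 0 with a warning rather than NA, so degenerate genes
#' drop out of edge weights instead of poisoning them.
#'
#' @param study an \code{\link{expression_study}}.
#' @param i,j gene IDs.
#' @return Correlation in [-1, 1].
#' @export
expression_correlation <- function(study, i, j) {
  x <- study$matrix[i, ]; y <- study$matrix[j, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance gene; correlation set to 0")
    return(0)
  }
  unname(cor(x, y))
}

#' Edge weight from confidence, co-expression and node significance
#'
#' \eqn{W_{ij} = c_{ij} |r_{ij}| (|w_i| + |w_j|) / 2}: an interaction
#' matters to the response when it is confidently annotated, co-expressed
#' in these samples, and joins significantly changed genes. Symmetric in
#' (i, j); zero iff the correlation is zero or both node weights are.
#'
#' @param w_i,w_j signed node weights in [-1, 1].
#' @param r_ij expression correlation in [-1, 1].
#' @param c_ij interactome confidence in (0, 1].
#' @return Non-negative edge weight.
#' @examples
#' edge_weight(0.6, 0.2, -0.5, 0.8)  # 0.16
#' @export
edge_weight <- function(w_i, w_j, r_ij, c_ij) {
  assert_that(all(abs(c(w_i, w_j)) <= 1), "node weights must be in [-1, 1]")
  assert_that(all(abs(r_ij) <= 1), "correlation must be in [-1, 1]")
  assert_that(all(c_ij > 0 & c_ij <= 1), "confidence must be in (0, 1]")
  c_ij * abs(r_ij) * (abs(w_i) + abs(w_j)) / 2
}

# Vectorized weights for an edge table against a named weight vector and
# the study's correlation structure.
edge_weights_for <- function(edges, weights, study) {
  if (nrow(edges) == 0) return(numeric(0))
  m <- study$matrix
  sds <- apply(m, 1, stats::sd)
  r <- vapply(seq_len(nrow(edges)), function(k) {
    a <- edges$from[k]; b <- edges$to[k]
    if (sds[a] == 0 || sds[b] == 0) 0 else cor(m[a, ], m[b, ])
  }, numeric(1))
  W <- edges$confidence * abs(r) *
    (abs(weights[edges$from]) + abs(weights[edges$to])) / 2
  list(W = unname(W), r = unname(r))
}

#' Empirical edge-weight threshold
#'
#' The null distribution is obtained by recomputing the edge weight on
#' \code{B} interactome edges drawn at random among measured genes, using
#' those genes' (possibly near-zero) weights and correlations. A candidate
#' is kept when \eqn{(1 + \#\{null \ge W\})/(1 + B) \le} \code{p_cutoff}.
#'
#' @param candidate_edges data.frame \code{from}, \code{to},
#'   \code{confidence}: interactome edges whose endpoints are both DEGs.
#' @param interactome full interactome edge list (the null pool).
#' @param degset a \code{degset} from \code{\link{call_degs}} supplying
#'   node weights for all measured genes.
#' @param study the expression study (for correlations).
#' @param B null draws (warning below 100).
#' @param p_cutoff empirical P cutoff, default 0.1.
#' @param seed RNG seed.
#' @return \code{candidate_edges} rows that pass, with columns
#'   \code{weight}, \code{correlation} and \code{empirical_p} added.
#' @export
empirical_edge_threshold <- function(candidate_edges, interactome, degset,
                                     study, B = 1000, p_cutoff = 0.1,
                                     seed = 1) {
  if (B < 100) warning("B < 100 gives a coarse empirical null")
  if (nrow(candidate_edges) == 0) {
    out <- candidate_edges
    out$weight <- numeric(0); out$correlation <- numeric(0)
    out$empirical_p <- numeric(0)
    return(out)
  }
  weights <- setNames(degset$weight, degset$gene)
  measured <- rownames(study$matrix)
  pool <- interactome[interactome$from %in% measured &
                        interactome$to %in% measured, , drop = FALSE]
  assert_that(nrow(pool) > 0, "no interactome edges among measured genes")
  obs <- edge_weights_for(candidate_edges, weights, study)
  null_w <- with_seed(seed, {
    idx <- sample.int(nrow(pool), B, replace = TRUE)
    edge_weights_for(pool[idx, , drop = FALSE], weights, study)$W
  })
  null_sorted <- sort(null_w)
  n_ge <- B - findInterval(obs$W - 1e-12, null_sorted)
  emp_p <- (1 + n_ge) / (1 + B)
  out <- candidate_edges
  out$weight <- obs$W
  out$correlation <- obs$r
  out$empirical_p <- emp_p
  out[emp_p <= p_cutoff, , drop = FALSE]
}

#' Build the condition-responsive network (ARN)
#'
#' Restricts the interactome to interactions between DEGs, scores each
#' candidate with \code{\link{edge_weight}}, applies
#' \code{\link{empirical_edge_threshold}}, and returns the network of DEGs
#' incident to at least one retained edge.
#'
#' @inheritParams empirical_edge_threshold
#' @return A \code{weighted_network}: list with \code{nodes} (data.frame
#'   \code{gene}, \code{weight}, \code{direction}) and \code{edges}
#'   (data.frame \code{from}, \code{to}, \code{weight},
#'   \code{correlation}, \code{confidence}, \code{empirical_p});
#'   undirected, each edge stored once.
#' @export
build_arn <- function(degset, interactome, study, B = 1000, p_cutoff = 0.1,
                      seed = 1) {
  stopifnot(inherits(degset, "degset"))
  degs <- degset$gene[degset$direction != "none"]
  cand <- interactome[interactome$from %in% degs &
                        interactome$to %in% degs, , drop = FALSE]
  kept <- if (nrow(cand) > 0) {
    empirical_edge_threshold(cand, interactome, degset, study,
                             B = B, p_cutoff = p_cutoff, seed = seed)
  } else cand
  if (is.null(kept$weight)) {
    kept$weight <- numeric(0); kept$correlation <- numeric(0)
    kept$empirical_p <- numeric(0)
  }
  if (nrow(kept) == 0) warning("no edges retained; ARN is empty")
  nodes <- sort(unique(c(kept$from, kept$to)))
  idx <- match(nodes, degset$gene)
  weighted_network(
    nodes = data.frame(gene = nodes,
                       weight = degset$weight[idx],
                       direction = degset$direction[idx],
                       stringsAsFactors = FALSE),
    edges = kept[, c("from", "to", "weight", "correlation", "confidence",
                     "empirical_p")])
}

#' Construct a weighted network object
#'
#' @param nodes data.frame with at least \code{gene} and \code{weight}
#'   (optionally \code{direction}).
#' @param edges data.frame with at least \code{from}, \code{to},
#'   \code{weight}; endpoints must appear in \code{nodes}.
#' @return list of class \code{weighted_network}.
#' @export
weighted_network <- function(nodes, edges) {
  assert_that(all(c("gene", "weight") %in% names(nodes)),
              "nodes need columns gene, weight")
  assert_that(all(c("from", "to", "weight") %in% names(edges)),
              "edges need columns from, to, weight")
  assert_that(all(c(edges$from, edges$to) %in% nodes$gene),
              "every edge endpoint must be a node")
  assert_that(all(edges$weight >= 0), "edge weights must be >= 0")
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Split a network into up- and down-regulated subnetworks
#'
#' Induced subgraphs on the nodes called up and down; edges joining the
#' two directions belong to neither.
#'
#' @param arn a \code{weighted_network} whose nodes carry
#'   \code{direction}.
#' @param degset optional \code{degset}; used for directions when the
#'   network nodes lack a \code{direction} column.
#' @return list with \code{up} and \code{down} \code{weighted_network}s.
#' @export
split_updown <- function(arn, degset = NULL) {
  stopifnot(inherits(arn, "weighted_network"))
  dir <- arn$nodes$direction
  if (is.null(dir)) {
    assert_that(!is.null(degset), "need directions from nodes or a degset")
    dir <- degset$direction[match(arn$nodes$gene, degset$gene)]
  }
  take <- function(d) {
    genes <- arn$nodes$gene[dir == d]
    weighted_network(arn$nodes[dir == d, , drop = FALSE],
                     arn$edges[arn$edges$from %in% genes &
                                 arn$edges$to %in% genes, , drop = FALSE])
  }
  list(up = take("up"), down = take("down"))
}
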