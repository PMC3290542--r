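# ResponseNet-style minimum-cost flow: route a fixed amount of flow from
# miRNA source nodes through the regulatory network to concordantly
# responding sink genes, minimizing total -log(normalized edge weight).
# Solved by successive shortest paths on the residual network (unit
# capacities; Bellman-Ford handles the negative residual arcs), which is
# optimal for convex costs and deterministic under a fixed edge order.

#' Build a flow problem from a regulatory network
#'
#' A super-source S feeds every source miRNA and every sink gene feeds a
#' super-sink T (cost 0, capacity 1). Directed regulatory edges enter as
#' single arcs; undirected functional edges as two antiparallel arcs. The
#' cost of a network arc is \eqn{-\log(W / W_{max})} with the normalized
#' weight floored at \code{weight_floor}, so all costs are finite and
#' non-negative; zero-weight edges are excluded.
#'
#' @param frn a \code{regulatory_network} from \code{\link{build_frn}}.
#' @param sources,sinks node IDs (non-empty, disjoint).
#' @param flow requested flow value; defaults to \code{length(sinks)} and
#'   is capped at the maximum feasible value when
#'   \code{\link{solve_min_cost_flow}} is called with
#'   \code{allow_shortfall = TRUE}.
#' @param capacity per-edge capacity (default 1).
#' @param weight_floor lower bound on the normalized weight.
#' @return list of class \code{flow_problem} with arc table and node names.
#' @export
build_flow_problem <- function(frn, sources, sinks, flow = length(sinks),
                               capacity = 1, weight_floor = 1e-6) {
  assert_that(length(sources) > 0 && length(sinks) > 0,
              "sources and sinks must be non-empty")
  assert_that(length(intersect(sources, sinks)) == 0,
              "sources and sinks must be disjoint")
  fun <- frn$base$edges
  reg <- frn$reg_edges
  arcs <- rbind(
    if (nrow(fun) > 0) data.frame(from = c(fun$from, fun$to),
                                  to = c(fun$to, fun$from),
                                  weight = c(fun$weight, fun$weight),
                                  stringsAsFactors = FALSE),
    if (nrow(reg) > 0) data.frame(from = reg$from, to = reg$to,
                                  weight = reg$weight,
                                  stringsAsFactors = FALSE))
  if (is.null(arcs)) arcs <- data.frame(from = character(0),
                                        to = character(0),
                                        weight = numeric(0))
  arcs <- arcs[arcs$weight > 0, , drop = FALSE]  # zero weight = infinite cost
  wmax <- if (nrow(arcs) > 0) max(arcs$weight) else 1
  cost <- -log(pmax(arcs$weight / wmax, weight_floor))
  nodes <- sort(unique(c(arcs$from, arcs$to, sources, sinks)))
  assert_that(!any(c("__S__", "__T__") %in% nodes), "reserved node name used")
  arc_tab <- rbind(
    data.frame(from = "__S__", to = sources, cost = 0,
               cap = capacity, stringsAsFactors = FALSE),
    data.frame(from = arcs$from, to = arcs$to, cost = cost,
               cap = capacity, stringsAsFactors = FALSE),
    data.frame(from = sinks, to = "__T__", cost = 0,
               cap = capacity, stringsAsFactors = FALSE))
  structure(list(arcs = arc_tab, nodes = c("__S__", nodes, "__T__"),
                 sources = sources, sinks = sinks, flow = flow),
            class = "flow_problem")
}

#' Solve a minimum-cost flow problem
#'
#' Successive shortest augmenting paths on the residual network. Among
#' feasible flows of the requested value the total cost is optimal; ties
#' between equal-cost shortest paths are broken by a fixed arc order, so
#' the solution is deterministic.
#'
#' @param problem a \code{flow_problem}.
#' @param allow_shortfall if \code{TRUE}, an infeasible request falls back
#'   to the maximum feasible flow instead of erroring.
#' @return list of class \code{flow_result}: \code{edges} (from, to, flow,
#'   cost per unit), \code{nodes} (node, throughput), \code{total_cost},
#'   \code{flow} (value actually routed).
#' @export
solve_min_cost_flow <- function(problem, allow_shortfall = FALSE) {
  stopifnot(inherits(problem, "flow_problem"))
  nodes <- problem$nodes
  n <- length(nodes)
  a <- problem$arcs
  m <- nrow(a)
  # residual arc arrays: forward arcs 1..m, reverse arcs m+1..2m
  afrom <- c(match(a$from, nodes), match(a$to, nodes))
  ato <- c(match(a$to, nodes), match(a$from, nodes))
  acost <- c(a$cost, -a$cost)
  acap <- c(a$cap, rep(0, m))
  partner <- c(m + seq_len(m), seq_len(m))
  s <- 1L; t <- n
  routed <- 0L
  total_cost <- 0
  while (routed < problem$flow) {
    # Bellman-Ford from s over residual arcs (fixed order => deterministic)
    dist <- rep(Inf, n); dist[s] <- 0
    pred_arc <- rep(NA_integer_, n)
    for (it in seq_len(n - 1)) {
      ok <- acap > 0 & is.finite(dist[afrom])
      nd <- dist[afrom[ok]] + acost[ok]
      improved <- FALSE
      idx <- which(ok)
      for (z in seq_along(idx)) {
        e <- idx[z]
        if (nd[z] < dist[ato[e]] - 1e-12) {
          dist[ato[e]] <- nd[z]
          pred_arc[ato[e]] <- e
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (!is.finite(dist[t])) {
      if (allow_shortfall) break
      stop("infeasible: cannot route ", problem$flow - routed,
           " more unit(s) of flow", call. = FALSE)
    }
    # trace path, find bottleneck, augment
    path <- integer(0); v <- t
    while (v != s) { path <- c(pred_arc[v], path); v <- afrom[pred_arc[v]] }
    push <- min(acap[path], problem$flow - routed)
    acap[path] <- acap[path] - push
    acap[partner[path]] <- acap[partner[path]] + push
    total_cost <- total_cost + push * dist[t]
    routed <- routed + push
  }
  fwd_flow <- acap[m + seq_len(m)]  # reverse residual = flow on forward arc
  res_edges <- data.frame(from = a$from, to = a$to, flow = fwd_flow,
                          cost = a$cost, stringsAsFactors = FALSE)
  res_edges <- res_edges[res_edges$flow > 0, , drop = FALSE]
  inflow <- tapply(res_edges$flow, res_edges$to, sum)
  inner <- setdiff(nodes, c("__S__", "__T__"))
  node_tab <- data.frame(node = inner,
                         throughput = as.numeric(inflow[inner]),
                         stringsAsFactors = FALSE)
  node_tab$throughput[is.na(node_tab$throughput)] <- 0
  structure(list(edges = res_edges, nodes = node_tab,
                 total_cost = total_cost, flow = routed),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: value %g, total cost %.4f, %d active edges\n",
              x$flow, x$total_cost, nrow(x$edges)))
  invisible(x)
}

#' Rank nodes by flow throughput
#'
#' Descending throughput with competition ranking (ties share the best
#' rank); the super-source/super-sink are excluded, as are nodes off all
#' flow paths.
#'
#' @param result a \code{flow_result}.
#' @return data.frame \code{node}, \code{throughput}, \code{rank}.
#' @export
rank_flow_nodes <- function(result) {
  stopifnot(inherits(result, "flow_result"))
  tab <- result$nodes[result$nodes$throughput > 0, , drop = FALSE]
  tab <- tab[order(-tab$throughput, tab$node), , drop = FALSE]
  tab$rank <- competition_rank(tab$throughput)
  rownames(tab) <- NULL
  tab
}

#' Export a flow result as a DOT graph
#'
#' @param result a \code{flow_result}.
#' @param path file to write.
#' @return Invisibly, the path.
#' @export
write_flow_dot <- function(result, path) {
  lines <- c("digraph flow {",
             sprintf("  \"%s\" -> \"%s\" [penwidth=%g, label=\"%.2f\"];",
                     result$edges$from, result$edges$to,
                     pmax(result$edges$flow, 0.5), result$edges$flow),
             "}")
  writeLines(lines, path)
  invisible(path)
}
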