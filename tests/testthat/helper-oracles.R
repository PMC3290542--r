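# Independent oracles used to validate the solvers against brute force.

# All simple __S__ -> __T__ paths of a flow problem, as arc-index vectors.
enumerate_st_paths <- function(problem) {
  a <- problem$arcs
  paths <- list()
  dfs <- function(v, visited, arcs_so_far) {
    if (v == "__T__") {
      paths[[length(paths) + 1L]] <<- arcs_so_far
      return(invisible(NULL))
    }
    for (e in which(a$from == v)) {
      w <- a$to[e]
      if (!(w %in% visited)) dfs(w, c(visited, w), c(arcs_so_far, e))
    }
  }
  dfs("__S__", "__S__", integer(0))
  paths
}

# Brute-force minimum-cost flow: integer flows with unit capacities
# decompose into arc-disjoint simple S->T paths (plus removable
# non-negative-cost cycles), so the optimum is the best combination of k
# distinct paths whose joint arc usage respects the capacities, for the
# largest feasible k <= problem$flow.
oracle_min_cost_flow <- function(problem) {
  a <- problem$arcs
  paths <- enumerate_st_paths(problem)
  best <- list(flow = 0L, cost = 0)
  if (length(paths) == 0) return(best)
  costs <- vapply(paths, function(p) sum(a$cost[p]), numeric(1))
  for (k in seq_len(min(problem$flow, length(paths)))) {
    combos <- utils::combn(length(paths), k)
    cost_k <- apply(combos, 2, function(idx) {
      usage <- table(unlist(paths[idx]))
      if (all(usage <= a$cap[as.integer(names(usage))])) {
        sum(costs[idx])
      } else NA_real_
    })
    if (any(!is.na(cost_k))) {
      best <- list(flow = k, cost = min(cost_k, na.rm = TRUE))
    }
  }
  best
}

# Seeded random unit-capacity flow problem with at most 8 interior nodes
# (10 including the super-source and super-sink).
random_flow_problem <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  arcs <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
  sources <- sample(nodes, sample(1:2, 1))
  sinks <- sample(setdiff(nodes, sources), sample(1:2, 1))
  arc_tab <- rbind(
    data.frame(from = "__S__", to = sources, cost = 0, cap = 1,
               stringsAsFactors = FALSE),
    if (nrow(arcs) > 0) {
      data.frame(from = arcs$from, to = arcs$to,
                 cost = round(runif(nrow(arcs), 0, 2), 3), cap = 1,
                 stringsAsFactors = FALSE)
    },
    data.frame(from = sinks, to = "__T__", cost = 0, cap = 1,
               stringsAsFactors = FALSE))
  structure(list(arcs = arc_tab, nodes = c("__S__", nodes, "__T__"),
                 sources = sources, sinks = sinks,
                 flow = sample(1:3, 1)),
            class = "flow_problem")
}

# Exhaustive simple-cycle enumeration (<= max_len nodes) built on igraph's
# path enumeration, independent of the package's own search: a cycle is
# rooted at its smallest node s and is s plus a simple path from one of
# s's successors back to s through nodes ordered after s.
oracle_cycles <- function(edges, max_len) {
  e <- unique(edges[edges$from != edges$to, c("from", "to"), drop = FALSE])
  nodes <- sort(unique(c(e$from, e$to)))
  g <- igraph::graph_from_data_frame(e, directed = TRUE, vertices = nodes)
  cycles <- list()
  for (s in nodes) {
    sub <- igraph::induced_subgraph(g, nodes[nodes >= s])
    succ <- sort(e$to[e$from == s & e$to > s])
    for (w in succ) {
      ps <- igraph::all_simple_paths(sub, from = w, to = s, mode = "out",
                                     cutoff = max_len - 1)
      for (p in ps) {
        nm <- igraph::V(sub)$name[p]
        cycles[[length(cycles) + 1L]] <- c(s, nm[-length(nm)])
      }
    }
  }
  cycles
}

# Canonical multiset representation of a cycle list for comparison.
cycle_signature <- function(cycles) {
  sort(vapply(cycles, paste, character(1), collapse = ">"))
}

# Seeded random digraph with n nodes and edge probability p.
random_digraph <- function(seed, n, p = 0.3) {
  set.seed(seed)
  pairs <- expand.grid(from = paste0("v", seq_len(n)),
                       to = paste0("v", seq_len(n)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# Small, fast synthetic configuration for unit tests.
small_config <- function(seed = 1, ...) {
  synthetic_config(n_genes = 300, n_mirnas = 40, n_de_up = 30,
                   n_de_down = 20, n_modules = 2, module_size = 10,
                   n_tfs = 10, n_de_mirnas = 4, seed = seed, ...)
}
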