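# Bounded enumeration of feedback loops (simple directed cycles) in the
# regulatory network. Only directed regulatory edges participate by
# default: feedback requires direction. A breadth-limited search from each
# start node, restricted to nodes ordered after the start, yields every
# simple cycle exactly once in its canonical rotation.

#' Enumerate feedback loops of bounded length
#'
#' All simple directed cycles with between 2 and \code{max_len} nodes.
#' Each cycle is reported once, rotated to start at its lexicographically
#' smallest node, and the output ordering is deterministic (by length,
#' then members).
#'
#' @param edges a \code{regulatory_network} (its directed regulatory edges
#'   are used; set \code{include_functional = TRUE} to also treat
#'   functional edges as bidirectional steps) or a data.frame with columns
#'   \code{from}, \code{to}.
#' @param max_len maximum cycle length (number of nodes), >= 2; default 5.
#' @param include_functional only meaningful for a
#'   \code{regulatory_network} input.
#' @return list of class \code{loop_set}; each element a character vector
#'   of cycle members in traversal order.
#' @examples
#' find_feedback_loops(data.frame(from = c("A", "B"), to = c("B", "A")))
#' @export
find_feedback_loops <- function(edges, max_len = 5,
                                include_functional = FALSE) {
  assert_that(max_len >= 2, "max_len must be at least 2")
  if (inherits(edges, "regulatory_network")) {
    e <- edges$reg_edges[, c("from", "to")]
    if (include_functional) {
      fun <- edges$base$edges
      e <- rbind(e, data.frame(from = c(fun$from, fun$to),
                               to = c(fun$to, fun$from)))
    }
  } else {
    e <- edges[, c("from", "to")]
  }
  e <- unique(e[e$from != e$to, , drop = FALSE])
  assert_that(nrow(e) >= 1, "need at least one directed edge")
  nodes <- sort(unique(c(e$from, e$to)))
  adj <- lapply(setNames(nodes, nodes),
                function(v) sort(e$to[e$from == v]))
  cycles <- list()
  # DFS from each start; only visit nodes ordered after the start so each
  # cycle is found exactly once, rooted at its smallest node
  for (start in nodes) {
    stack <- list(start)
    walk <- function(path) {
      v <- path[length(path)]
      for (w in adj[[v]]) {
        if (w == start && length(path) >= 2) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (w > start && !(w %in% path) && length(path) < max_len) {
          walk(c(path, w))
        }
      }
    }
    walk(start)
  }
  ord <- order(vapply(cycles, length, integer(1)),
               vapply(cycles, paste, character(1), collapse = "\r"))
  structure(cycles[ord], class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set: %d feedback loop(s)\n", length(x)))
  for (cy in head(x, 10)) cat(" ", paste(cy, collapse = " -> "), "\n")
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}
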