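# Regulator weighting and assembly of the full regulatory network (FRN):
# TFs are scored by prestige centrality over the DEGs they target (a TF
# need not be differentially expressed itself to matter), the top decile
# become hub TFs, and hub-TF / DE-miRNA edges are layered onto the ARN.

#' Prestige-centrality weights for transcription factors
#'
#' One-step weighted prestige: \eqn{score(TF) = \sum_t c_{TF,t} |w_t|}
#' over the TF's targets that are DEGs. The TF's own differential
#' expression is deliberately not required. With \code{iterative = TRUE} a
#' damped power iteration over the reversed regulatory graph is used
#' instead (scores flow from targets to their regulators until
#' convergence), normalized to the same scale.
#'
#' @param tf_targets data.frame \code{from} (TF), \code{to} (target),
#'   optional \code{confidence} (defaults to 1).
#' @param degset a \code{degset} from \code{\link{call_degs}}.
#' @param iterative use the damped power-iteration variant.
#' @param damping,tol,max_iter power-iteration controls.
#' @return Named numeric vector of TF scores (>= 0), all TFs present.
#' @export
prestige_weights <- function(tf_targets, degset, iterative = FALSE,
                             damping = 0.85, tol = 1e-10, max_iter = 200) {
  assert_that(nrow(tf_targets) > 0, "target map is empty")
  conf <- tf_targets$confidence %||% rep(1, nrow(tf_targets))
  w <- setNames(abs(degset$weight), degset$gene)
  is_deg <- setNames(degset$direction != "none", degset$gene)
  tv <- ifelse(tf_targets$to %in% degset$gene & is_deg[tf_targets$to],
               w[tf_targets$to], 0)
  tv[is.na(tv)] <- 0
  base <- tapply(conf * tv, tf_targets$from, sum)
  tfs <- sort(unique(tf_targets$from))
  scores <- setNames(rep(0, length(tfs)), tfs)
  scores[names(base)] <- as.numeric(base)
  if (!iterative) return(scores)
  # damped fixed point s = base + damping * M s, where M[tf, tf'] is the
  # out-degree-normalized confidence of tf -> tf' edges: a regulator also
  # inherits prestige from regulators it feeds. Row sums of M are <= 1, so
  # damping < 1 guarantees a contraction.
  deg <- table(tf_targets$from)
  is_tf_target <- tf_targets$to %in% tfs
  s <- scores
  for (i in seq_len(max_iter)) {
    contrib <- conf / as.numeric(deg[tf_targets$from]) *
      ifelse(is_tf_target, s[tf_targets$to], 0)
    contrib[is.na(contrib)] <- 0
    inherit <- tapply(contrib, tf_targets$from, sum)
    s_new <- scores
    s_new[names(inherit)] <- s_new[names(inherit)] +
      damping * as.numeric(inherit)
    if (max(abs(s_new - s)) < tol) { s <- s_new; break }
    s <- s_new
  }
  s
}

#' Select hub regulators
#'
#' The top \code{fraction} of regulators by score: \code{ceiling(fraction
#' * N)} of them, ranked score-descending with lexicographic tie-breaks so
#' selection is deterministic.
#'
#' @param tf_weights named score vector from \code{\link{prestige_weights}}.
#' @param fraction fraction to select, in (0, 1]; default 0.10.
#' @return Character vector of hub IDs.
#' @examples
#' select_hubs(setNames(runif(335), paste0("TF", 1:335)))  # 34 hubs
#' @export
select_hubs <- function(tf_weights, fraction = 0.10) {
  assert_that(length(tf_weights) >= 1, "need at least one regulator")
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  ord <- order(-tf_weights, names(tf_weights))
  names(tf_weights)[ord][seq_len(ceiling(fraction * length(tf_weights)))]
}

#' Assemble the full regulatory network (FRN)
#'
#' Adds directed regulatory edges to the ARN: hub TFs to their targets
#' among the ARN genes (and other hub TFs), and differentially expressed
#' miRNAs to their targets among the ARN genes and hub TFs. Regulatory
#' edge weight is \eqn{c \cdot (|w_{reg}| + |w_{target}|)/2} — the
#' functional-edge formula with the correlation factor at 1, since motif
#' and target maps carry no expression correlation; regulator weights are
#' prestige scores (TFs, rescaled to max 1) or DE weights (miRNAs), which
#' keeps all edge weights on one scale for the flow costs.
#'
#' @param arn the \code{\link{weighted_network}} from \code{\link{build_arn}}.
#' @param hub_tfs character vector from \code{\link{select_hubs}}.
#' @param tf_targets,mirna_targets directed edge lists (\code{from},
#'   \code{to}, optional \code{confidence}).
#' @param tf_weights prestige scores for (at least) the hub TFs.
#' @param mirna_degs \code{degset} of the miRNA study (defines DE miRNAs
#'   and their weights); genes with direction \code{none} are ignored.
#' @param anticorrelation_only keep a miRNA edge only when the miRNA and
#'   target expressions are negatively correlated (needs both studies).
#' @param study,mirna_study required for \code{anticorrelation_only}.
#' @return list of class \code{regulatory_network}: \code{base} (the ARN),
#'   \code{nodes} (all nodes with \code{type}, \code{weight}),
#'   \code{reg_edges} (directed: \code{from}, \code{to}, \code{type} in
#'   tf/mirna, \code{weight}, \code{confidence}).
#' @export
build_frn <- function(arn, hub_tfs, tf_targets, mirna_targets,
                      tf_weights, mirna_degs,
                      anticorrelation_only = FALSE,
                      study = NULL, mirna_study = NULL) {
  stopifnot(inherits(arn, "weighted_network"))
  arn_genes <- arn$nodes$gene
  node_w <- setNames(abs(arn$nodes$weight), arn_genes)
  hub_w <- if (length(hub_tfs)) {
    rescale_max_abs(tf_weights[hub_tfs])
  } else numeric(0)
  de_mir <- mirna_degs$gene[mirna_degs$direction != "none"]
  mir_w <- setNames(mirna_degs$weight, mirna_degs$gene)[de_mir]
  target_w <- c(node_w, abs(hub_w))
  reg_rows <- function(map, regs, reg_w, type, allowed_targets) {
    m <- map[map$from %in% regs & map$to %in% allowed_targets, , drop = FALSE]
    if (nrow(m) == 0) {
      return(data.frame(from = character(0), to = character(0),
                        type = character(0), weight = numeric(0),
                        confidence = numeric(0), stringsAsFactors = FALSE))
    }
    conf <- m$confidence %||% rep(1, nrow(m))
    data.frame(from = m$from, to = m$to, type = type,
               weight = conf * (abs(reg_w[m$from]) + target_w[m$to]) / 2,
               confidence = conf, row.names = NULL, stringsAsFactors = FALSE)
  }
  tf_e <- reg_rows(tf_targets, hub_tfs, hub_w, "tf",
                   c(arn_genes, setdiff(hub_tfs, arn_genes)))
  mir_e <- reg_rows(mirna_targets, de_mir, mir_w, "mirna",
                    c(arn_genes, setdiff(hub_tfs, arn_genes)))
  if (anticorrelation_only && nrow(mir_e) > 0) {
    assert_that(!is.null(study) && !is.null(mirna_study),
                "anticorrelation filter needs both expression studies")
    shared <- intersect(colnames(study$matrix), colnames(mirna_study$matrix))
    keep <- vapply(seq_len(nrow(mir_e)), function(k) {
      tg <- mir_e$to[k]
      if (!tg %in% rownames(study$matrix)) return(TRUE) # unmeasurable: keep
      cor(mirna_study$matrix[mir_e$from[k], shared],
          study$matrix[tg, shared]) < 0
    }, logical(1))
    mir_e <- mir_e[keep, , drop = FALSE]
  }
  reg_edges <- unique(rbind(tf_e, mir_e))
  extra <- setdiff(unique(c(reg_edges$from, reg_edges$to)), arn_genes)
  nodes <- rbind(
    data.frame(node = arn_genes, type = "gene",
               weight = arn$nodes$weight, stringsAsFactors = FALSE),
    data.frame(node = extra,
               type = ifelse(extra %in% hub_tfs, "tf", "mirna"),
               weight = unname(c(hub_w, mir_w)[extra]),
               stringsAsFactors = FALSE))
  structure(list(base = arn, nodes = nodes, reg_edges = reg_edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "regulatory_network: %d nodes, %d functional + %d regulatory edges\n",
    nrow(x$nodes), nrow(x$base$edges), nrow(x$reg_edges)))
  invisible(x)
}

#' Annotated fraction among top-ranked IDs
#'
#' For each requested percentage p, the fraction of the top
#' \code{ceiling(p/100 * N)} scored IDs that belong to a binary annotation
#' set. Generalizes rank-vs-annotation validation curves (e.g. literature
#' co-citation of top-weighted regulators with a phenotype keyword).
#'
#' @param scores named numeric vector.
#' @param annotated character vector of annotated IDs.
#' @param percents percentages in (0, 100].
#' @return Named numeric vector, one fraction per percent.
#' @export
weight_rank_annotation_curve <- function(scores, annotated,
                                         percents = c(1, 5, 10, 25, 50, 100)) {
  assert_that(length(scores) > 0, "scores must be non-empty")
  assert_that(length(percents) > 0, "percents must be non-empty")
  ord <- names(scores)[order(-scores, names(scores))]
  vapply(setNames(percents, paste0("top", percents, "%")), function(p) {
    k <- ceiling(p / 100 * length(scores))
    mean(ord[seq_len(k)] %in% annotated)
  }, numeric(1))
}
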