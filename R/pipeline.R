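# End-to-end orchestration: configuration, in-memory stage runner, and the
# file-based pipeline with logged thresholds and seeds.

#' Pipeline configuration
#'
#' Collects input paths and every tunable threshold. The defaults are the
#' method's canonical cutoffs: DEGs at BH FDR 0.1, per-individual
#' concordance at P 0.05, empirical edge P 0.1, MCL granularity 1.5, top
#' 10% hub TFs, enrichment FDR 0.05, feedback loops of up to 5 steps.
#'
#' @param expression,samples,mirna_expression,interactome,tf_targets,mirna_targets
#'   input file paths (TSV; see \code{\link{write_fixtures}} for the
#'   layouts).
#' @param genesets optional GMT file for enrichment.
#' @param out_dir directory for stage outputs.
#' @param deg_fdr,concordance_alpha,edge_p,mcl_inflation,hub_fraction,enrich_fdr,loop_max_len
#'   stage thresholds (see Description).
#' @param B permutation rounds for all permutation nulls.
#' @param flow requested flow value (default: number of sink genes, capped
#'   at the maximum feasible flow).
#' @param seed master seed; per-stage sub-seeds are derived from it and
#'   logged.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expression, samples, mirna_expression,
                            interactome, tf_targets, mirna_targets,
                            genesets = NULL, out_dir = ".",
                            deg_fdr = 0.1, concordance_alpha = 0.05,
                            edge_p = 0.1, mcl_inflation = 1.5,
                            hub_fraction = 0.10, enrich_fdr = 0.05,
                            loop_max_len = 5, B = 1000, flow = NULL,
                            seed = 1) {
  cfg <- as.list(environment())
  thr <- c(deg_fdr = deg_fdr, concordance_alpha = concordance_alpha,
           edge_p = edge_p, hub_fraction = hub_fraction,
           enrich_fdr = enrich_fdr)
  assert_that(all(thr > 0 & thr <= 1),
              "all probability thresholds must lie in (0, 1]")
  assert_that(mcl_inflation > 1, "mcl_inflation must exceed 1")
  assert_that(loop_max_len >= 2, "loop_max_len must be at least 2")
  assert_that(B >= 1, "B must be positive")
  structure(cfg, class = "pipeline_config")
}

with_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run every analysis stage on in-memory inputs
#'
#' The computational core of \code{\link{run_pipeline}}, usable directly
#' on a synthetic dataset from \code{\link{simulate_dataset}}: calls DEGs
#' and DE miRNAs, finds concordant sink genes, builds and splits the
#' responsive network, dissects modules, weights and selects hub TFs,
#' assembles the regulatory network, extracts the minimum-cost flow from
#' DE miRNAs to concordant genes, enumerates feedback loops and computes
#' gene-set enrichment.
#'
#' @param dataset an \code{altnet_dataset} or a list with the same
#'   elements (\code{study}, \code{mirna_study}, \code{interactome},
#'   \code{tf_targets}, \code{mirna_targets}, optional \code{genesets}).
#' @param deg_fdr,concordance_alpha,edge_p,mcl_inflation,hub_fraction,enrich_fdr,loop_max_len,B,flow,seed
#'   as in \code{\link{pipeline_config}}.
#' @return list of class \code{altnet_results} with elements \code{degs},
#'   \code{mirna_degs}, \code{concordant}, \code{arn}, \code{networks}
#'   (up/down), \code{modules} (up/down \code{module_set}s),
#'   \code{tf_weights}, \code{hub_tfs}, \code{frn}, \code{flow}
#'   (\code{flow_result} or NULL), \code{flow_ranks}, \code{loops},
#'   \code{enrichment}, \code{params}.
#' @export
analyze_dataset <- function(dataset,
                            deg_fdr = 0.1, concordance_alpha = 0.05,
                            edge_p = 0.1, mcl_inflation = 1.5,
                            hub_fraction = 0.10, enrich_fdr = 0.05,
                            loop_max_len = 5, B = 1000, flow = NULL,
                            seed = 1) {
  res <- list(params = list(
    deg_fdr = deg_fdr, concordance_alpha = concordance_alpha,
    edge_p = edge_p, mcl_inflation = mcl_inflation,
    hub_fraction = hub_fraction, enrich_fdr = enrich_fdr,
    loop_max_len = loop_max_len, B = B, flow = flow, seed = seed,
    stage_seeds = c(deg = sub_seed(seed, 21), mirna_deg = sub_seed(seed, 22),
                    concordance = sub_seed(seed, 23),
                    edge_null = sub_seed(seed, 24))))
  res$degs <- with_stage("diffexpr",
    call_degs(dataset$study, B = B, fdr_cutoff = deg_fdr,
              seed = sub_seed(seed, 21)))
  res$mirna_degs <- with_stage("diffexpr",
    call_degs(dataset$mirna_study, B = B, fdr_cutoff = deg_fdr,
              seed = sub_seed(seed, 22)))
  res$concordant <- with_stage("diffexpr",
    call_concordant(dataset$study, alpha = concordance_alpha, B = B,
                    seed = sub_seed(seed, 23)))
  res$arn <- with_stage("netbuild",
    build_arn(res$degs, dataset$interactome, dataset$study, B = B,
              p_cutoff = edge_p, seed = sub_seed(seed, 24)))
  res$networks <- with_stage("netbuild", split_updown(res$arn))
  res$modules <- with_stage("netmodules", list(
    up = dissect_modules(res$networks$up, inflation = mcl_inflation),
    down = dissect_modules(res$networks$down, inflation = mcl_inflation)))
  res$tf_weights <- with_stage("regulators",
    prestige_weights(dataset$tf_targets, res$degs))
  res$hub_tfs <- with_stage("regulators",
    select_hubs(res$tf_weights, hub_fraction))
  res$frn <- with_stage("regulators",
    build_frn(res$arn, res$hub_tfs, dataset$tf_targets,
              dataset$mirna_targets, res$tf_weights, res$mirna_degs))
  sinks <- intersect(c(res$concordant$up, res$concordant$down),
                     res$frn$nodes$node)
  sources <- intersect(
    res$mirna_degs$gene[res$mirna_degs$direction != "none"],
    res$frn$nodes$node)
  res$flow <- with_stage("flownet", {
    if (length(sources) > 0 && length(setdiff(sinks, sources)) > 0) {
      prob <- build_flow_problem(res$frn, sources, setdiff(sinks, sources),
                                 flow = flow %||% length(sinks))
      solve_min_cost_flow(prob, allow_shortfall = TRUE)
    } else NULL
  })
  res$flow_ranks <- if (!is.null(res$flow)) rank_flow_nodes(res$flow)
  res$loops <- with_stage("loops", {
    if (nrow(res$frn$reg_edges) > 0) {
      find_feedback_loops(res$frn, max_len = loop_max_len)
    } else structure(list(), class = "loop_set")
  })
  res$enrichment <- with_stage("enrichstats", {
    if (!is.null(dataset$genesets)) {
      universe <- rownames(dataset$study$matrix)
      degs_by_dir <- split(res$degs$gene, res$degs$direction)
      do.call(rbind, lapply(c("up", "down"), function(d) {
        q <- degs_by_dir[[d]]
        if (is.null(q) || length(q) == 0) return(NULL)
        tab <- fisher_enrichment(q, dataset$genesets, universe,
                                 fdr_cutoff = enrich_fdr)
        cbind(query = paste0("degs_", d), tab)
      }))
    } else NULL
  })
  class(res) <- "altnet_results"
  res
}

#' @export
print.altnet_results <- function(x, ...) {
  n_deg <- sum(x$degs$direction != "none")
  cat(sprintf(paste0(
    "altnet_results: %d DEGs (%d up, %d down); ARN %d nodes / %d edges;\n",
    "  %d + %d modules; %d hub TFs; flow value %s; %d feedback loop(s)\n"),
    n_deg, sum(x$degs$direction == "up"), sum(x$degs$direction == "down"),
    nrow(x$arn$nodes), nrow(x$arn$edges),
    length(x$modules$up$modules), length(x$modules$down$modules),
    length(x$hub_tfs),
    if (is.null(x$flow)) "none" else format(x$flow$flow),
    length(x$loops)))
  invisible(x)
}

#' Run the full pipeline from input files
#'
#' Reads the configured inputs, executes diffexpr, netbuild, netmodules,
#' regulators, flownet, loops and enrichstats in order, and writes every
#' stage's outputs plus a run log (effective thresholds, seed and
#' sub-seeds) to \code{out_dir}. Re-running with the same configuration
#' reproduces all outputs bit-identically. Any stage failure aborts with
#' the stage name and cause.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, the \code{altnet_results} list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- list(
    study = with_stage("diffexpr",
      read_expression(config$expression, config$samples)),
    mirna_study = with_stage("diffexpr",
      read_expression(config$mirna_expression, config$samples)),
    interactome = with_stage("netbuild", read_edge_list(config$interactome)),
    tf_targets = with_stage("regulators", read_edge_list(config$tf_targets)),
    mirna_targets = with_stage("regulators",
                               read_edge_list(config$mirna_targets)),
    genesets = if (!is.null(config$genesets)) {
      with_stage("enrichstats", read_gmt(config$genesets))
    })
  res <- analyze_dataset(
    dataset,
    deg_fdr = config$deg_fdr, concordance_alpha = config$concordance_alpha,
    edge_p = config$edge_p, mcl_inflation = config$mcl_inflation,
    hub_fraction = config$hub_fraction, enrich_fdr = config$enrich_fdr,
    loop_max_len = config$loop_max_len, B = config$B, flow = config$flow,
    seed = config$seed)
  write_results(res, config)
  invisible(res)
}

write_results <- function(res, config) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  p <- function(f) file.path(out, f)
  write_tsv(res$degs[, c("gene", "direction", "p", "fdr", "weight")],
            p("degs.tsv"))
  write_tsv(res$mirna_degs[, c("gene", "direction", "p", "fdr", "weight")],
            p("mirna_degs.tsv"))
  write_tsv(data.frame(
    gene = c(res$concordant$up, res$concordant$down),
    direction = rep(c("up", "down"),
                    c(length(res$concordant$up), length(res$concordant$down)))),
    p("concordant.tsv"))
  write_tsv(res$arn$edges, p("arn.tsv"))
  write_tsv(res$arn$nodes, p("nodes.tsv"))
  mod_rows <- do.call(rbind, lapply(c("up", "down"), function(d) {
    ms <- res$modules[[d]]$modules
    if (length(ms) == 0) return(NULL)
    data.frame(network = d,
               module = rep(names(ms), vapply(ms, length, integer(1))),
               gene = unlist(ms, use.names = FALSE))
  }))
  write_tsv(mod_rows %||% data.frame(network = character(0),
                                     module = character(0),
                                     gene = character(0)),
            p("modules.tsv"))
  jsonlite::write_json(
    lapply(res$modules,
           function(m) lapply(m$modules, length)),
    p("modules_summary.json"), auto_unbox = TRUE)
  write_tsv(data.frame(tf = names(res$tf_weights),
                       weight = unname(res$tf_weights),
                       hub = names(res$tf_weights) %in% res$hub_tfs),
            p("tf_weights.tsv"))
  frn_edges <- rbind(
    data.frame(source = res$frn$base$edges$from,
               target = res$frn$base$edges$to, type = "functional",
               weight = res$frn$base$edges$weight),
    data.frame(source = res$frn$reg_edges$from,
               target = res$frn$reg_edges$to, type = res$frn$reg_edges$type,
               weight = res$frn$reg_edges$weight))
  write_tsv(frn_edges, p("frn_edges.tsv"))
  if (!is.null(res$flow)) {
    write_tsv(res$flow$edges, p("flow_edges.tsv"))
    write_tsv(res$flow$nodes, p("flow_nodes.tsv"))
    write_flow_dot(res$flow, p("flow.dot"))
  }
  write_tsv(data.frame(
    loop = rep(seq_along(res$loops),
               vapply(res$loops, length, integer(1))),
    member = unlist(res$loops) %||% character(0)),
    p("loops.tsv"))
  if (!is.null(res$enrichment)) write_tsv(res$enrichment, p("enrichment.tsv"))
  jsonlite::write_json(res$params, p("run_log.json"), auto_unbox = TRUE)
  invisible(out)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of \code{\link{pipeline_config}}.
#'
#' @param path YAML file.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
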