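# Synthetic-data generators with planted ground truth.
#
# The generators emulate the study design that motivates the package: a
# handful of individuals sampled under a "low" and a "high" condition, with
# large between-individual baselines at the low condition, a shared planted
# response at the high condition, planted dense interactome modules, and a
# planted miRNA -> TF -> gene regulatory cascade. Everything is a pure
# function of the master seed.

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the motivating study design: 4 individuals with 2 low-
#' and 2 high-condition samples each, except the last individual who has a
#' single low-condition sample (15 samples in total); a planted response of
#' 2 log2 units against residual noise of 0.5; five planted interactome
#' modules of 20 genes carved from the planted up- and down-regulated
#' genes; and a planted miRNA -> TF -> gene cascade.
#'
#' @param n_genes,n_mirnas number of genes / miRNAs measured.
#' @param individuals number of individuals.
#' @param samples_per_condition optional data.frame with columns
#'   \code{individual}, \code{low}, \code{high} giving per-individual sample
#'   counts; the default is 2/2 with the last individual reduced to one
#'   low-condition sample.
#' @param n_de_up,n_de_down number of planted up-/down-regulated genes.
#' @param effect_size log2-scale mean shift of planted genes in
#'   high-condition columns (0 gives a null study).
#' @param indiv_sd SD of the per-gene, per-individual baseline offsets
#'   (between-individual variation at the low condition).
#' @param noise_sd residual SD of a single measurement.
#' @param high_noise_shrink factor in (0, 1] multiplying the residual noise
#'   SD in high-condition columns (the uniformity of profiles at the high
#'   condition).
#' @param baseline_mean,baseline_sd per-gene baseline expression
#'   distribution (log2 units).
#' @param n_modules,module_size planted module count and size; modules are
#'   carved from the planted DE genes and never mix directions.
#' @param p_in,p_out interactome edge probability within / outside planted
#'   modules; \code{p_in > p_out} is required.
#' @param n_de_mirnas,mirna_effect_size planted differentially expressed
#'   miRNAs and their shift.
#' @param n_tfs number of transcription-factor regulators.
#' @param targets_per_tf,mirna_targets_per_mirna nominal out-degrees of the
#'   regulator maps.
#' @param mirna_tf_bias probability that a decoy miRNA target is a TF
#'   rather than a gene (miRNAs predominantly target TFs).
#' @param de_target_bias probability that an extra target of the planted
#'   cascade TF is a planted DE gene.
#' @param decoy_density multiplier on all decoy regulator edges; 0 leaves
#'   only the planted cascade.
#' @param cascade_length number of nodes in the planted cascade
#'   (miRNA, TFs..., gene); at least 2.
#' @param confidence_range range of interactome edge confidences.
#' @param seed master seed; sub-seeds for the individual generators are
#'   derived from it by fixed offsets.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 2000, n_mirnas = 100,
                             individuals = 4,
                             samples_per_condition = NULL,
                             n_de_up = 60, n_de_down = 40,
                             effect_size = 2,
                             indiv_sd = 1, noise_sd = 0.5,
                             high_noise_shrink = 0.3,
                             baseline_mean = 8, baseline_sd = 2,
                             n_modules = 5, module_size = 20,
                             p_in = 0.8, p_out = 0.02,
                             n_de_mirnas = 8, mirna_effect_size = 2,
                             n_tfs = 30,
                             targets_per_tf = 12,
                             mirna_targets_per_mirna = 8,
                             mirna_tf_bias = 0.7,
                             de_target_bias = 0.8,
                             decoy_density = 1,
                             cascade_length = 3,
                             confidence_range = c(0.4, 1),
                             seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_genes = n_genes, n_mirnas = n_mirnas,
              individuals = individuals, n_tfs = n_tfs,
              n_modules = n_modules, module_size = module_size)
  assert_that(all(counts > 0) && all(counts == round(counts)),
              "all counts must be positive integers")
  assert_that(n_de_up >= 0 && n_de_down >= 0 && n_de_up + n_de_down <= n_genes,
              "planted DE counts must be non-negative and fit in n_genes")
  assert_that(effect_size >= 0, "effect_size must be >= 0")
  assert_that(p_in > p_out && p_in <= 1 && p_out >= 0,
              "p_in must exceed p_out")
  assert_that(high_noise_shrink > 0 && high_noise_shrink <= 1,
              "high_noise_shrink must be in (0, 1]")
  assert_that(cascade_length >= 2, "cascade_length must be at least 2")
  assert_that(decoy_density >= 0, "decoy_density must be >= 0")
  n_up_mod <- min(n_modules, n_de_up %/% module_size)
  assert_that(n_up_mod + n_de_down %/% module_size >= n_modules,
              "planted DE genes cannot fill n_modules modules of module_size")
  if (is.null(cfg$samples_per_condition)) {
    spc <- data.frame(individual = paste0("I", seq_len(individuals)),
                      low = rep(2L, individuals),
                      high = rep(2L, individuals))
    spc$low[individuals] <- 1L  # mirrors the individual with a missing sample
    cfg$samples_per_condition <- spc
  } else {
    spc <- cfg$samples_per_condition
    assert_that(all(c("individual", "low", "high") %in% names(spc)) &&
                  all(spc$low >= 1) && all(spc$high >= 1),
                "samples_per_condition needs >=1 sample per condition")
  }
  structure(cfg, class = "synthetic_config")
}

gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))
mirna_ids <- function(cfg) sprintf("miR%03d", seq_len(cfg$n_mirnas))
tf_ids <- function(cfg) sprintf("TF%02d", seq_len(cfg$n_tfs))

# Draw the planted truth (DE genes, modules, DE miRNAs, cascade) as a pure
# function of the master seed. Shared by all generators so that they agree
# without passing state around.
plant_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(sub_seed(cfg$seed, 0), {
    genes <- gene_ids(cfg)
    mirnas <- mirna_ids(cfg)
    tfs <- tf_ids(cfg)
    de <- sample(genes, cfg$n_de_up + cfg$n_de_down)
    de_up <- sort(de[seq_len(cfg$n_de_up)])
    de_down <- sort(de[-seq_len(cfg$n_de_up)])
    # modules: fill with up-regulated genes first, then down-regulated;
    # a module never mixes directions
    n_up_mod <- min(cfg$n_modules, cfg$n_de_up %/% cfg$module_size)
    assign_pool <- function(pool, n_mod, offset) {
      picked <- sample(pool, n_mod * cfg$module_size)
      setNames(rep(sprintf("M%d", offset + seq_len(n_mod)),
                   each = cfg$module_size), picked)
    }
    module_assignments <- c(
      if (n_up_mod > 0) assign_pool(de_up, n_up_mod, 0),
      if (cfg$n_modules - n_up_mod > 0)
        assign_pool(de_down, cfg$n_modules - n_up_mod, n_up_mod))
    n_dm <- min(cfg$n_de_mirnas, cfg$n_mirnas)
    de_mirnas <- sample(mirnas, n_dm)
    mirna_direction <- setNames(
      rep(c("up", "down"), length.out = n_dm), de_mirnas)
    # cascade: miRNA -> TF [-> TF ...] -> planted module gene
    n_mid <- cfg$cascade_length - 2L
    cascade_nodes <- c(de_mirnas[1],
                       if (n_mid > 0) sample(tfs, n_mid),
                       sample(names(module_assignments)[
                         names(module_assignments) %in% de_up], 1))
    cascade_edges <- data.frame(from = head(cascade_nodes, -1),
                                to = cascade_nodes[-1],
                                stringsAsFactors = FALSE)
    structure(list(de_up = de_up, de_down = de_down,
                   module_assignments = module_assignments,
                   de_mirnas = de_mirnas,
                   mirna_direction = mirna_direction,
                   cascade_nodes = cascade_nodes,
                   cascade_edges = cascade_edges,
                   concordant_genes = sort(c(de_up, de_down))),
              class = "planted_truth")
  })
}

build_sample_sheet <- function(cfg) {
  spc <- cfg$samples_per_condition
  rows <- lapply(seq_len(nrow(spc)), function(i) {
    ind <- spc$individual[i]
    data.frame(
      sample = c(sprintf("%s_low_%d", ind, seq_len(spc$low[i])),
                 sprintf("%s_high_%d", ind, seq_len(spc$high[i]))),
      individual = ind,
      condition = c(rep("low", spc$low[i]), rep("high", spc$high[i])),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

simulate_matrix <- function(cfg, ids, up, down, effect, seed_offset) {
  sheet <- build_sample_sheet(cfg)
  n <- length(ids)
  with_seed(sub_seed(cfg$seed, seed_offset), {
    baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    inds <- unique(sheet$individual)
    offsets <- matrix(rnorm(n * length(inds), 0, cfg$indiv_sd),
                      n, length(inds), dimnames = list(ids, inds))
    m <- matrix(0, n, nrow(sheet), dimnames = list(ids, sheet$sample))
    for (j in seq_len(nrow(sheet))) {
      hi <- sheet$condition[j] == "high"
      noise_sd <- cfg$noise_sd * if (hi) cfg$high_noise_shrink else 1
      m[, j] <- baseline + offsets[, sheet$individual[j]] +
        rnorm(n, 0, noise_sd)
      if (hi) {
        m[up, j] <- m[up, j] + effect
        m[down, j] <- m[down, j] - effect
      }
    }
    expression_study(m, sheet)
  })
}

#' Generate a synthetic gene expression study with planted truth
#'
#' Produces a log2-scale gene-by-sample matrix following the configured
#' design: per-gene baselines, per-gene/per-individual offsets added to all
#' of an individual's columns, residual noise shrunk by
#' \code{high_noise_shrink} in high-condition columns, and planted up/down
#' genes shifted by \eqn{\pm}\code{effect_size} in every high-condition
#' column.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return A list with elements \code{study}
#'   (\code{\link{expression_study}}) and \code{truth} (planted truth:
#'   \code{de_up}, \code{de_down}, \code{module_assignments},
#'   \code{cascade_edges}, \code{concordant_genes}, ...).
#' @examples
#' cfg <- synthetic_config(n_genes = 100, n_de_up = 5, n_de_down = 5,
#'                         n_modules = 1, module_size = 5, seed = 1)
#' gs <- generate_study(cfg)
#' dim(gs$study$matrix)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- plant_truth(config)
  study <- simulate_matrix(config, gene_ids(config),
                           truth$de_up, truth$de_down,
                           config$effect_size, seed_offset = 1)
  list(study = study, truth = truth)
}

#' Generate the matching synthetic miRNA expression study
#'
#' Same sample design and noise model as \code{\link{generate_study}}, with
#' the planted differentially expressed miRNAs shifted by
#' \code{mirna_effect_size} in the direction recorded in the planted truth.
#'
#' @inheritParams generate_study
#' @return A list with elements \code{study} and \code{truth}.
#' @export
generate_mirna_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- plant_truth(config)
  up <- names(truth$mirna_direction)[truth$mirna_direction == "up"]
  down <- names(truth$mirna_direction)[truth$mirna_direction == "down"]
  study <- simulate_matrix(config, mirna_ids(config), up, down,
                           config$mirna_effect_size, seed_offset = 4)
  list(study = study, truth = truth)
}

# Decode pair indices k in 1..choose(n,2) (ordered by first endpoint) into
# (i, j) with i < j.
decode_pairs <- function(k, n) {
  cum <- c(0, cumsum(n - seq_len(n - 1)))
  i <- findInterval(k - 0.5, cum)
  j <- i + (k - cum[i])
  cbind(i, j)
}

#' Generate a synthetic functional interactome with planted modules
#'
#' Planted modules are Erdős–Rényi-dense internally (\code{p_in}) and all
#' other gene pairs are connected sparsely (\code{p_out}). Edge confidences
#' are drawn uniformly from \code{confidence_range}; there are no
#' self-loops and no duplicate undirected edges.
#'
#' @inheritParams generate_study
#' @return data.frame with columns \code{from}, \code{to},
#'   \code{confidence} (undirected edges, \code{from < to}).
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- plant_truth(config)
  genes <- gene_ids(config)
  n <- length(genes)
  mod_of <- setNames(rep(NA_character_, n), genes)
  mod_of[names(truth$module_assignments)] <- truth$module_assignments
  with_seed(sub_seed(config$seed, 2), {
    # background edges over all pairs
    total_pairs <- n * (n - 1) / 2
    m_bg <- rbinom(1, total_pairs, config$p_out)
    bg <- if (m_bg > 0) {
      pr <- decode_pairs(sort(sample(total_pairs, m_bg)), n)
      same_mod <- !is.na(mod_of[pr[, 1]]) & !is.na(mod_of[pr[, 2]]) &
        mod_of[pr[, 1]] == mod_of[pr[, 2]]
      pr[!same_mod, , drop = FALSE]
    } else matrix(integer(0), 0, 2)
    # dense edges inside each planted module
    within <- lapply(split(match(names(mod_of)[!is.na(mod_of)], genes),
                           mod_of[!is.na(mod_of)]), function(idx) {
      idx <- sort(idx)
      pr <- t(utils::combn(idx, 2))
      pr[runif(nrow(pr)) < config$p_in, , drop = FALSE]
    })
    pr <- rbind(bg, do.call(rbind, within))
    data.frame(from = genes[pr[, 1]], to = genes[pr[, 2]],
               confidence = runif(nrow(pr), config$confidence_range[1],
                                  config$confidence_range[2]),
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic TF-target and miRNA-target regulator maps
#'
#' Always contains the planted cascade (miRNA \eqn{\to} TF \eqn{\to} planted
#' gene). Decoy edges are added on top: every TF receives
#' \code{targets_per_tf * decoy_density} random gene targets (the cascade TF
#' draws its extra targets mostly from planted DE genes, which is what makes
#' it a genuine hub), and every miRNA receives
#' \code{mirna_targets_per_mirna * decoy_density} targets that are TFs with
#' probability \code{mirna_tf_bias} and genes otherwise.
#'
#' @inheritParams generate_study
#' @param truth optionally, a planted truth already obtained from
#'   \code{\link{generate_study}}; regenerated from the seed when missing.
#' @return list with \code{tf_targets} and \code{mirna_targets}
#'   (data.frames \code{from}, \code{to}, \code{confidence}) and the
#'   \code{truth}.
#' @export
generate_regulators <- function(config, truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_that(config$cascade_length >= 2, "cascade_length must be >= 2")
  truth <- truth %||% plant_truth(config)
  genes <- gene_ids(config)
  tfs <- tf_ids(config)
  mirnas <- mirna_ids(config)
  de_genes <- c(truth$de_up, truth$de_down)
  casc <- truth$cascade_edges
  cascade_tfs <- intersect(truth$cascade_nodes, tfs)
  with_seed(sub_seed(config$seed, 3), {
    n_extra_tf <- round(max(config$targets_per_tf - 1, 0) *
                          config$decoy_density)
    n_tf <- round(config$targets_per_tf * config$decoy_density)
    tf_edges <- lapply(tfs, function(tf) {
      planted <- casc$to[casc$from == tf]
      if (tf %in% cascade_tfs) {
        k <- n_extra_tf
        pool_de <- runif(k) < config$de_target_bias
        extra <- c(sample(setdiff(de_genes, planted), sum(pool_de)),
                   sample(setdiff(genes, de_genes), k - sum(pool_de)))
      } else {
        extra <- if (n_tf > 0) sample(genes, n_tf) else character(0)
      }
      tg <- unique(c(planted, extra))
      if (length(tg) == 0) return(NULL)
      data.frame(from = tf, to = tg, stringsAsFactors = FALSE)
    })
    n_mir <- round(config$mirna_targets_per_mirna * config$decoy_density)
    mir_edges <- lapply(mirnas, function(mi) {
      planted <- casc$to[casc$from == mi]
      extra <- if (n_mir > 0) {
        is_tf <- runif(n_mir) < config$mirna_tf_bias
        c(sample(tfs, min(sum(is_tf), length(tfs))),
          sample(genes, n_mir - sum(is_tf)))
      } else character(0)
      tg <- unique(c(planted, setdiff(extra, planted)))
      if (length(tg) == 0) return(NULL)
      data.frame(from = mi, to = tg, stringsAsFactors = FALSE)
    })
    finish <- function(lst) {
      df <- do.call(rbind, lst)
      if (is.null(df)) df <- data.frame(from = character(0), to = character(0))
      df$confidence <- runif(nrow(df), 0.5, 1)
      df
    }
    list(tf_targets = finish(tf_edges), mirna_targets = finish(mir_edges),
         truth = truth)
  })
}

#' Generate synthetic gene-set annotations
#'
#' One set per planted module (the module's genes plus 30% random extras),
#' plus random decoy sets, so enrichment statistics have signal to find.
#'
#' @inheritParams generate_regulators
#' @param n_random_sets,random_set_size decoy sets.
#' @return A \code{geneset_collection} (see \code{\link{read_gmt}}).
#' @export
generate_genesets <- function(config, truth = NULL, n_random_sets = 10,
                              random_set_size = 30) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- truth %||% plant_truth(config)
  genes <- gene_ids(config)
  with_seed(sub_seed(config$seed, 5), {
    mods <- split(names(truth$module_assignments), truth$module_assignments)
    sets <- lapply(mods, function(g) {
      unique(c(g, sample(setdiff(genes, g), round(0.3 * length(g)))))
    })
    names(sets) <- paste0("SET_", names(mods))
    rnd <- lapply(seq_len(n_random_sets),
                  function(i) sample(genes, random_set_size))
    names(rnd) <- sprintf("SET_RND%02d", seq_len(n_random_sets))
    sets <- c(sets, rnd)
    geneset_collection(sets, descriptions = setNames(
      c(paste("planted module", names(mods)),
        rep("random decoy set", n_random_sets)), names(sets)))
  })
}

#' Generate a complete synthetic dataset
#'
#' Bundles the gene study, miRNA study, interactome, regulator maps,
#' gene-set annotations and the planted truth into one object; the input of
#' \code{\link{run_pipeline}} smoke tests and of \code{\link{write_fixtures}}.
#'
#' @inheritParams generate_study
#' @return list of class \code{altnet_dataset}.
#' @export
simulate_dataset <- function(config) {
  gs <- generate_study(config)
  ms <- generate_mirna_study(config)
  reg <- generate_regulators(config, gs$truth)
  structure(list(config = config,
                 truth = gs$truth,
                 study = gs$study,
                 mirna_study = ms$study,
                 interactome = generate_interactome(config),
                 tf_targets = reg$tf_targets,
                 mirna_targets = reg$mirna_targets,
                 genesets = generate_genesets(config, gs$truth)),
            class = "altnet_dataset")
}

#' Write a synthetic dataset to plain-text fixture files
#'
#' Emits \code{expression.tsv}, \code{mirna_expression.tsv},
#' \code{samples.tsv}, \code{interactome.tsv}, \code{tf_targets.tsv},
#' \code{mirna_targets.tsv}, \code{sets.gmt} and \code{truth.json} (all
#' tab-separated with header rows, UTF-8).
#'
#' @param dataset an \code{altnet_dataset} from \code{\link{simulate_dataset}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(dataset, dir) {
  stopifnot(inherits(dataset, "altnet_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  write_expression(dataset$study, path("expression.tsv"))
  write_expression(dataset$mirna_study, path("mirna_expression.tsv"))
  write_tsv(dataset$study$samples, path("samples.tsv"))
  write_tsv(dataset$interactome, path("interactome.tsv"))
  write_tsv(dataset$tf_targets, path("tf_targets.tsv"))
  write_tsv(dataset$mirna_targets, path("mirna_targets.tsv"))
  write_gmt(dataset$genesets, path("sets.gmt"))
  truth <- dataset$truth
  truth$module_assignments <- as.list(truth$module_assignments)
  truth$mirna_direction <- as.list(truth$mirna_direction)
  jsonlite::write_json(unclass(truth), path("truth.json"), auto_unbox = TRUE)
  invisible(setNames(path(c("expression.tsv", "mirna_expression.tsv",
                            "samples.tsv", "interactome.tsv",
                            "tf_targets.tsv", "mirna_targets.tsv",
                            "sets.gmt", "truth.json")),
                     c("expression", "mirna_expression", "samples",
                       "interactome", "tf_targets", "mirna_targets",
                       "sets", "truth")))
}
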