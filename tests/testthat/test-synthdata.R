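test_that("synthetic_config validates its inputs", {
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.5), "p_in")
  expect_error(synthetic_config(n_genes = 10, n_de_up = 20), "fit in")
  expect_error(synthetic_config(high_noise_shrink = 0), "high_noise_shrink")
  expect_error(synthetic_config(n_modules = 10, module_size = 50),
               "cannot fill")
  expect_error(synthetic_config(cascade_length = 1), "cascade_length")
})

test_that("the default design has 15 samples, one individual short a low", {
  cfg <- synthetic_config()
  sheet <- generate_study(cfg)$study$samples
  expect_equal(nrow(sheet), 15)
  tab <- table(sheet$individual, sheet$condition)
  expect_equal(unname(tab["I4", "low"]), 1)
  expect_true(all(tab[1:3, ] == 2))
})

test_that("generators are pure functions of the seed", {
  cfg <- small_config(seed = 3)
  expect_identical(generate_study(cfg), generate_study(cfg))
  expect_identical(generate_interactome(cfg), generate_interactome(cfg))
  expect_identical(generate_regulators(cfg), generate_regulators(cfg))
  other <- generate_study(small_config(seed = 4))
  expect_false(identical(generate_study(cfg)$study$matrix,
                         other$study$matrix))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  expected <- runif(1)
  set.seed(123)
  invisible(generate_study(small_config(seed = 5)))
  expect_equal(runif(1), expected)
})

test_that("planted truth has the configured structure", {
  cfg <- synthetic_config()
  tr <- generate_study(cfg)$truth
  expect_length(tr$de_up, 60)
  expect_length(tr$de_down, 40)
  expect_length(intersect(tr$de_up, tr$de_down), 0)
  # modules never mix directions
  mods <- split(names(tr$module_assignments), tr$module_assignments)
  expect_length(mods, 5)
  for (m in mods) {
    expect_equal(length(m), 20)
    expect_true(all(m %in% tr$de_up) || all(m %in% tr$de_down))
  }
  # cascade is miRNA -> TF -> planted up-regulated gene
  expect_length(tr$cascade_nodes, 3)
  expect_match(tr$cascade_nodes[1], "^miR")
  expect_match(tr$cascade_nodes[2], "^TF")
  expect_true(tr$cascade_nodes[3] %in% tr$de_up)
  expect_equal(tr$cascade_edges$from, tr$cascade_nodes[1:2])
  expect_equal(tr$cascade_edges$to, tr$cascade_nodes[2:3])
})

test_that("planted genes shift by the effect size in high columns only", {
  cfg <- small_config(seed = 11)
  gs <- generate_study(cfg)
  m <- gs$study$matrix
  sheet <- gs$study$samples
  hi <- sheet$sample[sheet$condition == "high"]
  lo <- sheet$sample[sheet$condition == "low"]
  shift <- rowMeans(m[, hi]) - rowMeans(m[, lo])
  expect_gt(min(shift[gs$truth$de_up]), 1)     # planted +2 against noise
  expect_lt(max(shift[gs$truth$de_down]), -1)  # planted -2
  neutral <- setdiff(rownames(m), c(gs$truth$de_up, gs$truth$de_down))
  expect_lt(max(abs(shift[neutral])), 1.9)
  expect_lt(abs(mean(shift[neutral])), 0.3)
})

test_that("a zero effect size yields a null study", {
  cfg <- small_config(seed = 12, effect_size = 0)
  gs <- generate_study(cfg)
  m <- gs$study$matrix
  sheet <- gs$study$samples
  shift <- rowMeans(m[, sheet$condition == "high"]) -
    rowMeans(m[, sheet$condition == "low"])
  expect_lt(abs(mean(shift[gs$truth$de_up])), 0.5)
})

test_that("the interactome is a simple undirected graph, dense in modules", {
  cfg <- small_config(seed = 13)
  net <- generate_interactome(cfg)
  expect_true(all(net$from < net$to))
  expect_false(any(duplicated(paste(net$from, net$to))))
  expect_true(all(net$confidence >= cfg$confidence_range[1] &
                    net$confidence <= cfg$confidence_range[2]))
  tr <- generate_study(cfg)$truth
  mods <- split(names(tr$module_assignments), tr$module_assignments)
  key <- paste(net$from, net$to)
  in_density <- sapply(mods, function(g) {
    pairs <- t(combn(sort(g), 2))
    mean(paste(pairs[, 1], pairs[, 2]) %in% key)
  })
  expect_true(all(in_density > 0.5))                     # p_in = 0.8
  expect_lt(nrow(net) / choose(cfg$n_genes, 2), 0.06)   # p_out = 0.02
})

test_that("regulator maps always contain the cascade; decoys scale", {
  cfg <- small_config(seed = 14)
  reg <- generate_regulators(cfg)
  tr <- reg$truth
  casc <- tr$cascade_edges
  mir_keys <- paste(reg$mirna_targets$from, reg$mirna_targets$to)
  tf_keys <- paste(reg$tf_targets$from, reg$tf_targets$to)
  expect_true(paste(casc$from[1], casc$to[1]) %in% mir_keys)
  expect_true(paste(casc$from[2], casc$to[2]) %in% tf_keys)
  expect_true(all(reg$tf_targets$confidence > 0 &
                    reg$tf_targets$confidence <= 1))
  bare <- generate_regulators(small_config(seed = 14, decoy_density = 0))
  expect_equal(nrow(bare$tf_targets), 1)   # only the cascade TF edge
  expect_equal(nrow(bare$mirna_targets), 1)
  dense <- generate_regulators(small_config(seed = 14, decoy_density = 2))
  expect_gt(nrow(dense$tf_targets), nrow(reg$tf_targets))
})

test_that("gene sets cover planted modules plus decoys", {
  cfg <- small_config(seed = 15)
  sets <- generate_genesets(cfg)
  tr <- generate_study(cfg)$truth
  mods <- split(names(tr$module_assignments), tr$module_assignments)
  for (nm in names(mods)) {
    expect_true(all(mods[[nm]] %in% sets$sets[[paste0("SET_", nm)]]))
  }
  expect_length(grep("^SET_RND", names(sets$sets)), 10)
})

test_that("fixtures round-trip through the plain-text formats", {
  dir <- tempfile("fixtures")
  ds <- simulate_dataset(small_config(seed = 16))
  paths <- write_fixtures(ds, dir)
  expect_true(all(file.exists(paths)))
  st <- read_expression(paths["expression"], paths["samples"])
  expect_equal(st$matrix, ds$study$matrix, tolerance = 1e-4)
  expect_equal(st$samples$individual, ds$study$samples$individual)
  gmt <- read_gmt(paths["sets"])
  expect_equal(gmt$sets, ds$genesets$sets)
  net <- read_edge_list(paths["interactome"])
  expect_equal(net$from, ds$interactome$from)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(unlist(truth$de_up), ds$truth$de_up)
  unlink(dir, recursive = TRUE)
})
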