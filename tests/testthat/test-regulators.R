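toy_degset <- function(genes, weights, directions) {
  structure(data.frame(gene = genes, direction = directions,
                       weight = weights, stringsAsFactors = FALSE),
            class = c("degset", "data.frame"))
}

test_that("prestige centrality sums confidence-weighted DEG target weights", {
  degs <- toy_degset(c("g1", "g2", "g3"), c(0.8, -0.5, 0.9),
                     c("up", "down", "none"))
  map <- data.frame(from = c("T1", "T1", "T2", "T2", "T3"),
                    to = c("g1", "g2", "g3", "g1", "gX"),
                    confidence = c(1, 0.5, 1, 0.25, 1))
  w <- prestige_weights(map, degs)
  expect_equal(w[["T1"]], 1 * 0.8 + 0.5 * 0.5)  # |weights| of DEG targets
  expect_equal(w[["T2"]], 0.25 * 0.8)           # g3 is not a DEG
  expect_equal(w[["T3"]], 0)                    # unknown target
  # confidence defaults to 1
  w2 <- prestige_weights(map[, c("from", "to")], degs)
  expect_equal(w2[["T1"]], 0.8 + 0.5)
})

test_that("the iterative variant adds inherited prestige and converges", {
  degs <- toy_degset(c("g1", "g2"), c(1, 0.5), c("up", "up"))
  map <- data.frame(from = c("T1", "T2", "T2"), to = c("g1", "T1", "g2"),
                    confidence = 1)
  base <- prestige_weights(map, degs)
  iter <- prestige_weights(map, degs, iterative = TRUE)
  expect_equal(base[["T2"]], 0.5)
  # T2 regulates T1 (score 1), inheriting 0.85 * 1/2 on top of its base
  expect_equal(iter[["T2"]], 0.5 + 0.85 * 0.5 * iter[["T1"]])
  expect_equal(iter[["T1"]], base[["T1"]])
  expect_true(all(iter >= base - 1e-12))
  expect_identical(iter, prestige_weights(map, degs, iterative = TRUE))
})

test_that("hub selection takes the top decile with deterministic ties", {
  scores <- setNames(runif(335), sprintf("TF%03d", 1:335))
  expect_length(select_hubs(scores), 34)  # ceiling(0.1 * 335)
  tied <- setNames(c(1, 1, 1, 0), c("b", "a", "c", "d"))
  expect_equal(select_hubs(tied, 0.5), c("a", "b"))
  expect_equal(select_hubs(tied, 0.25), "a")
  expect_error(select_hubs(tied, 0), "fraction")
  expect_error(select_hubs(numeric(0)), "at least one")
})

make_small_frn <- function() {
  arn <- weighted_network(
    data.frame(gene = c("g1", "g2", "g3"), weight = c(0.9, -0.6, 0.3),
               direction = c("up", "down", "up")),
    data.frame(from = c("g1", "g2"), to = c("g2", "g3"),
               weight = c(0.5, 0.2)))
  tf_map <- data.frame(from = c("T1", "T1", "T2"),
                       to = c("g1", "g9", "g2"), confidence = c(0.8, 1, 1))
  mir_map <- data.frame(from = c("m1", "m1", "m2"),
                        to = c("T1", "g3", "g1"), confidence = 1)
  mir_degs <- toy_degset(c("m1", "m2"), c(1, -0.4), c("up", "none"))
  list(arn = arn, tf_map = tf_map, mir_map = mir_map, mir_degs = mir_degs)
}

test_that("the FRN layers directed regulator edges onto the ARN", {
  x <- make_small_frn()
  frn <- build_frn(x$arn, hub_tfs = "T1", tf_targets = x$tf_map,
                   mirna_targets = x$mir_map,
                   tf_weights = c(T1 = 2, T2 = 1),
                   mirna_degs = x$mir_degs)
  expect_s3_class(frn, "regulatory_network")
  # only hub TFs and DE miRNAs regulate; targets stay inside ARN + hubs
  expect_setequal(unique(frn$reg_edges$from), c("T1", "m1"))
  expect_false("g9" %in% frn$reg_edges$to)
  expect_false("m2" %in% frn$reg_edges$from)  # not differentially expressed
  # hub weights are rescaled to max 1: T1 weight becomes 1
  tf_edge <- frn$reg_edges[frn$reg_edges$from == "T1" &
                             frn$reg_edges$to == "g1", ]
  expect_equal(tf_edge$weight, 0.8 * (1 + 0.9) / 2)
  mir_tf <- frn$reg_edges[frn$reg_edges$from == "m1" &
                            frn$reg_edges$to == "T1", ]
  expect_equal(nrow(mir_tf), 1)   # miRNAs may target hub TFs
  expect_setequal(frn$nodes$node, c("g1", "g2", "g3", "T1", "m1"))
  expect_equal(frn$nodes$type[frn$nodes$node == "T1"], "tf")
  expect_equal(frn$nodes$type[frn$nodes$node == "m1"], "mirna")
})

test_that("the anticorrelation filter keeps only opposed miRNA targets", {
  x <- make_small_frn()
  mk_study <- function(rows) {
    colnames(rows) <- paste0("s", 1:4)
    sheet <- data.frame(sample = paste0("s", 1:4),
                        individual = c("A", "A", "B", "B"),
                        condition = c("low", "high", "low", "high"))
    expression_study(rows, sheet)
  }
  gstudy <- mk_study(rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1),
                           g3 = c(0, 1, 0, 1)))
  mstudy <- mk_study(rbind(m1 = c(4, 3, 2, 1), m2 = c(1, 2, 3, 4)))
  frn <- build_frn(x$arn, hub_tfs = character(0),
                   tf_targets = x$tf_map[0, ],
                   mirna_targets = data.frame(
                     from = c("m1", "m1"), to = c("g1", "g2"),
                     confidence = 1),
                   tf_weights = numeric(0), mirna_degs = x$mir_degs,
                   anticorrelation_only = TRUE,
                   study = gstudy, mirna_study = mstudy)
  # m1 falls with g1 rising (kept) and with g2 falling (dropped)
  expect_equal(frn$reg_edges$to, "g1")
  expect_error(build_frn(x$arn, character(0), x$tf_map[0, ],
                         x$mir_map, numeric(0), x$mir_degs,
                         anticorrelation_only = TRUE),
               "both expression studies")
})

test_that("the annotation curve reports top-slice annotated fractions", {
  scores <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1),
                     paste0("r", 1:10))
  annotated <- c("r1", "r2", "r5")
  curve <- weight_rank_annotation_curve(scores, annotated,
                                        percents = c(10, 20, 50, 100))
  expect_equal(unname(curve), c(1, 1, 3 / 5, 3 / 10))
  expect_named(curve, c("top10%", "top20%", "top50%", "top100%"))
  expect_error(weight_rank_annotation_curve(numeric(0), "x"), "non-empty")
})
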