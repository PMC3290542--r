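make_tiny_study <- function(values) {
  sheet <- data.frame(sample = c("A_l1", "A_l2", "A_h1", "A_h2",
                                 "B_l1", "B_h1"),
                      individual = c("A", "A", "A", "A", "B", "B"),
                      condition = c("low", "low", "high", "high",
                                    "low", "high"),
                      stringsAsFactors = FALSE)
  expression_study(values, sheet)
}

test_that("pairwise fold changes form every within-individual pair", {
  m <- matrix(0, 2, 6, dimnames = list(c("g1", "g2"),
                                       c("A_l1", "A_l2", "A_h1", "A_h2",
                                         "B_l1", "B_h1")))
  m["g1", ] <- c(1, 2, 5, 7, 10, 13)
  m["g2", ] <- c(0, 0, 1, 1, 2, 2)
  st <- make_tiny_study(m)
  fc <- pairwise_fold_changes(st)
  expect_equal(ncol(fc), 2 * 2 + 1)  # 4 pairs for A, 1 for B
  expect_equal(attr(fc, "individual"), c(rep("A", 4), "B"))
  expect_equal(fc["g1", "A_h1.vs.A_l1"], 4)
  expect_equal(fc["g1", "A_h2.vs.A_l2"], 5)
  expect_equal(fc["g1", "B_h1.vs.B_l1"], 3)
  expect_equal(fc["g2", "B_h1.vs.B_l1"], 0)
})

test_that("the default design yields 14 comparisons", {
  st <- generate_study(synthetic_config(n_genes = 50, n_de_up = 5,
                                        n_de_down = 5, n_modules = 1,
                                        module_size = 5, seed = 2))$study
  expect_equal(ncol(pairwise_fold_changes(st)), 14)  # 4 + 4 + 4 + 2
})

test_that("rank product is the geometric mean of per-comparison ranks", {
  fc <- cbind(c1 = c(2, 1, -1), c2 = c(1.5, 0.2, -0.5))
  rownames(fc) <- paste0("g", 1:3)
  expect_equal(rank_product(fc, "up"),
               c(g1 = 1, g2 = 2, g3 = 3))
  expect_equal(rank_product(fc, "down"),
               c(g1 = 3, g2 = 2, g3 = 1))
  # average ranks on ties
  fc2 <- cbind(c(1, 1, 0))
  rownames(fc2) <- paste0("g", 1:3)
  expect_equal(unname(rank_product(fc2, "up")), c(1.5, 1.5, 3))
})

test_that("rank product is invariant to monotone per-comparison rescaling", {
  set.seed(8)
  fc <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), NULL))
  fc2 <- fc
  fc2[, 1] <- 10 * fc2[, 1] + 3   # strictly increasing transforms
  fc2[, 2] <- exp(fc2[, 2])
  expect_equal(rank_product(fc, "up"), rank_product(fc2, "up"))
})

test_that("exhaustive permutation P-values match direct enumeration", {
  fc <- cbind(c(3, 1, -2), c(2, -1, 0.5))
  rownames(fc) <- paste0("g", 1:3)
  p <- permutation_pvalues(fc, direction = "up", exhaustive = TRUE)
  # independent enumeration: all 36 pairs of column permutations
  r <- apply(-fc, 2, rank)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), 3:1)
  null_rp <- c()
  for (p1 in perms) for (p2 in perms) {
    null_rp <- c(null_rp, sqrt(r[p1, 1] * r[p2, 2]))
  }
  obs <- sqrt(r[, 1] * r[, 2])
  expected <- (1 + sapply(obs, function(o) sum(null_rp <= o + 1e-9))) /
    (1 + length(null_rp))
  expect_equal(unname(p), unname(expected))
})

test_that("sampled permutation P-values are valid, seeded and scheme-aware", {
  set.seed(21)
  fc <- matrix(rnorm(200), 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), NULL))
  attr(fc, "individual") <- c("A", "A", "B", "B")
  p1 <- permutation_pvalues(fc, direction = "up", B = 200, seed = 5)
  p2 <- permutation_pvalues(fc, direction = "up", B = 200, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  pb <- permutation_pvalues(fc, direction = "up", B = 200, seed = 5,
                            scheme = "individual")
  expect_true(all(pb > 0 & pb <= 1))
  # block scheme demands the individual attribute
  attr(fc, "individual") <- NULL
  expect_error(permutation_pvalues(fc, direction = "up", B = 10,
                                   scheme = "individual"),
               "individual")
})

test_that("a strong consistent gene gets a small P-value", {
  set.seed(22)
  fc <- matrix(rnorm(300), 100, 3,
               dimnames = list(sprintf("g%03d", 1:100), NULL))
  fc["g001", ] <- 6
  attr(fc, "individual") <- c("A", "B", "C")
  for (sch in c("comparison", "individual")) {
    p <- permutation_pvalues(fc, direction = "up", B = 300, seed = 1,
                             scheme = sch)
    expect_lt(p["g001"], 0.01)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), rep(0.04, 4))
  p2 <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  manual <- rev(cummin(rev(sort(p2) * 5 / seq_len(5))))[rank(p2)]
  expect_equal(bh_fdr(p2), pmin(manual, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, NA)), "0, 1")
})

test_that("call_degs recovers planted genes with correct sign", {
  cfg <- small_config(seed = 31)
  gs <- generate_study(cfg)
  degs <- call_degs(gs$study, B = 300, seed = 31)
  expect_s3_class(degs, "degset")
  expect_true(all(gs$truth$de_up %in% degs$gene[degs$direction == "up"]))
  expect_true(all(gs$truth$de_down %in%
                    degs$gene[degs$direction == "down"]))
  expect_equal(max(abs(degs$weight)), 1)
  expect_true(all(degs$weight[degs$direction == "up"] > 0))
  expect_true(all(degs$weight[degs$direction == "down"] < 0))
  expect_true(all(degs$fdr[degs$direction != "none"] <= 0.1))
})

test_that("call_degs is deterministic in the seed", {
  cfg <- small_config(seed = 32)
  st <- generate_study(cfg)$study
  expect_identical(call_degs(st, B = 100, seed = 9),
                   call_degs(st, B = 100, seed = 9))
})

test_that("concordant genes are the planted response, empty under the null", {
  # the per-individual block-permutation P is a rank quantile, so at most
  # an alpha fraction of genes can pass per individual; keep the planted
  # fraction below alpha, as in the default design
  cfg <- synthetic_config(n_genes = 500, n_de_up = 20, n_de_down = 15,
                          n_modules = 1, module_size = 10, n_tfs = 10,
                          n_de_mirnas = 4, n_mirnas = 40, seed = 33)
  gs <- generate_study(cfg)
  conc <- call_concordant(gs$study, B = 300, seed = 33)
  expect_gt(mean(gs$truth$de_up %in% conc$up), 0.85)
  expect_gt(mean(gs$truth$de_down %in% conc$down), 0.85)
  expect_length(intersect(conc$up, conc$down), 0)
  # the quantile cap itself
  expect_lte(length(conc$up), 0.05 * cfg$n_genes)
  expect_lte(length(conc$down), 0.05 * cfg$n_genes)
  null_st <- generate_study(small_config(seed = 34, effect_size = 0))$study
  conc0 <- call_concordant(null_st, B = 300, seed = 34)
  expect_lt(length(conc0$up) + length(conc0$down), 5)
})

test_that("concordance needs at least two individuals", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  sheet <- data.frame(sample = paste0("s", 1:4), individual = "A",
                      condition = c("low", "low", "high", "high"))
  st <- expression_study(m, sheet)
  expect_error(call_concordant(st, B = 10), "2 individuals")
})

test_that("the 2^-ddCt fold change follows the textbook arithmetic", {
  expect_equal(delta_delta_ct(c(20, 15), c(24, 16)), 8)
  expect_equal(delta_delta_ct(c(20, 15), c(20, 15)), 1)
  expect_error(delta_delta_ct(c(20, 15), 24), "treated and control")
  expect_error(delta_delta_ct(c(-1, 15), c(24, 16)), "positive")
})
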