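# Rank-product differential expression with gene-permutation nulls.
#
# The statistic follows the rank-product convention: within every pairwise
# high-vs-low comparison genes are ranked by fold change (rank 1 = most
# changed in the tested direction, average ranks on ties) and a gene's
# statistic is the geometric mean of its ranks. Significance comes from a
# pooled gene-permutation null (per comparison or per individual block;
# see permutation_pvalues), and the P-value of a gene is the fraction of
# null statistics at least as extreme, with a +1 pseudo-count.

#' Within-individual pairwise log2 fold changes
#'
#' One comparison per (high sample, low sample) pair within the same
#' individual; the value is high minus low on the log2 scale. Pairing
#' within individuals cancels their baseline offsets, which is what makes
#' the statistic usable at very small n.
#'
#' @param study an \code{\link{expression_study}}.
#' @return A genes-by-comparisons numeric matrix; the \code{"individual"}
#'   attribute records which individual each comparison came from.
#' @examples
#' gs <- generate_study(synthetic_config(n_genes = 50, n_de_up = 5,
#'                                       n_de_down = 5, n_modules = 1,
#'                                       module_size = 5, seed = 1))
#' fc <- pairwise_fold_changes(gs$study)
#' ncol(fc)  # 4 + 4 + 4 + 2 comparisons for the default design
#' @export
pairwise_fold_changes <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  sheet <- study$samples
  cols <- list(); inds <- character(0)
  for (ind in unique(sheet$individual)) {
    his <- sheet$sample[sheet$individual == ind & sheet$condition == "high"]
    los <- sheet$sample[sheet$individual == ind & sheet$condition == "low"]
    for (h in his) for (l in los) {
      cols[[length(cols) + 1L]] <- study$matrix[, h] - study$matrix[, l]
      names(cols)[length(cols)] <- paste0(h, ".vs.", l)
      inds <- c(inds, ind)
    }
  }
  assert_that(length(cols) > 0, "no high/low comparison could be formed")
  fc <- do.call(cbind, cols)
  rownames(fc) <- rownames(study$matrix)
  attr(fc, "individual") <- inds
  fc
}

#' Rank-product statistic
#'
#' @param fc genes-by-comparisons fold-change matrix
#'   (\code{\link{pairwise_fold_changes}}).
#' @param direction \code{"up"}: rank 1 is the largest fold change;
#'   \code{"down"}: rank 1 is the smallest. Ties receive average ranks.
#' @return Named vector of per-gene rank products
#'   \eqn{RP_g = (\prod_k r_{gk})^{1/K}}.
#' @export
rank_product <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  assert_that(is.matrix(fc) && ncol(fc) >= 1 && nrow(fc) >= 1,
              "fc must be a non-empty matrix")
  r <- fc_ranks(fc, direction)
  setNames(exp(rowMeans(log(r))), rownames(fc))
}

fc_ranks <- function(fc, direction) {
  s <- if (direction == "up") -fc else fc
  apply(s, 2, rank, ties.method = "average")
}

#' Gene-permutation P-values for rank products
#'
#' Builds the null by permuting each comparison's rank vector independently
#' \code{B} times; the pooled null then contains \code{nrow(fc) * B} rank
#' products and \eqn{P_g = (1 + \#\{null \le RP_g\}) / (1 + nB)}.
#'
#' @inheritParams rank_product
#' @param rp_observed observed rank products from \code{\link{rank_product}}
#'   (recomputed when \code{NULL}).
#' @param B number of permutation rounds (>= 1; >= 100 recommended).
#' @param seed RNG seed for the permutations; \code{exhaustive = TRUE}
#'   instead enumerates all K-tuples of permutations (tiny matrices only)
#'   and needs no seed.
#' @param exhaustive enumerate the complete permutation null
#'   (\code{scheme = "comparison"} only).
#' @param scheme \code{"comparison"}: every comparison's rank vector is
#'   permuted independently (the classic rank-product null; exact when
#'   comparisons share no samples). \code{"individual"}: one permutation
#'   per individual's block of comparisons (requires the
#'   \code{"individual"} attribute that \code{\link{pairwise_fold_changes}}
#'   attaches). Because all-pairs comparisons within an individual reuse
#'   samples, their rank vectors are correlated, and the block scheme
#'   preserves that correlation exactly — under the null genes are
#'   exchangeable within an individual, so the block null is exactly
#'   calibrated where the per-comparison null is anti-conservative.
#' @return Named per-gene P-values in (0, 1].
#' @export
permutation_pvalues <- function(fc, rp_observed = NULL,
                                direction = c("up", "down"),
                                B = 1000, seed = 1, exhaustive = FALSE,
                                scheme = c("comparison", "individual")) {
  direction <- match.arg(direction)
  scheme <- match.arg(scheme)
  assert_that(B >= 1, "B must be at least 1")
  n <- nrow(fc)
  if (is.null(rp_observed)) rp_observed <- rank_product(fc, direction)
  obs_log <- log(rp_observed) # compare on the log scale, same ordering
  lr <- log(fc_ranks(fc, direction))
  K <- ncol(lr)
  if (scheme == "individual") {
    blocks <- attr(fc, "individual")
    assert_that(!is.null(blocks) && length(blocks) == K,
                "scheme 'individual' needs the per-comparison individual attribute")
    block_cols <- split(seq_len(K), blocks)
  } else {
    block_cols <- as.list(seq_len(K))
  }
  if (exhaustive) {
    assert_that(scheme == "comparison",
                "exhaustive mode supports scheme 'comparison' only")
    assert_that(factorial(n)^K <= 1e5, "exhaustive mode is for tiny matrices")
    perms <- all_perms(n)
    combos <- expand.grid(rep(list(seq_along(perms)), K))
    null_log <- unlist(lapply(seq_len(nrow(combos)), function(i) {
      m <- vapply(seq_len(K),
                  function(k) lr[perms[[combos[i, k]]], k], numeric(n))
      rowMeans(m)
    }))
    B_eff <- nrow(combos)
  } else {
    null_log <- with_seed(seed, {
      out <- numeric(n * B)
      m <- matrix(0, n, K)
      for (b in seq_len(B)) {
        for (cols in block_cols) m[, cols] <- lr[sample.int(n), cols]
        out[((b - 1) * n + 1):(b * n)] <- rowMeans(m)
      }
      out
    })
    B_eff <- B
  }
  null_sorted <- sort(null_log)
  counts <- findInterval(obs_log + 1e-9, null_sorted)
  setNames((1 + counts) / (1 + n * B_eff), names(rp_observed))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' \code{\link[stats]{p.adjust}}).
#'
#' @param p vector of P-values in [0, 1].
#' @return Adjusted values, monotone in the sorted order, all <= 1.
#' @export
bh_fdr <- function(p) {
  assert_that(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
              "P-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes by rank product
#'
#' For every gene the smaller of the up/down permutation P-values chooses
#' the candidate direction; BH adjustment is applied within each direction;
#' genes at FDR below \code{fdr_cutoff} are called. Node weights are the
#' signed \eqn{-\log_{10} P} of the chosen direction, rescaled so
#' \eqn{\max |w| = 1} — a monotone rescaling, so every downstream
#' rank-based step is unaffected by the choice of scale.
#'
#' @param study an \code{\link{expression_study}}.
#' @param B permutation rounds.
#' @param fdr_cutoff BH FDR cutoff defining DEGs (default 0.1).
#' @param seed RNG seed.
#' @param scheme permutation-null scheme passed to
#'   \code{\link{permutation_pvalues}}. The default \code{"individual"}
#'   (one gene-label permutation per individual's block of comparisons)
#'   is exactly calibrated for the all-pairs comparison design, whose
#'   sample reuse makes the classic per-comparison null anti-conservative.
#' @return A data.frame of class \code{degset}: one row per gene with
#'   \code{gene}, \code{direction} (up/down/none), \code{rp_up},
#'   \code{rp_down}, \code{p_up}, \code{p_down}, \code{p}, \code{fdr},
#'   \code{weight}.
#' @export
call_degs <- function(study, B = 1000, fdr_cutoff = 0.1, seed = 1,
                      scheme = c("individual", "comparison")) {
  scheme <- match.arg(scheme)
  fc <- pairwise_fold_changes(study)
  rp_up <- rank_product(fc, "up")
  rp_down <- rank_product(fc, "down")
  p_up <- permutation_pvalues(fc, rp_up, "up", B = B,
                              seed = sub_seed(seed, 11), scheme = scheme)
  p_down <- permutation_pvalues(fc, rp_down, "down", B = B,
                                seed = sub_seed(seed, 12), scheme = scheme)
  choose_up <- p_up < p_down | (p_up == p_down & rp_up <= rp_down)
  fdr_up <- bh_fdr(p_up)
  fdr_down <- bh_fdr(p_down)
  p <- ifelse(choose_up, p_up, p_down)
  fdr <- ifelse(choose_up, fdr_up, fdr_down)
  direction <- ifelse(fdr <= fdr_cutoff,
                      ifelse(choose_up, "up", "down"), "none")
  weight <- rescale_max_abs(ifelse(choose_up, 1, -1) * (-log10(p)))
  out <- data.frame(gene = rownames(fc), direction = direction,
                    rp_up = rp_up, rp_down = rp_down,
                    p_up = p_up, p_down = p_down,
                    p = p, fdr = fdr, weight = weight,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("degset", "data.frame")
  out
}

#' Concordantly regulated genes across individuals
#'
#' A gene is concordant-up when its per-individual rank-product P-value
#' (computed from that individual's comparisons only) is at most
#' \code{alpha} with the up direction preferred in every individual;
#' analogously down. These are the sink genes of the flow analysis.
#'
#' @inheritParams call_degs
#' @param alpha per-individual significance cutoff (default 0.05).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
call_concordant <- function(study, alpha = 0.05, B = 1000, seed = 1,
                            scheme = c("individual", "comparison")) {
  scheme <- match.arg(scheme)
  sheet <- study$samples
  inds <- unique(sheet$individual)
  assert_that(length(inds) >= 2, "need at least 2 individuals")
  fc <- pairwise_fold_changes(study)
  by_ind <- attr(fc, "individual")
  genes <- rownames(fc)
  up_ok <- rep(TRUE, length(genes)); down_ok <- rep(TRUE, length(genes))
  used <- 0L
  for (i in seq_along(inds)) {
    cols <- which(by_ind == inds[i])
    if (length(cols) == 0) {
      warning("individual ", inds[i], " has no comparisons; excluded")
      next
    }
    used <- used + 1L
    fci <- fc[, cols, drop = FALSE]
    attr(fci, "individual") <- by_ind[cols]
    p_up <- permutation_pvalues(fci, direction = "up", B = B,
                                seed = sub_seed(seed, 100 + i),
                                scheme = scheme)
    p_down <- permutation_pvalues(fci, direction = "down", B = B,
                                  seed = sub_seed(seed, 200 + i),
                                  scheme = scheme)
    up_ok <- up_ok & p_up <= alpha & p_up < p_down
    down_ok <- down_ok & p_down <= alpha & p_down < p_up
  }
  assert_that(used >= 2, "fewer than 2 individuals contributed comparisons")
  list(up = genes[up_ok], down = genes[down_ok])
}

#' Relative quantification by the 2^-ddCt method
#'
#' @param treated,control numeric vectors \code{c(ct_target, ct_reference)}
#'   of PCR cycle numbers for the treated and control condition.
#' @return Fold change \eqn{2^{-\Delta\Delta C_T}}.
#' @examples
#' delta_delta_ct(c(20, 15), c(24, 16))  # 8-fold up
#' @export
delta_delta_ct <- function(treated, control) {
  assert_that(length(treated) == 2 && length(control) == 2 &&
                all(is.finite(c(treated, control))),
              "treated and control must each supply (ct_target, ct_reference)")
  assert_that(all(c(treated, control) > 0, na.rm = TRUE),
              "Ct values must be positive")
  ddct <- (treated[1] - treated[2]) - (control[1] - control[2])
  unname(2^(-ddct))
}
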