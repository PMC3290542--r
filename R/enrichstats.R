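# Gene-set statistics: Fisher's-exact over-representation with BH
# correction, paired gene-set shift tests, and correlation-distance
# sample clustering for study QC.

#' Fisher's exact gene-set enrichment
#'
#' One-sided (over-representation) hypergeometric test of a query gene set
#' against every set of a collection, restricted to the measured-gene
#' universe, with BH correction across the collection.
#'
#' @param query character vector of gene IDs (must lie in \code{universe}).
#' @param collection a \code{geneset_collection} (\code{\link{read_gmt}})
#'   or named list of gene-ID vectors.
#' @param universe character vector: the measured genes.
#' @param fdr_cutoff BH FDR cutoff flagging enrichment (default 0.05).
#' @return data.frame \code{set}, \code{set_size}, \code{overlap},
#'   \code{p}, \code{fdr}, \code{enriched}, sorted by P.
#' @export
fisher_enrichment <- function(query, collection, universe,
                              fdr_cutoff = 0.05) {
  assert_that(length(universe) > 0 && length(query) > 0,
              "query and universe must be non-empty")
  assert_that(all(query %in% universe), "query must be within the universe")
  sets <- if (inherits(collection, "geneset_collection")) {
    collection$sets
  } else collection
  N <- length(universe); m <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    # P(overlap >= k) for a draw of m from N with length(s) marked
    p <- phyper(k - 1, length(s), N - length(s), m, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$enriched <- out$fdr <= fdr_cutoff
  out[order(out$p, out$set), , drop = FALSE]
}

#' Paired shift test for a gene set between two expression groups
#'
#' Per-gene group means are computed from the replicates of each group;
#' the set's mean differences are then tested with a paired Student's
#' t-test across genes (each gene is its own pair). An unpaired
#' pooled-variance variant is available.
#'
#' @param genes gene IDs of the set.
#' @param exprA,exprB gene-by-replicate matrices (>= 2 replicates each,
#'   rownames = gene IDs).
#' @param paired paired across genes (default) or two-sample.
#' @return list \code{t}, \code{p}, \code{mean_shift}, \code{n_genes}.
#' @export
geneset_shift_test <- function(genes, exprA, exprB, paired = TRUE) {
  assert_that(ncol(exprA) >= 2 && ncol(exprB) >= 2,
              "need at least 2 replicates per group")
  common <- intersect(genes, intersect(rownames(exprA), rownames(exprB)))
  assert_that(length(common) >= 2,
              "gene set shares fewer than 2 genes with the matrices")
  ma <- rowMeans(exprA[common, , drop = FALSE])
  mb <- rowMeans(exprB[common, , drop = FALSE])
  if (isTRUE(all.equal(ma, mb))) {
    return(list(t = 0, p = 1, mean_shift = 0, n_genes = length(common)))
  }
  ht <- t.test(ma, mb, paired = paired, var.equal = !paired)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_shift = mean(ma - mb), n_genes = length(common))
}

#' Hierarchical clustering of samples by correlation distance
#'
#' Distance is 1 - Pearson correlation between sample expression vectors;
#' agglomeration uses average linkage. A constant sample vector gets
#' correlation 0 (distance 1) to every other sample, with a warning.
#'
#' @param study an \code{\link{expression_study}} with >= 3 samples.
#' @return An \code{\link[stats]{hclust}} tree over the samples.
#' @export
hclust_samples <- function(study) {
  m <- study$matrix
  assert_that(ncol(m) >= 3, "need at least 3 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant sample vector(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations set to 0")
  }
  r <- suppressWarnings(cor(m))
  r[!is.finite(r)] <- 0
  d <- 1 - r
  diag(d) <- 0
  hclust(as.dist(d), method = "average")
}
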