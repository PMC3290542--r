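#' Construct an expression study
#'
#' Bundles a log2-scale expression matrix with its sample sheet. All
#' differential-expression statistics in the package operate on this
#' container.
#'
#' @param matrix numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs), log2 units.
#' @param samples data.frame with columns \code{sample}, \code{individual},
#'   \code{condition}; \code{condition} must be \code{"low"} or
#'   \code{"high"}. Row order defines the column order expected in
#'   \code{matrix}.
#' @return An object of class \code{expression_study}: a list with elements
#'   \code{matrix} and \code{samples}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' sheet <- data.frame(sample = paste0("S", 1:4),
#'                     individual = c("A", "A", "B", "B"),
#'                     condition = c("low", "high", "low", "high"))
#' expression_study(m, sheet)
#' @export
expression_study <- function(matrix, samples) {
  assert_that(is.matrix(matrix) && is.numeric(matrix),
              "`matrix` must be a numeric matrix")
  assert_that(!is.null(rownames(matrix)) && !is.null(colnames(matrix)),
              "`matrix` needs gene rownames and sample colnames")
  dup <- rownames(matrix)[duplicated(rownames(matrix))]
  assert_that(length(dup) == 0,
              paste0("duplicate gene IDs: ", paste(unique(dup), collapse = ", ")))
  assert_that(is.data.frame(samples) &&
                all(c("sample", "individual", "condition") %in% names(samples)),
              "`samples` needs columns sample, individual, condition")
  samples$sample <- as.character(samples$sample)
  samples$individual <- as.character(samples$individual)
  samples$condition <- as.character(samples$condition)
  assert_that(all(samples$condition %in% c("low", "high")),
              "condition must be 'low' or 'high'")
  assert_that(setequal(colnames(matrix), samples$sample) &&
                ncol(matrix) == nrow(samples),
              "matrix columns and sample sheet disagree")
  matrix <- matrix[, samples$sample, drop = FALSE]
  assert_that(length(unique(samples$condition)) == 2,
              "both conditions must be present")
  per <- table(samples$individual, samples$condition)
  assert_that(all(per > 0),
              "every individual needs at least one sample per condition")
  structure(list(matrix = matrix, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples, %d individuals (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$samples$individual)),
              paste(names(table(x$samples$condition)),
                    table(x$samples$condition), sep = "=", collapse = ", ")))
  invisible(x)
}
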