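# File formats: headered TSV matrices and edge lists, GMT gene sets.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read an expression study from TSV files
#'
#' \code{path} is a gene-by-sample matrix with a header row and the gene
#' ID in the first column; \code{samples_path} is the sample sheet with
#' columns \code{sample}, \code{individual}, \code{condition}.
#'
#' @param path expression matrix TSV.
#' @param samples_path sample sheet TSV.
#' @return An \code{\link{expression_study}}.
#' @export
read_expression <- function(path, samples_path) {
  tab <- read_tsv(path)
  assert_that(ncol(tab) >= 2, "expression table needs genes plus samples")
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0,
              paste0("duplicate gene IDs in ", path, ": ",
                     paste(dup, collapse = ", ")))
  m <- as.matrix(tab[, -1, drop = FALSE])
  assert_that(is.numeric(m), "non-numeric expression values")
  rownames(m) <- ids
  sheet <- read_tsv(samples_path)
  missing <- setdiff(colnames(m), sheet$sample)
  assert_that(length(missing) == 0,
              paste0("samples absent from sample sheet: ",
                     paste(missing, collapse = ", ")))
  expression_study(m, sheet[sheet$sample %in% colnames(m), , drop = FALSE])
}

#' Write an expression study matrix as TSV
#'
#' @param study an \code{\link{expression_study}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_expression <- function(study, path) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (unique non-empty names,
#'   non-empty sets).
#' @param descriptions optional named character vector.
#' @return list of class \code{geneset_collection} with elements
#'   \code{sets} and \code{descriptions}.
#' @export
geneset_collection <- function(sets, descriptions = NULL) {
  assert_that(length(sets) > 0 && !is.null(names(sets)) &&
                !anyDuplicated(names(sets)) && all(nzchar(names(sets))),
              "sets must have unique non-empty names")
  assert_that(all(vapply(sets, length, integer(1)) > 0),
              "sets must be non-empty")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = lapply(sets, as.character),
                 descriptions = descriptions[names(sets)]),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets (sizes %s%s)\n",
              length(x$sets),
              paste(head(vapply(x$sets, length, integer(1)), 5),
                    collapse = ", "),
              if (length(x$sets) > 5) ", ..." else ""))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard dialect: one set per line, tab-separated, fields are set name,
#' description, then members; blank members are dropped.
#'
#' @param path GMT file.
#' @return A \code{\link{geneset_collection}}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  assert_that(length(bad) == 0,
              paste0("GMT parse error at line ", paste(bad, collapse = ", "),
                     ": need name, description and at least one member"))
  nms <- vapply(fields, `[`, character(1), 1)
  dup <- unique(nms[duplicated(nms)])
  assert_that(length(dup) == 0,
              paste0("duplicate set names: ", paste(dup, collapse = ", ")))
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- nms
  geneset_collection(sets, setNames(vapply(fields, `[`, character(1), 2),
                                    nms))
}

#' Write gene sets in GMT format
#'
#' @param collection a \code{\link{geneset_collection}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "",
            collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an edge list TSV
#'
#' @param path TSV with header; the first two columns are endpoints, an
#'   optional \code{confidence} column is preserved.
#' @return data.frame \code{from}, \code{to}(, \code{confidence}).
#' @export
read_edge_list <- function(path) {
  tab <- read_tsv(path)
  assert_that(ncol(tab) >= 2, "edge list needs at least two columns")
  out <- data.frame(from = as.character(tab[[1]]),
                    to = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  if ("confidence" %in% names(tab)) {
    out$confidence <- as.numeric(tab$confidence)
    assert_that(all(out$confidence > 0 & out$confidence <= 1),
                "confidences must lie in (0, 1]")
  }
  out
}
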