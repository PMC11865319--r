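.EXPRESSION_UNITS <- c("TPM", "nTPM", "counts", "CPTT", "RPM", "intensity",
                       "log2p1", "lnp1")
.LOG_UNITS <- c("log2p1", "lnp1")
.SPECIES <- c("human", "mouse", "synthetic")

#' Gene-by-sample expression matrix
#'
#' The basic container of the package: a numeric genes x samples matrix with a
#' unit tag, a species label and a free-text condition label (e.g. a cancer
#' type or tissue). Gene and sample identifiers are case-sensitive opaque
#' strings; human/mouse symbol casing (DBI vs Dbi) is preserved and
#' cross-species joins must go through an explicit label map, never
#' case-folding.
#'
#' Values must be finite, with no missing entries, and non-negative unless the
#' unit is one of the log scales (`log2p1`, `lnp1`).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty rownames (gene ids) and colnames (sample ids).
#' @param unit expression unit, one of `r paste(.EXPRESSION_UNITS, collapse=", ")`.
#' @param species `"human"`, `"mouse"` or `"synthetic"`.
#' @param condition free condition label.
#' @return an object of class `expression_matrix` (a numeric matrix with
#'   `unit`, `species` and `condition` attributes).
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("DBI", "ACAT2"), c("s1", "s2")))
#' em <- expression_matrix(m, unit = "TPM", species = "human", condition = "liver")
#' @export
expression_matrix <- function(values, unit, species = "synthetic",
                              condition = "unspecified") {
  unit <- match.arg(unit, .EXPRESSION_UNITS)
  species <- match.arg(species, .SPECIES)
  stopifnot(is.character(condition), length(condition) == 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite with no missing entries")
  if (!unit %in% .LOG_UNITS && any(values < 0))
    stop("negative values are not allowed for linear unit '", unit, "'")
  structure(values, unit = unit, species = species, condition = condition,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [unit=%s, species=%s, condition=%s]\n",
              nrow(x), ncol(x), attr(x, "unit"), attr(x, "species"),
              attr(x, "condition")))
  invisible(x)
}

# Re-attach class/attributes after a matrix operation stripped them.
.rewrap <- function(values, template, unit = attr(template, "unit")) {
  expression_matrix(values, unit = unit, species = attr(template, "species"),
                    condition = attr(template, "condition"))
}

#' Read an expression table from TSV
#'
#' Canonical orientation is genes-in-rows with a header row of sample ids and
#' the first header cell literally `gene_id`; `orientation =
#' "genes_in_columns"` accepts the transposed layout (first column then holds
#' sample ids) and transposes it on read. Malformed headers, non-numeric cells
#' and duplicate ids raise errors naming the offending row or column.
#'
#' @param path path to a delimited text file.
#' @param unit,species,condition metadata for the resulting matrix (a TSV
#'   carries none).
#' @param sep field delimiter (default tab).
#' @param orientation `"genes_in_rows"` (canonical) or `"genes_in_columns"`.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, unit = "TPM", species = "synthetic",
                                  condition = "unspecified", sep = "\t",
                                  orientation = c("genes_in_rows",
                                                  "genes_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("malformed header in ", path, ": expected an id column plus >=1 ",
         "sample column")
  id_col <- names(df)[1L]
  if (orientation == "genes_in_rows" && id_col != "gene_id")
    stop("malformed header in ", path, ": first header cell must be 'gene_id', got '",
         id_col, "'")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate ", if (orientation == "genes_in_rows") "gene" else "sample",
         " id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  num <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                dimnames = list(ids, names(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    col <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric value '", col[bad[1L]], "' at row '", ids[bad[1L]],
           "', column '", names(df)[j + 1L], "' in ", path)
    num[, j] <- v
  }
  if (orientation == "genes_in_columns") num <- t(num)
  expression_matrix(num, unit = unit, species = species, condition = condition)
}

#' Write an expression matrix as canonical TSV
#'
#' Genes in rows, header `gene_id` then sample ids, tab-delimited, `.` decimal
#' separator. Short decimal fixtures round-trip value-exactly through
#' [read_expression_table()].
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse single-cell matrix (MatrixMarket + label files)
#'
#' Reads a MatrixMarket coordinate file together with two one-column label
#' files (no header): row (gene) labels and column (cell) labels. The result
#' stays sparse (`Matrix::dgCMatrix` with dimnames), suitable for
#' [dotplot_summary()]; use [as_expression_matrix()] to densify.
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param genes_path one gene id per line, in row order.
#' @param cells_path one cell id per line, in column order.
#' @return a sparse `dgCMatrix` with gene/cell dimnames.
#' @export
read_expression_mtx <- function(mtx_path, genes_path, cells_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (length(genes) != nrow(m))
    stop("gene label file has ", length(genes), " entries but matrix has ",
         nrow(m), " rows")
  if (length(cells) != ncol(m))
    stop("cell label file has ", length(cells), " entries but matrix has ",
         ncol(m), " columns")
  if (anyDuplicated(genes)) stop("duplicate gene id(s) in ", genes_path)
  if (anyDuplicated(cells)) stop("duplicate cell id(s) in ", cells_path)
  dimnames(m) <- list(genes, cells)
  m
}

#' Densify a sparse matrix into an expression_matrix
#'
#' @param x a sparse `Matrix` with dimnames.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
as_expression_matrix <- function(x, unit = "counts", species = "synthetic",
                                 condition = "unspecified") {
  expression_matrix(as.matrix(x), unit = unit, species = species,
                    condition = condition)
}

#' Log-transform an expression matrix
#'
#' Elementwise `log2(x + 1)` or `ln(x + 1)`, the two pseudo-count transforms
#' used throughout the pipeline (bulk screens run on log2(TPM + 1); single-cell
#' summaries on ln(CPTT + 1)). Applying a log transform to an already
#' log-scale matrix is an error; `identity` returns the input unchanged.
#'
#' @param x an [expression_matrix()] on a linear-scale unit.
#' @param mode `"log2p1"`, `"lnp1"` or `"identity"`.
#' @return an [expression_matrix()] with the unit tag updated.
#' @export
transform_expression <- function(x, mode = c("log2p1", "lnp1", "identity")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expression_matrix"))
  if (mode == "identity") return(x)
  if (attr(x, "unit") %in% .LOG_UNITS)
    stop("matrix is already on a log scale (unit '", attr(x, "unit"),
         "'); refusing to transform again")
  v <- if (mode == "log2p1") log2(unclass(x) + 1) else log1p(unclass(x))
  .rewrap(v, x, unit = mode)
}
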