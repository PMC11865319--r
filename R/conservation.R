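#' Paired cross-species / cross-modality profile
#'
#' Aligned value vectors over matched units (organs or cell types) for two
#' species or modalities (e.g. human nTPM vs mouse nTPM, or mRNA vs protein
#' PPB). Built either directly or via [align_profiles()] from two named
#' vectors and an optional label-mapping table.
#'
#' @param labels matched unit labels.
#' @param x,y numeric values for sides A and B, aligned with `labels`.
#' @param modality_x,modality_y free-text modality tags.
#' @return an object of class `profile_pair`.
#' @export
profile_pair <- function(labels, x, y, modality_x = "A", modality_y = "B") {
  if (length(labels) != length(x) || length(x) != length(y))
    stop("labels, x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 matched units")
  if (anyNA(x) || anyNA(y)) stop("missing values after join are not allowed")
  if (anyDuplicated(labels)) stop("duplicate unit label(s)")
  structure(list(labels = as.character(labels), x = as.numeric(x),
                 y = as.numeric(y), modality_x = modality_x,
                 modality_y = modality_y),
            class = "profile_pair")
}

#' Align two named profiles into a profile_pair
#'
#' Joins two named value vectors by unit label, optionally through an explicit
#' mapping table (columns `from` = labels of `x`, `to` = labels of `y`) —
#' cross-species organ or cell-type naming rarely agrees literally. Unmatched
#' labels are dropped with a message.
#'
#' @param x,y named numeric vectors.
#' @param mapping optional data.frame with columns `from`, `to`.
#' @inheritParams profile_pair
#' @return a [profile_pair()].
#' @export
align_profiles <- function(x, y, mapping = NULL, modality_x = "A",
                           modality_y = "B") {
  stopifnot(!is.null(names(x)), !is.null(names(y)))
  if (is.null(mapping))
    mapping <- data.frame(from = names(x), to = names(x),
                          stringsAsFactors = FALSE)
  keep <- mapping$from %in% names(x) & mapping$to %in% names(y)
  dropped <- mapping$from[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " unmatched unit(s): ",
            paste(utils::head(dropped, 5), collapse = ", "))
  mapping <- mapping[keep, , drop = FALSE]
  profile_pair(labels = mapping$from, x = unname(x[mapping$from]),
               y = unname(y[mapping$to]), modality_x = modality_x,
               modality_y = modality_y)
}

#' Spearman correlation of a matched profile pair
#'
#' @param pair a [profile_pair()].
#' @return a [stat_result()] (`test_id = "spearman"`).
#' @export
profile_correlation <- function(pair) {
  stopifnot(inherits(pair, "profile_pair"))
  spearman_test(pair$x, pair$y)
}

#' Dot-plot summary of single-cell expression for one gene
#'
#' Per cell type: the mean of `ln(x + 1)` over all cells of that type (dot
#' color in the conventional display) and the percentage of cells with a
#' nonzero raw value (dot size). Percent-expressing is invariant under any
#' positive rescaling of the counts; the mean scaled expression is not.
#'
#' @param sc a sparse `Matrix` (genes x cells, from [read_expression_mtx()])
#'   or an [expression_matrix()], unit counts or CPTT.
#' @param cell_type_labels character vector of cell-type labels, either named
#'   by cell id or aligned with the matrix columns; every cell must be
#'   labeled.
#' @param gene gene id to summarize.
#' @return data.frame `cell_type`, `mean_scaled_expression`, `pct_expressing`,
#'   `n_cells`, ordered by cell type.
#' @export
dotplot_summary <- function(sc, cell_type_labels, gene) {
  cells <- colnames(sc)
  if (!gene %in% rownames(sc)) stop("gene '", gene, "' absent from matrix")
  if (inherits(sc, "expression_matrix") &&
      !attr(sc, "unit") %in% c("counts", "CPTT"))
    stop("dotplot_summary expects counts or CPTT, got unit '",
         attr(sc, "unit"), "'")
  if (!is.null(names(cell_type_labels)))
    cell_type_labels <- cell_type_labels[cells]
  if (length(cell_type_labels) != length(cells))
    stop("cell_type_labels must cover every cell")
  unlabeled <- cells[is.na(cell_type_labels) | !nzchar(cell_type_labels)]
  if (length(unlabeled))
    stop("unlabeled cell(s): ", paste(utils::head(unlabeled, 10), collapse = ", "))
  v <- as.numeric(sc[gene, ])
  out <- do.call(rbind, lapply(sort(unique(cell_type_labels)), function(ct) {
    vv <- v[cell_type_labels == ct]
    data.frame(cell_type = ct,
               mean_scaled_expression = mean(log1p(vv)),
               pct_expressing = 100 * mean(vv > 0),
               n_cells = length(vv), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Immunoblot densitometry normalization
#'
#' Each lane's chemiluminescent band intensity is first normalized to its own
#' Ponceau (total protein) intensity, then divided by the same ratio of the
#' membrane's shared loading-control lane (LC2, a pooled lysate loaded at
#' 2 ug on every membrane), giving relative expression values that are
#' invariant under per-membrane multiplicative exposure changes. A log2
#' column is included for heatmap export.
#'
#' @param lanes data.frame with columns `tissue`, `sex` (`F`/`M`, may be NA
#'   for control lanes), `band_intensity`, `ponceau_intensity`,
#'   `membrane_id`; intensities must be positive.
#' @param lc2_tissue the `tissue` value identifying the LC2 lane on each
#'   membrane (default `"LC2"`). If a membrane carries several LC2 lanes
#'   their ratios are averaged.
#' @return `lanes` (LC2 rows removed) with added columns `relative` and
#'   `log2_relative`.
#' @export
quantify_blot <- function(lanes, lc2_tissue = "LC2") {
  need <- c("tissue", "sex", "band_intensity", "ponceau_intensity", "membrane_id")
  if (!all(need %in% names(lanes)))
    stop("lanes must have columns: ", paste(need, collapse = ", "))
  if (any(lanes$band_intensity <= 0) || any(lanes$ponceau_intensity <= 0))
    stop("intensities must be positive")
  ratio <- lanes$band_intensity / lanes$ponceau_intensity
  is_lc <- lanes$tissue == lc2_tissue
  no_lc <- setdiff(unique(lanes$membrane_id), unique(lanes$membrane_id[is_lc]))
  if (length(no_lc))
    stop("membrane(s) without an LC2 lane: ", paste(no_lc, collapse = ", "))
  lc_ratio <- tapply(ratio[is_lc], lanes$membrane_id[is_lc], mean)
  out <- lanes[!is_lc, , drop = FALSE]
  out$relative <- ratio[!is_lc] / as.numeric(lc_ratio[as.character(out$membrane_id)])
  out$log2_relative <- log2(out$relative)
  rownames(out) <- NULL
  out
}

#' Per-tissue sex-dimorphism test with BH correction
#'
#' Two-sided pooled-variance Student t-test of female vs male relative
#' expression within each tissue, BH-adjusted across tissues; tissues with
#' `q < 0.1` are flagged. Tissues with fewer than 2 values per sex are
#' skipped with a warning rather than an error.
#'
#' @param values data.frame with columns `tissue`, `sex` (`F`/`M`) and
#'   `relative` (from [quantify_blot()]).
#' @param q_flag flagging threshold on the BH q-value (default 0.1).
#' @return data.frame `tissue`, `estimate` (mean F - mean M), `p`, `q`,
#'   `flagged`, plus a `skipped` attribute naming skipped tissues.
#' @export
sex_dimorphism_test <- function(values, q_flag = 0.1) {
  need <- c("tissue", "sex", "relative")
  if (!all(need %in% names(values)))
    stop("values must have columns: ", paste(need, collapse = ", "))
  tissues <- sort(unique(values$tissue))
  rows <- list(); skipped <- character(0)
  for (ti in tissues) {
    f <- values$relative[values$tissue == ti & values$sex == "F"]
    m <- values$relative[values$tissue == ti & values$sex == "M"]
    if (length(f) < 2L || length(m) < 2L) {
      skipped <- c(skipped, ti)
      next
    }
    p <- if (stats::sd(f) == 0 && stats::sd(m) == 0) {
      if (mean(f) == mean(m)) 1 else 0
    } else stats::t.test(f, m, var.equal = TRUE)$p.value
    rows[[ti]] <- data.frame(tissue = ti, estimate = mean(f) - mean(m),
                             p = p, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped tissue(s) with < 2 values per sex: ",
            paste(skipped, collapse = ", "))
  if (!length(rows))
    return(structure(data.frame(tissue = character(0), estimate = numeric(0),
                                p = numeric(0), q = numeric(0),
                                flagged = logical(0)), skipped = skipped))
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out$flagged <- out$q < q_flag
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}
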