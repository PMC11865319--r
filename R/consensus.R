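#' Regulator x database binary prediction table
#'
#' Holds binary predictions of candidate regulators (transcription factors or
#' miRNAs) across several databases, each database tagged with the species
#' panel (human or mouse) it interrogates.
#'
#' @param predictions binary (0/1) matrix, regulators in rows (rownames =
#'   regulator ids), databases in columns (colnames = database ids).
#' @param db_species character vector, one of `"human"`/`"mouse"` per
#'   database column.
#' @return an object of class `prediction_table`.
#' @export
prediction_table <- function(predictions, db_species) {
  if (!is.matrix(predictions) || is.null(rownames(predictions)) ||
      is.null(colnames(predictions)))
    stop("'predictions' must be a matrix with regulator rownames and database colnames")
  if (anyDuplicated(rownames(predictions)))
    stop("duplicate regulator id(s)")
  if (anyDuplicated(colnames(predictions)))
    stop("duplicate database id(s)")
  if (!all(predictions %in% c(0, 1)))
    stop("predictions must be binary (0/1)")
  if (length(db_species) != ncol(predictions))
    stop("db_species must tag every database column")
  if (!all(db_species %in% c("human", "mouse")))
    stop("db_species entries must be 'human' or 'mouse'")
  structure(list(predictions = predictions,
                 db_species = stats::setNames(db_species, colnames(predictions))),
            class = "prediction_table")
}

#' Read a long-format prediction TSV
#'
#' Expects columns `regulator`, `database`, `species`, `predicted` (0/1); one
#' row per regulator x database pair (missing pairs count as 0).
#'
#' @param path TSV path.
#' @return a [prediction_table()].
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("regulator", "database", "species", "predicted")
  if (!all(need %in% names(df)))
    stop("prediction TSV must have columns: ", paste(need, collapse = ", "))
  sp <- unique(df[, c("database", "species")])
  if (anyDuplicated(sp$database))
    stop("a database is tagged with more than one species")
  regs <- sort(unique(df$regulator))
  dbs <- sp$database
  m <- matrix(0L, length(regs), length(dbs), dimnames = list(regs, dbs))
  m[cbind(match(df$regulator, regs), match(df$database, dbs))] <-
    as.integer(df$predicted)
  prediction_table(m, sp$species)
}

#' Two-branch consensus rule
#'
#' A regulator is selected when it is predicted by at least `t_both_h` human
#' AND `t_both_m` mouse databases, or by at least `t_alt_h` human AND
#' `t_alt_m` mouse databases. The defaults (3,3 | 4,2) encode the published
#' high-confidence rule over 7 human and 4 mouse databases.
#'
#' @param t_both_h,t_both_m first-branch thresholds (default 3, 3).
#' @param t_alt_h,t_alt_m second-branch thresholds (default 4, 2).
#' @return a list of class `consensus_rule`.
#' @export
consensus_rule <- function(t_both_h = 3L, t_both_m = 3L,
                           t_alt_h = 4L, t_alt_m = 2L) {
  r <- lapply(list(t_both_h = t_both_h, t_both_m = t_both_m,
                   t_alt_h = t_alt_h, t_alt_m = t_alt_m), as.integer)
  if (any(unlist(r) < 0L)) stop("thresholds must be nonnegative")
  structure(r, class = "consensus_rule")
}

#' Select high-confidence regulators by multi-database consensus
#'
#' Counts, per regulator, the supporting human and mouse databases and applies
#' the two-branch [consensus_rule()] disjunction. Selection is monotone:
#' adding a prediction can never deselect a regulator.
#'
#' @param table a [prediction_table()].
#' @param rule a [consensus_rule()].
#' @return data.frame `regulator`, `h_count`, `m_count`, `selected`, ordered
#'   by regulator id; selected regulators first by descending total support is
#'   available via the `selected` flag.
#' @export
consensus_select <- function(table, rule = consensus_rule()) {
  stopifnot(inherits(table, "prediction_table"), inherits(rule, "consensus_rule"))
  h_cols <- table$db_species == "human"
  m_cols <- table$db_species == "mouse"
  n_h <- sum(h_cols); n_m <- sum(m_cols)
  if (rule$t_both_h > n_h || rule$t_alt_h > n_h)
    stop("human threshold exceeds the human panel size (", n_h, ")")
  if (rule$t_both_m > n_m || rule$t_alt_m > n_m)
    stop("mouse threshold exceeds the mouse panel size (", n_m, ")")
  h <- rowSums(table$predictions[, h_cols, drop = FALSE])
  m <- rowSums(table$predictions[, m_cols, drop = FALSE])
  sel <- (h >= rule$t_both_h & m >= rule$t_both_m) |
         (h >= rule$t_alt_h & m >= rule$t_alt_m)
  out <- data.frame(regulator = rownames(table$predictions),
                    h_count = as.integer(h), m_count = as.integer(m),
                    selected = unname(sel), stringsAsFactors = FALSE)
  out[order(out$regulator), , drop = FALSE]
}

#' Conserved-miRNA Venn selection
#'
#' Keeps a miRNA when it is predicted by at least `per_species_min` database
#' in the human panel AND in the mouse panel (the cross-species Venn
#' intersection; the minimum per species is a parameter, default 1).
#'
#' @param table a [prediction_table()] of miRNA predictions.
#' @param per_species_min minimum supporting databases per species (default 1).
#' @return data.frame `regulator`, `h_count`, `m_count`, `selected`.
#' @export
mirna_consensus <- function(table, per_species_min = 1L) {
  rule <- consensus_rule(per_species_min, per_species_min,
                         per_species_min, per_species_min)
  consensus_select(table, rule)
}

#' Negative-correlation screen of candidate miRNAs
#'
#' Correlates each candidate miRNA's expression (rows of `mirna_matrix`, RPM
#' scale) with the seed gene's expression over matched samples (Spearman) and
#' flags miRNAs that are negatively and significantly correlated
#' (`rho < 0` and `p < alpha`, default `alpha = 0.01`).
#'
#' @param mirna_matrix [expression_matrix()] of miRNAs x samples.
#' @param seed_vector numeric vector of seed-gene expression over the same
#'   samples (matched by position, or by names when both are named).
#' @param alpha significance threshold (default 0.01).
#' @return data.frame `mirna`, `rho`, `p_rho`, `flagged`.
#' @export
mirna_screen <- function(mirna_matrix, seed_vector, alpha = 0.01) {
  stopifnot(inherits(mirna_matrix, "expression_matrix"))
  if (!is.null(names(seed_vector)))
    seed_vector <- seed_vector[colnames(mirna_matrix)]
  if (length(seed_vector) != ncol(mirna_matrix) || anyNA(seed_vector))
    stop("seed_vector must cover every sample of the miRNA matrix")
  if (ncol(mirna_matrix) < 3L) stop("need at least 3 samples")
  sp <- row_spearman(unclass(mirna_matrix), as.numeric(seed_vector))
  data.frame(mirna = sp$gene_id, rho = sp$rho, p_rho = sp$p_rho,
             flagged = sp$rho < 0 & sp$p_rho < alpha,
             stringsAsFactors = FALSE)
}
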