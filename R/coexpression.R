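#' Stratify samples by seed-gene expression
#'
#' Splits the samples of one condition at the median of the seed gene's
#' expression: samples strictly above the median are `High`, all others `Low`
#' (ties at the median go to `Low`, so `High` is the strict upper half). The
#' split is deterministic.
#'
#' @param x an [expression_matrix()] with at least 3 samples.
#' @param seed_gene gene id of the seed.
#' @return named character vector (`"High"`/`"Low"`) over the samples of `x`.
#' @export
stratify_by_seed <- function(x, seed_gene) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!seed_gene %in% rownames(x))
    stop("seed gene '", seed_gene, "' absent from matrix")
  if (ncol(x) < 3L) stop("need at least 3 samples to stratify")
  v <- unclass(x)[seed_gene, ]
  if (length(unique(v)) == 1L)
    stop("degenerate stratification: all seed values identical")
  lab <- ifelse(v > stats::median(v), "High", "Low")
  if (!any(lab == "High") || !any(lab == "Low"))
    stop("degenerate stratification: one group is empty")
  names(lab) <- colnames(x)
  lab
}

#' Per-condition double-filter co-expression screen
#'
#' The discovery screen run inside each condition. On `log2(x + 1)` values:
#'
#' * differential expression between the seed-High and seed-Low sample halves
#'   (log2FC = mean High - mean Low; two-sided Welch t-test), and
#' * Spearman correlation of every gene with the seed over all samples.
#'
#' A gene passes when `log2FC > fc_threshold`, `p_dge < p_threshold`,
#' `rho > rho_threshold` and `p_rho < p_threshold` (defaults 0, 0.05, 0.3,
#' 0.05). Constant gene rows get `rho = 0`, `p_rho = 1`, `p_dge = 1` and never
#' pass.
#'
#' @param x a linear-scale [expression_matrix()] for one condition.
#' @param seed_gene seed gene id.
#' @param fc_threshold,p_threshold,rho_threshold screen thresholds.
#' @return a `coexpression_table`: data.frame with columns `gene_id`,
#'   `log2fc`, `p_dge`, `rho`, `p_rho`, `passes`; the condition label and
#'   thresholds are attached as attributes.
#' @export
condition_screen <- function(x, seed_gene, fc_threshold = 0,
                             p_threshold = 0.05, rho_threshold = 0.3) {
  stopifnot(inherits(x, "expression_matrix"))
  if (attr(x, "unit") %in% .LOG_UNITS)
    stop("condition_screen expects a linear-scale matrix; got unit '",
         attr(x, "unit"), "'")
  strata <- stratify_by_seed(x, seed_gene)
  L <- unclass(transform_expression(x, "log2p1"))
  dge <- row_welch(L, names(strata)[strata == "High"],
                   names(strata)[strata == "Low"])
  sp <- row_spearman(L, L[seed_gene, ])
  tab <- merge(dge, sp, by = "gene_id", sort = FALSE)
  tab <- tab[match(rownames(x), tab$gene_id), ]
  rownames(tab) <- NULL
  tab$passes <- tab$log2fc > fc_threshold & tab$p_dge < p_threshold &
    tab$rho > rho_threshold & tab$p_rho < p_threshold
  structure(tab, condition = attr(x, "condition"), seed_gene = seed_gene,
            thresholds = list(fc = fc_threshold, p = p_threshold,
                              rho = rho_threshold),
            class = c("coexpression_table", "data.frame"))
}

#' Intersect per-condition screens into a network
#'
#' Counts, per gene, the number of conditions whose screen it passed, and
#' keeps genes supported by at least `min_conditions` conditions (boundary
#' inclusive). The seed gene always passes its own screen and is removed only
#' here, at reporting. Members are ordered by descending support, then
#' lexicographically.
#'
#' @param tables list of `coexpression_table`s (one per condition).
#' @param min_conditions minimum number of passing conditions (default 20).
#' @return a `network_result`: list with `seed_gene`, `members` (data.frame
#'   `gene_id`, `support`), `support_counts` (named vector over all genes),
#'   `n_conditions`, `min_conditions`, `thresholds`.
#' @export
build_network <- function(tables, min_conditions = 20L) {
  if (length(tables) == 0L) stop("empty table list")
  if (min_conditions > length(tables))
    stop("min_conditions (", min_conditions, ") exceeds the number of ",
         "screened conditions (", length(tables), ")")
  seed_gene <- attr(tables[[1L]], "seed_gene")
  genes <- tables[[1L]]$gene_id
  support <- stats::setNames(integer(length(genes)), genes)
  for (tab in tables) {
    stopifnot(inherits(tab, "coexpression_table"))
    if (!identical(attr(tab, "seed_gene"), seed_gene))
      stop("tables screen different seed genes")
    support[tab$gene_id[tab$passes]] <-
      support[tab$gene_id[tab$passes]] + 1L
  }
  keep <- names(support)[support >= min_conditions & names(support) != seed_gene]
  ord <- order(-support[keep], keep)
  members <- data.frame(gene_id = keep[ord],
                        support = unname(support[keep][ord]),
                        stringsAsFactors = FALSE)
  structure(list(seed_gene = seed_gene, members = members,
                 support_counts = support,
                 n_conditions = length(tables),
                 min_conditions = as.integer(min_conditions),
                 thresholds = attr(tables[[1L]], "thresholds")),
            class = "network_result")
}

#' Wrap an externally obtained gene list as a network result
#'
#' Convenience constructor for running [validate_network()] or
#' [annotate_network()] on a member list that came from outside the discovery
#' screen (e.g. a published network).
#'
#' @param seed_gene seed gene id.
#' @param member_gene_ids character vector of member gene ids (seed excluded).
#' @param support optional per-member support counts (default `NA`).
#' @return a `network_result`.
#' @export
network_from_genes <- function(seed_gene, member_gene_ids, support = NA_integer_) {
  stopifnot(is.character(member_gene_ids), length(member_gene_ids) >= 1L)
  if (seed_gene %in% member_gene_ids)
    stop("member list must not contain the seed gene")
  if (anyDuplicated(member_gene_ids)) stop("duplicate member gene id(s)")
  structure(list(seed_gene = seed_gene,
                 members = data.frame(gene_id = member_gene_ids,
                                      support = rep_len(support,
                                                        length(member_gene_ids)),
                                      stringsAsFactors = FALSE),
                 support_counts = NULL, n_conditions = NA_integer_,
                 min_conditions = NA_integer_, thresholds = NULL),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("co-expression network of %s: %d members (support >= %d of %d conditions)\n",
              x$seed_gene, nrow(x$members), x$min_conditions, x$n_conditions))
  if (nrow(x$members)) print(utils::head(x$members, 10))
  invisible(x)
}

#' Validate a network in an independent dataset
#'
#' Recomputes, in an independent expression matrix (any species), the Spearman
#' correlation of every network member with the seed gene on `log2(x + 1)`
#' values. A member replicates when `rho > 0` and `p < 0.05` (raw p, matching
#' the discovery conditions; BH q-values are additionally reported). Members
#' absent from the matrix are listed as missing, not failed.
#'
#' @param network a `network_result`.
#' @param x an [expression_matrix()] from the validation dataset.
#' @param seed_gene seed gene id in `x` (cross-species symbol casing may
#'   differ from `network$seed_gene`; supply the label used in `x`).
#' @return a `validation_table`: data.frame `gene_id`, `rho`, `p_rho`,
#'   `q_rho`, `replicated`, with attributes `missing` (character vector),
#'   `dataset` and `species`.
#' @export
validate_network <- function(network, x, seed_gene = network$seed_gene) {
  stopifnot(inherits(network, "network_result"), inherits(x, "expression_matrix"))
  if (nrow(network$members) == 0L) stop("network has no members to validate")
  if (!seed_gene %in% rownames(x))
    stop("seed gene '", seed_gene, "' absent from validation matrix")
  genes <- network$members$gene_id
  present <- genes[genes %in% rownames(x)]
  missing <- setdiff(genes, present)
  L <- if (attr(x, "unit") %in% .LOG_UNITS) unclass(x)
       else unclass(transform_expression(x, "log2p1"))
  sp <- row_spearman(L[present, , drop = FALSE], L[seed_gene, ])
  sp$q_rho <- benjamini_hochberg(sp$p_rho)
  sp$replicated <- sp$rho > 0 & sp$p_rho < 0.05
  structure(sp, missing = missing, dataset = attr(x, "condition"),
            species = attr(x, "species"),
            class = c("validation_table", "data.frame"))
}

#' Annotation summary and enrichment of a network
#'
#' Summarizes how many network members are annotated to the mitochondrial
#' compartment and to the metabolism category, as counts and fractions of the
#' network, with a one-sided hypergeometric overrepresentation p-value of each
#' label against a background gene universe.
#'
#' @param network a `network_result` (the seed gene is not part of the member
#'   list and is not counted).
#' @param annotations data.frame with columns `gene_id`, `compartment`
#'   (`mitochondrion`/`other`/`unknown`), `category`
#'   (`metabolism`/`other`/`unknown`), one row per gene. Members missing from
#'   the table count as `unknown`.
#' @param background_gene_ids character vector defining the background
#'   universe (must contain the network members).
#' @return an `annotation_summary` list: `n_network`, `n_mitochondrial`,
#'   `frac_mitochondrial`, `p_mitochondrial`, `n_metabolism`,
#'   `frac_metabolism`, `p_metabolism`.
#' @export
annotate_network <- function(network, annotations, background_gene_ids) {
  stopifnot(inherits(network, "network_result"))
  members <- network$members$gene_id
  if (length(members) == 0L) stop("empty network")
  if (anyDuplicated(annotations$gene_id))
    stop("annotation table must have one row per gene_id")
  if (!all(members %in% background_gene_ids))
    stop("background must contain every network member")
  ann_of <- function(ids, col) {
    v <- annotations[[col]][match(ids, annotations$gene_id)]
    v[is.na(v)] <- "unknown"
    v
  }
  n <- length(members)
  N <- length(unique(background_gene_ids))
  summ <- list(n_network = n)
  for (lab in c(mitochondrial = "mitochondrion", metabolism = "metabolism")) {
    col <- if (lab == "mitochondrion") "compartment" else "category"
    key <- if (lab == "mitochondrion") "mitochondrial" else "metabolism"
    k <- sum(ann_of(members, col) == lab)
    K <- sum(ann_of(unique(background_gene_ids), col) == lab)
    summ[[paste0("n_", key)]] <- k
    summ[[paste0("frac_", key)]] <- k / n
    summ[[paste0("p_", key)]] <-
      if (K == 0L) 1 else hypergeom_enrichment_p(k, n, K, N)
  }
  structure(summ, class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("network of %d genes: %d mitochondrial (%.0f%%, enrichment p = %.3g), %d metabolism (%.0f%%, enrichment p = %.3g)\n",
              x$n_network, x$n_mitochondrial, 100 * x$frac_mitochondrial,
              x$p_mitochondrial, x$n_metabolism, 100 * x$frac_metabolism,
              x$p_metabolism))
  invisible(x)
}

# F1 of a recovered member set against planted truth (seed excluded on both
# sides); used by the pipeline's recovery block and the benchmarks.
recovery_f1 <- function(network, truth) {
  stopifnot(inherits(network, "network_result"), inherits(truth, "sim_truth"))
  found <- network$members$gene_id
  planted <- setdiff(truth$module_gene_ids, truth$seed_gene)
  tp <- length(intersect(found, planted))
  prec <- if (length(found)) tp / length(found) else 0
  rec <- if (length(planted)) tp / length(planted) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = length(found) - tp, fn = length(planted) - tp,
       precision = prec, recall = rec, f1 = f1)
}
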