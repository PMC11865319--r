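#' One regulator perturbation dataset
#'
#' A control-vs-perturbed expression comparison for one regulator (e.g. an
#' siRNA knockdown or a knockout RNA-seq experiment). The regulator's own
#' transcript may or may not be present in the matrix (knockout designs often
#' have no residual transcript).
#'
#' @param regulator regulator id.
#' @param dataset dataset label.
#' @param matrix an [expression_matrix()] over all samples.
#' @param group character vector over samples: `"control"` or `"perturbed"`.
#' @return an object of class `perturbation_dataset`.
#' @export
perturbation_dataset <- function(regulator, dataset, matrix, group) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (length(group) != ncol(matrix))
    stop("'group' must label every sample")
  if (!all(group %in% c("control", "perturbed")))
    stop("group labels must be 'control' or 'perturbed'")
  if (!any(group == "control") || !any(group == "perturbed"))
    stop("both groups must be nonempty")
  structure(list(regulator = regulator, dataset = dataset, matrix = matrix,
                 group = stats::setNames(group, colnames(matrix))),
            class = "perturbation_dataset")
}

#' Choose the two-group test suited to the data at hand
#'
#' Deterministic rule picking among Student's t, Welch's t and the Wilcoxon
#' rank-sum test: small groups (either n < 4) use the exact Wilcoxon; if a
#' Shapiro-Wilk normality check rejects (alpha = 0.05) in either group, use
#' Wilcoxon; if the variance ratio (larger/smaller) exceeds 4, use Welch;
#' otherwise pooled-variance Student.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return `"student_t"`, `"welch_t"` or `"wilcoxon"`.
#' @export
choose_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("both groups must have >= 2 observations")
  if (na < 4L || nb < 4L) return("wilcoxon")
  normal_ok <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (!normal_ok(group_a) || !normal_ok(group_b)) return("wilcoxon")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (max(va, vb) / min(va, vb) > 4) return("welch_t")
  "student_t"
}

# Two-sided p for one gene under the chosen test. Degenerate inputs (both
# groups constant) get p = 1 when equal, p = 0 otherwise.
.two_group_p <- function(a, b, test_id) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  switch(test_id,
         wilcoxon = suppressWarnings(
           stats::wilcox.test(a, b, alternative = "two.sided")$p.value),
         welch_t = stats::t.test(a, b, var.equal = FALSE)$p.value,
         student_t = stats::t.test(a, b, var.equal = TRUE)$p.value)
}

#' Per-gene perturbation effects
#'
#' For every gene of `gene_set` present in the dataset's matrix, computes the
#' effect as the difference of group means on `log2(x + 1)` (perturbed minus
#' control) and a two-sided p-value from the test chosen per gene by
#' [choose_test()]. Genes absent from the matrix are reported in the
#' `missing` attribute, not as rows.
#'
#' @param dataset a [perturbation_dataset()].
#' @param gene_set character vector of gene ids (typically seed + network).
#' @return data.frame `gene_id`, `effect`, `p`, `test_id`, with attributes
#'   `regulator`, `dataset` and `missing`.
#' @export
perturbation_effects <- function(dataset, gene_set) {
  stopifnot(inherits(dataset, "perturbation_dataset"))
  if (length(gene_set) == 0L) stop("empty gene_set")
  x <- dataset$matrix
  L <- if (attr(x, "unit") %in% .LOG_UNITS) unclass(x)
       else unclass(transform_expression(x, "log2p1"))
  present <- gene_set[gene_set %in% rownames(L)]
  missing <- setdiff(gene_set, present)
  ctrl <- names(dataset$group)[dataset$group == "control"]
  pert <- names(dataset$group)[dataset$group == "perturbed"]
  rows <- lapply(present, function(g) {
    a <- L[g, pert]; b <- L[g, ctrl]
    test_id <- choose_test(a, b)
    data.frame(gene_id = g, effect = mean(a) - mean(b),
               p = .two_group_p(a, b, test_id), test_id = test_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, regulator = dataset$regulator, dataset = dataset$dataset,
            missing = missing, class = c("effect_table", "data.frame"))
}

#' Coherent net effect of a regulator perturbation on the network
#'
#' Decides whether a perturbation dataset shows a coherent effect on the seed
#' gene and its co-expression network, and if so reports the total-network
#' score. Coherence requires all of:
#'
#' * the seed gene's effect is significant (`p < alpha`),
#' * strictly more than a `majority` fraction of network genes respond with
#'   the same sign as the seed, and
#' * (network gate, on by default) a one-sample Wilcoxon signed-rank test of
#'   the network effects against 0 is significant at `network_alpha` with the
#'   median effect agreeing in sign with the seed. Set `network_alpha = NA`
#'   to gate on the seed and the sign-majority only.
#'
#' When coherent, `total_network_score` is the mean network effect,
#' `total_network_p` the one-sample Wilcoxon p, and the direction is
#' `activator` when inhibition of the regulator decreases seed + network
#' (negative effects) or `repressor` when it increases them; otherwise the
#' direction is `NS` and the total fields are withheld (`NA`).
#'
#' @param effects an effect table from [perturbation_effects()] covering the
#'   seed and at least one network gene.
#' @param seed_gene seed gene id.
#' @param network a `network_result` or a character vector of network gene
#'   ids.
#' @param alpha seed significance threshold (default 0.05).
#' @param majority sign-majority fraction that must be strictly exceeded
#'   (default 0.5).
#' @param network_alpha significance threshold of the network-side gate
#'   (default = `alpha`; `NA` disables the gate).
#' @return a `net_effect` list: `regulator`, `dataset`, `effects`,
#'   `seed_effect`, `seed_p`, `coherent`, `direction`
#'   (`activator`/`repressor`/`NS`), `total_network_score`,
#'   `total_network_p`, `n_network`, `frac_same_sign`.
#' @export
network_net_effect <- function(effects, seed_gene, network, alpha = 0.05,
                               majority = 0.5, network_alpha = alpha) {
  stopifnot(inherits(effects, "data.frame"))
  net_genes <- if (inherits(network, "network_result"))
    network$members$gene_id else as.character(network)
  net_genes <- setdiff(net_genes, seed_gene)
  srow <- effects[effects$gene_id == seed_gene, , drop = FALSE]
  if (nrow(srow) != 1L) stop("seed effect missing from effect table")
  nrows <- effects[effects$gene_id %in% net_genes, , drop = FALSE]
  if (nrow(nrows) == 0L) stop("no network genes in effect table")
  seed_eff <- srow$effect; seed_p <- srow$p
  seed_sign <- sign(seed_eff)
  frac_same <- mean(sign(nrows$effect) == seed_sign)
  net_p <- if (all(nrows$effect == 0)) 1 else suppressWarnings(
    stats::wilcox.test(nrows$effect, mu = 0,
                       alternative = "two.sided")$p.value)
  coherent <- seed_p < alpha && seed_sign != 0 && frac_same > majority
  if (coherent && !is.na(network_alpha))
    coherent <- net_p < network_alpha &&
      sign(stats::median(nrows$effect)) == seed_sign
  direction <- "NS"
  score <- NA_real_; score_p <- NA_real_
  if (coherent) {
    direction <- if (seed_sign < 0) "activator" else "repressor"
    score <- mean(nrows$effect)
    score_p <- net_p
  }
  structure(list(regulator = attr(effects, "regulator"),
                 dataset = attr(effects, "dataset"),
                 effects = effects, seed_effect = seed_eff, seed_p = seed_p,
                 coherent = coherent, direction = direction,
                 total_network_score = score, total_network_p = score_p,
                 n_network = nrow(nrows), frac_same_sign = frac_same),
            class = "net_effect")
}

#' @export
print.net_effect <- function(x, ...) {
  cat(sprintf("%s / %s: %s (seed effect %.2f, p = %.3g; %d network genes, %.0f%% same sign)\n",
              x$regulator %||% "?", x$dataset %||% "?", x$direction,
              x$seed_effect, x$seed_p, x$n_network, 100 * x$frac_same_sign))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-dataset net effects into per-regulator calls
#'
#' A regulator is called `activator` or `repressor` when at least one of its
#' datasets is coherent and a strict majority of its coherent datasets agree
#' in direction; ties or no coherent dataset give `NS`. Also emits the
#' dot-plot-ready long table (regulator x gene x effect).
#'
#' @param net_effects list of `net_effect` objects (any mix of regulators).
#' @return list with `calls` (data.frame `regulator`, `n_datasets`,
#'   `n_coherent`, `n_activator`, `n_repressor`, `call`) and `long` (data.frame
#'   `regulator`, `dataset`, `gene_id`, `effect`, `p`, `coherent`,
#'   `direction`).
#' @export
aggregate_regulators <- function(net_effects) {
  stopifnot(length(net_effects) >= 1L)
  regs <- vapply(net_effects, function(e) e$regulator %||% NA_character_, "")
  long <- do.call(rbind, lapply(net_effects, function(e) {
    data.frame(regulator = e$regulator %||% NA_character_,
               dataset = e$dataset %||% NA_character_,
               gene_id = e$effects$gene_id, effect = e$effects$effect,
               p = e$effects$p, coherent = e$coherent,
               direction = e$direction, stringsAsFactors = FALSE)
  }))
  calls <- do.call(rbind, lapply(sort(unique(regs)), function(r) {
    es <- net_effects[regs == r]
    dirs <- vapply(es, `[[`, "", "direction")
    n_act <- sum(dirs == "activator"); n_rep <- sum(dirs == "repressor")
    n_coh <- sum(vapply(es, `[[`, TRUE, "coherent"))
    call <- "NS"
    if (n_coh >= 1L) {
      if (n_act > n_coh / 2) call <- "activator"
      if (n_rep > n_coh / 2) call <- "repressor"
    }
    data.frame(regulator = r, n_datasets = length(es), n_coherent = n_coh,
               n_activator = n_act, n_repressor = n_rep, call = call,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  list(calls = calls, long = long)
}
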