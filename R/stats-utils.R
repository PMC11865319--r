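#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around the standard BH step-up procedure: adjusted
#' values are clipped to 1 and monotone in the order of the input p-values,
#' and `q[i] >= p[i]` always holds.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of BH-adjusted q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

# One Spearman correlation test. Exact null distribution (no ties, n <
# exact_n) via cor.test; asymptotic t approximation otherwise. Degenerate
# (constant) inputs yield rho = 0, p = 1 rather than NA so that screening
# code can treat them as non-passing.
spearman_test <- function(x, y, exact_n = 10L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations for Spearman")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(stat_result(estimate = 0, p_value = 1, n = n, test_id = "spearman"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n < exact_n && !has_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE,
                         alternative = "two.sided")$p.value
  } else {
    p <- .spearman_p_asymptotic(rho, n)
  }
  stat_result(estimate = rho, p_value = min(p, 1), n = n, test_id = "spearman")
}

.spearman_p_asymptotic <- function(rho, n) {
  p <- rep_len(0, length(rho))
  ok <- abs(rho) < 1
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

# Vectorized Spearman of every row of X against y (asymptotic p). Constant
# rows get rho = 0, p = 1.
row_spearman <- function(X, y) {
  n <- length(y)
  stopifnot(ncol(X) == n, n >= 3L)
  R <- t(apply(X, 1L, rank))
  ry <- rank(y)
  const <- apply(R, 1L, function(r) all(r == r[1L]))
  rho <- rep_len(0, nrow(X))
  p <- rep_len(1, nrow(X))
  if (stats::sd(ry) > 0 && any(!const)) {
    rc <- suppressWarnings(as.vector(stats::cor(t(R[!const, , drop = FALSE]), ry)))
    rho[!const] <- rc
    capped <- pmin(pmax(rc, -1), 1)
    p[!const] <- ifelse(abs(capped) >= 1, 0, .spearman_p_asymptotic(capped, n))
  }
  data.frame(gene_id = rownames(X), rho = rho, p_rho = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized two-sided Welch t-test of rows of X between two sample groups,
# returning the mean difference (group1 - group0) and p. Rows with zero
# variance in both groups: p = 1 if the means agree, 0 otherwise.
row_welch <- function(X, group1, group0) {
  X1 <- X[, group1, drop = FALSE]
  X0 <- X[, group0, drop = FALSE]
  n1 <- ncol(X1); n0 <- ncol(X0)
  stopifnot(n1 >= 2L, n0 >= 2L)
  m1 <- rowMeans(X1); m0 <- rowMeans(X0)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((X0 - m0)^2) / (n0 - 1)
  diff <- m1 - m0
  se2 <- v1 / n1 + v0 / n0
  p <- rep_len(1, nrow(X))
  pos <- se2 > 0
  if (any(pos)) {
    tt <- diff[pos] / sqrt(se2[pos])
    df <- se2[pos]^2 / ((v1[pos] / n1)^2 / (n1 - 1) + (v0[pos] / n0)^2 / (n0 - 1))
    p[pos] <- 2 * stats::pt(-abs(tt), df)
  }
  p[!pos & diff != 0] <- 0
  data.frame(gene_id = rownames(X), log2fc = diff, p_dge = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' A single statistical test result
#'
#' Lightweight container for an effect estimate (effect size or rho), its
#' p-value, an optional BH q-value, the sample count, and the identity of the
#' test that produced it.
#'
#' @param estimate numeric effect size or correlation.
#' @param p_value p-value in \[0, 1\].
#' @param n sample count behind the estimate.
#' @param test_id one of `student_t`, `welch_t`, `wilcoxon`, `spearman`,
#'   `hypergeometric`, `one_sample_wilcoxon`.
#' @param q_value optional BH-adjusted p.
#' @return a list of class `stat_result`.
#' @export
stat_result <- function(estimate, p_value, n, test_id,
                        q_value = NA_real_) {
  test_id <- match.arg(test_id, c("student_t", "welch_t", "wilcoxon",
                                  "spearman", "hypergeometric",
                                  "one_sample_wilcoxon"))
  if (is.na(p_value) || p_value < 0 || p_value > 1)
    stop("p_value must lie in [0, 1]")
  structure(list(estimate = estimate, p_value = p_value, q_value = q_value,
                 n = n, test_id = test_id),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4g, p = %.3g, n = %d\n",
              x$test_id, x$estimate, x$p_value, x$n))
  invisible(x)
}

# One-sided hypergeometric overrepresentation p-value: probability of
# observing >= k annotated genes when drawing n from a background of N genes
# of which K are annotated.
hypergeom_enrichment_p <- function(k, n, K, N) {
  stopifnot(k <= n, K <= N, n <= N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
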