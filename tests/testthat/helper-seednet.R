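# Shared fixtures and independent oracles for the test suite.

# Small dense expression matrix with default ids.
tiny_em <- function(values, unit = "TPM", genes = NULL, samples = NULL, ...) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, unit = unit, ...)
}

# Independent BH step-up oracle: q_i = min over all j with p_j ranked at or
# above p_i of p_j * m / rank_j (ties resolved as p.adjust does, via the
# ordering of sorted p), clipped at 1. Deliberately a naive double loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(o == i)           # rank of p[i]
    cands <- vapply(ri:m, function(r) p[o[r]] * m / r, 0)
    q[i] <- min(1, cands)
  }
  q
}

# Brute-force strict-median stratification: a sample is High iff its value is
# strictly greater than at least ceiling(n/2) of the values (i.e. it lies in
# the strict upper half).
oracle_stratify <- function(v) {
  n <- length(v)
  above <- vapply(v, function(x) sum(x > v), 0L)
  unname(ifelse(above >= ceiling(n / 2), "High", "Low"))
}

# Minimal hand-built coexpression_table carrying only what build_network
# reads.
fake_screen_table <- function(genes, passes, seed_gene = "SEED",
                              condition = "c") {
  structure(data.frame(gene_id = genes, passes = passes,
                       stringsAsFactors = FALSE),
            condition = condition, seed_gene = seed_gene,
            thresholds = list(fc = 0, p = 0.05, rho = 0.3),
            class = c("coexpression_table", "data.frame"))
}

# Hand-built effect table for net-effect rule tests.
fake_effects <- function(genes, effects, ps, regulator = "TFx",
                         dataset = "ds1") {
  structure(data.frame(gene_id = genes, effect = effects, p = ps,
                       test_id = "student_t", stringsAsFactors = FALSE),
            regulator = regulator, dataset = dataset, missing = character(0),
            class = c("effect_table", "data.frame"))
}

# Independent recomputation of the coherence / direction rule (seed
# significance, strict sign majority, network-side signed-rank gate).
oracle_net_decision <- function(seed_eff, seed_p, net_eff, alpha = 0.05,
                                majority = 0.5, network_alpha = alpha) {
  s <- sign(seed_eff)
  ok <- seed_p < alpha && s != 0 && mean(sign(net_eff) == s) > majority
  if (ok && !is.na(network_alpha)) {
    wp <- if (all(net_eff == 0)) 1 else
      suppressWarnings(stats::wilcox.test(net_eff, mu = 0)$p.value)
    ok <- wp < network_alpha && sign(stats::median(net_eff)) == s
  }
  if (!ok) return("NS")
  if (s < 0) "activator" else "repressor"
}

# Fixture annotation table shipped with the package (44-gene published
# network, 22 mitochondrial members).
dbi_annotation <- function() {
  utils::read.delim(system.file("extdata", "dbi_network_annotation.tsv",
                                package = "seednet"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
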