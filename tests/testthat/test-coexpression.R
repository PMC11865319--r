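test_that("stratification splits at the median with ties going Low", {
  em <- function(v) tiny_em(matrix(v, 1, length(v),
                                   dimnames = list("SEED", NULL)),
                            genes = "SEED")
  s <- stratify_by_seed(em(c(1, 2, 3, 4)), "SEED")
  expect_identical(unname(s), c("Low", "Low", "High", "High"))
  s <- stratify_by_seed(em(c(5, 5, 5, 9)), "SEED")
  expect_identical(unname(s), c("Low", "Low", "Low", "High"))
  s <- stratify_by_seed(em(c(1, 2, 3)), "SEED")
  expect_identical(unname(s), c("Low", "Low", "High"))
  expect_error(stratify_by_seed(em(c(2, 2, 2, 2)), "SEED"), "degenerate")
  expect_error(stratify_by_seed(em(c(1, 2, 3, 4)), "nope"), "absent")
})

test_that("stratification equals brute force on all short integer vectors", {
  for (n in 3:6) {
    grid <- as.matrix(expand.grid(rep(list(1:3), n)))
    for (i in seq_len(nrow(grid))) {
      v <- unname(grid[i, ])
      if (length(unique(v)) == 1L) next
      em <- tiny_em(matrix(v, 1, n, dimnames = list("SEED", NULL)),
                    genes = "SEED")
      if (!any(v > median(v))) {   # strict upper half empty: degenerate
        expect_error(stratify_by_seed(em, "SEED"), "degenerate")
        next
      }
      expect_identical(unname(stratify_by_seed(em, "SEED")),
                       oracle_stratify(v))
    }
  }
})

test_that("condition_screen applies the double filter", {
  set.seed(21)
  n <- 30
  s <- exp(rnorm(n, 3))
  X <- rbind(SEED = s,
             MONO = 2 * s + 1,                  # increasing function of seed
             ANTI = max(s) + 1 - s,             # strictly decreasing
             FLAT = rep(5, n),                  # constant row
             NOISE = exp(rnorm(n, 3)))
  em <- tiny_em(X, genes = rownames(X))
  tab <- condition_screen(em, "SEED")
  row <- function(g) tab[tab$gene_id == g, ]
  expect_equal(row("SEED")$rho, 1)
  expect_true(row("SEED")$passes)
  expect_gt(row("SEED")$log2fc, 0)
  expect_equal(row("ANTI")$rho, -1)
  expect_false(row("ANTI")$passes)
  expect_equal(row("FLAT")$rho, 0)
  expect_equal(row("FLAT")$p_rho, 1)
  expect_equal(row("FLAT")$p_dge, 1)
  expect_false(row("FLAT")$passes)
  expect_true(row("MONO")$passes)
  # passes flag is exactly the conjunction of the four thresholds
  with(tab, expect_identical(passes, log2fc > 0 & p_dge < 0.05 &
                                     rho > 0.3 & p_rho < 0.05))
  # refuses log-scale input
  expect_error(condition_screen(transform_expression(em, "log2p1"), "SEED"),
               "linear")
})

test_that("Spearman rho is invariant under the monotone log transform", {
  set.seed(8)
  em <- tiny_em(matrix(rexp(200, 0.1), 10, 20))
  lin <- unclass(em); lg <- unclass(transform_expression(em, "log2p1"))
  for (i in 2:10)
    expect_equal(cor(lin[1, ], lin[i, ], method = "spearman"),
                 cor(lg[1, ], lg[i, ], method = "spearman"))
})

test_that("noiseless module genes pass the screen in every condition", {
  p <- simulate_panel(sim_config(seed = 5, n_conditions = 3,
                                 n_samples_per_condition = 30, n_genes = 100,
                                 module_size = 10, noise_sd = 0))
  for (m in p$matrices) {
    tab <- condition_screen(m, p$truth$seed_gene)
    expect_true(all(tab$passes[tab$gene_id %in% p$truth$module_gene_ids]))
    expect_false(any(tab$passes[!tab$gene_id %in% p$truth$module_gene_ids]))
  }
})

test_that("build_network equals the set-counting oracle and is monotone", {
  genes <- c("SEED", sprintf("g%02d", 1:30))
  set.seed(33)
  for (rep in 1:1000) {
    n_tab <- sample(3:8, 1)
    masks <- matrix(runif(length(genes) * n_tab) < 0.5, length(genes), n_tab)
    masks[1, ] <- TRUE                      # seed passes its own screen
    tabs <- lapply(seq_len(n_tab), function(j)
      fake_screen_table(genes, masks[, j], condition = paste0("c", j)))
    min_c <- sample(seq_len(n_tab), 1)
    net <- build_network(tabs, min_c)
    support <- rowSums(masks)
    expected <- setdiff(genes[support >= min_c], "SEED")
    expect_setequal(net$members$gene_id, expected)
    expect_identical(unname(net$support_counts[net$members$gene_id]),
                     as.integer(support[match(net$members$gene_id, genes)]))
  }
  # monotone: raising min_conditions never adds members
  tabs <- lapply(1:6, function(j)
    fake_screen_table(genes, runif(length(genes)) < 0.6, condition = paste0("c", j)))
  prev <- build_network(tabs, 1)$members$gene_id
  for (k in 2:6) {
    cur <- build_network(tabs, k)$members$gene_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # boundary: support exactly at min_conditions is a member
  tabs20 <- lapply(1:36, function(j)
    fake_screen_table(c("SEED", "gA", "gB"), c(TRUE, j <= 20, j <= 19),
                      condition = paste0("c", j)))
  net <- build_network(tabs20, 20)
  expect_identical(net$members$gene_id, "gA")
  expect_error(build_network(list(), 1), "empty")
  # ordering: descending support then lexicographic
  tabs_o <- lapply(1:3, function(j)
    fake_screen_table(c("SEED", "gB", "gA", "gC"),
                      c(TRUE, TRUE, TRUE, j == 1), condition = paste0("c", j)))
  expect_identical(build_network(tabs_o, 1)$members$gene_id,
                   c("gA", "gB", "gC"))
})

test_that("validation replicates the discovery panel and tracks missing genes", {
  p <- simulate_panel(sim_config(seed = 6, n_conditions = 3,
                                 n_samples_per_condition = 40, n_genes = 100,
                                 module_size = 10, noise_sd = 0))
  tabs <- lapply(p$matrices, condition_screen, seed_gene = p$truth$seed_gene)
  net <- build_network(tabs, 3)
  # self-consistency: validating on a discovery matrix replicates everything
  v <- validate_network(net, p$matrices[[1]])
  expect_true(all(v$replicated))
  expect_identical(attr(v, "missing"), character(0))
  # a member absent from the matrix is missing, not failed
  x2 <- p$matrices[[2]]
  drop <- net$members$gene_id[1]
  x2b <- expression_matrix(unclass(x2)[setdiff(rownames(x2), drop), ],
                           unit = "TPM")
  v2 <- validate_network(net, x2b)
  expect_identical(attr(v2, "missing"), drop)
  expect_equal(nrow(v2), nrow(net$members) - 1)
  expect_error(validate_network(net, x2b, seed_gene = "nope"), "absent")
})

test_that("a second-species panel sharing the module mostly replicates", {
  cfg <- sim_config(seed = 10, n_conditions = 12, n_samples_per_condition = 50,
                    n_genes = 300, module_size = 20)
  p <- simulate_panel(cfg)
  tabs <- lapply(p$matrices, condition_screen, seed_gene = p$truth$seed_gene)
  net <- build_network(tabs, 7)
  # independent panel sharing the planted module (deeper sampling, as a
  # cross-species compendium would provide)
  vcfg <- sim_config(seed = 10, n_conditions = 12,
                     n_samples_per_condition = 200, n_genes = 300,
                     module_size = 20)
  v <- validate_network(net, simulate_panel(vcfg, truth = p$truth,
                                            n_conditions = 1,
                                            seed_offset = 77)$matrices[[1]])
  expect_gte(mean(v$replicated), 0.9)
})

test_that("permuting the seed row yields an empty network", {
  cfg <- sim_config(seed = 12, n_conditions = 36, n_samples_per_condition = 50,
                    n_genes = 400, module_size = 44)
  p <- simulate_panel(cfg)
  set.seed(99)
  tabs <- lapply(p$matrices, function(m) {
    v <- unclass(m)
    v[p$truth$seed_gene, ] <- sample(v[p$truth$seed_gene, ])
    condition_screen(expression_matrix(v, unit = "TPM"), p$truth$seed_gene)
  })
  expect_equal(nrow(build_network(tabs, 20)$members), 0)
})

test_that("annotation summary counts, fractions and enrichment are exact", {
  ann <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    compartment = rep(c("mitochondrion", "other"), each = 50),
                    category = "other", stringsAsFactors = FALSE)
  net <- network_from_genes("SEED", c("g001", "g002", "g051", "g052"))
  s <- annotate_network(net, ann, ann$gene_id)
  expect_equal(s$n_network, 4)
  expect_equal(s$n_mitochondrial, 2)
  expect_equal(s$frac_mitochondrial, 0.5)
  # exact hypergeometric tail: P(X >= 2), X ~ Hypergeom(N=100, K=50, n=4)
  exact <- sum(vapply(2:4, function(k)
    choose(50, k) * choose(50, 4 - k) / choose(100, 4), 0))
  expect_equal(s$p_mitochondrial, exact)
  # no annotated member -> zero counts, p = 1
  net0 <- network_from_genes("SEED", c("g051", "g052"))
  ann0 <- ann; ann0$compartment <- "other"
  s0 <- annotate_network(net0, ann0, ann$gene_id)
  expect_equal(s0$n_mitochondrial, 0)
  expect_equal(s0$p_mitochondrial, 1)
  expect_error(annotate_network(network_from_genes("SEED", "gX"), ann,
                                ann$gene_id), "background")
})
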