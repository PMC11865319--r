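# Small config used across generator tests: keeps runtimes in seconds.
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_conditions = 4, n_samples_per_condition = 30,
             n_genes = 120, module_size = 12, ...)
}

test_that("simulate_panel is deterministic and honours the planted model", {
  a <- simulate_panel(small_cfg())
  b <- simulate_panel(small_cfg())
  expect_identical(lapply(a$matrices, unclass), lapply(b$matrices, unclass))
  expect_identical(a$truth$loadings, b$truth$loadings)
  # seed gene is in the module, module size as configured
  expect_true(a$truth$seed_gene %in% a$truth$module_gene_ids)
  expect_length(a$truth$module_gene_ids, 12)
  # a different seed changes the data
  c <- simulate_panel(small_cfg(seed = 2))
  expect_false(identical(unclass(a$matrices[[1]]), unclass(c$matrices[[1]])))
})

test_that("noiseless module genes are exactly monotone in the seed", {
  p <- simulate_panel(small_cfg(noise_sd = 0, loading_module = c(1, 1),
                                baseline_log2 = c(6, 10)))
  L <- transform_expression(p$matrices[[1]], "log2p1")
  s <- unclass(L)[p$truth$seed_gene, ]
  for (g in setdiff(p$truth$module_gene_ids, p$truth$seed_gene)[1:5])
    expect_equal(cor(unclass(L)[g, ], s, method = "spearman"), 1)
})

test_that("seed-module rank correlation matches the closed-form oracle", {
  # Single-factor Gaussian model: Pearson rho between seed (loading 0.9) and
  # a module gene with loading a is a*0.9/sqrt((a^2+s^2)(0.81+s^2)); Spearman
  # follows via (6/pi) asin(r/2). High baselines avoid the linear-scale floor.
  cfg <- sim_config(seed = 3, n_conditions = 20, n_samples_per_condition = 200,
                    n_genes = 300, module_size = 20, baseline_log2 = c(6, 10))
  p <- simulate_panel(cfg)
  a <- p$truth$loadings[setdiff(p$truth$module_gene_ids, p$truth$seed_gene)]
  pear <- a * 0.9 / sqrt((a^2 + 1) * (0.81 + 1))
  expected <- mean((6 / pi) * asin(pear / 2))
  meas <- mean(vapply(p$matrices, function(m) {
    L <- unclass(transform_expression(m, "log2p1"))
    s <- L[p$truth$seed_gene, ]
    mean(apply(L[names(a), ], 1, function(g) cor(g, s, method = "spearman")))
  }, 0))
  # absolute Monte-Carlo band: gene estimates within a condition share the
  # factor path, so the effective replication is the 20 conditions
  expect_lt(abs(meas - expected), 0.03)
})

test_that("non-module genes are independent of the seed (rho centred at 0)", {
  p <- simulate_panel(sim_config(seed = 1, n_conditions = 4,
                                 n_samples_per_condition = 100,
                                 n_genes = 500, module_size = 12))
  L <- unclass(transform_expression(p$matrices[[1]], "log2p1"))
  bg <- setdiff(rownames(L), p$truth$module_gene_ids)
  rho <- apply(L[bg, ], 1, cor, y = L[p$truth$seed_gene, ],
               method = "spearman")
  expect_lt(abs(mean(rho)), 0.02)
  expect_equal(sd(rho), 1 / sqrt(99), tolerance = 0.2)
})

test_that("prediction tables hit the exact binomial consensus tail", {
  cfg <- sim_config(seed = 9, n_regulators = 10000, n_true_regulators = 2000,
                    p_detect_true = 0.8, p_detect_false = 0.1)
  sim <- simulate_prediction_tables(cfg)
  sel <- consensus_select(sim$table)
  signs <- sim$truth$regulator_signs
  pass_prob <- function(p, nh = 7, nm = 4) {
    A <- (1 - pbinom(2, nh, p)) * (1 - pbinom(2, nm, p))
    B <- (1 - pbinom(3, nh, p)) * (1 - pbinom(1, nm, p))
    AB <- (1 - pbinom(3, nh, p)) * (1 - pbinom(2, nm, p))
    A + B - AB
  }
  for (grp in list(c("null", 0.1), c("activator|repressor", 0.8))) {
    regs <- names(signs)[grepl(grp[1], signs)]
    k <- sum(sel$selected[match(regs, sel$regulator)])
    pr <- pass_prob(as.numeric(grp[2]))
    band <- qbinom(c(1e-4, 1 - 1e-4), length(regs), pr)
    expect_gte(k, band[1]); expect_lte(k, band[2])
  }
})

test_that("degenerate detection probabilities force the trivial extremes", {
  cfg <- sim_config(seed = 2, n_regulators = 20, n_true_regulators = 6,
                    p_detect_true = 1, p_detect_false = 0)
  sim <- simulate_prediction_tables(cfg)
  sel <- consensus_select(sim$table)
  signs <- sim$truth$regulator_signs
  expect_true(all(sel$h_count[match(names(signs)[signs != "null"],
                                    sel$regulator)] == 7))
  expect_true(all(sel$m_count[match(names(signs)[signs != "null"],
                                    sel$regulator)] == 4))
  expect_true(all(!sel$selected[match(names(signs)[signs == "null"],
                                      sel$regulator)]))
  # no detection at all -> nothing selected downstream
  cfg0 <- sim_config(seed = 2, n_regulators = 20, n_true_regulators = 6,
                     p_detect_true = 0, p_detect_false = 0)
  expect_false(any(consensus_select(simulate_prediction_tables(cfg0)$table)$selected))
})

test_that("perturbation effects are planted at +/- effect size", {
  cfg <- small_cfg(noise_sd = 0.1, effect_size_perturbation = 2,
                   n_regulators = 2, n_true_regulators = 2,
                   n_datasets_per_regulator = 1, baseline_log2 = c(6, 10))
  pan <- simulate_panel(cfg)
  pred <- simulate_prediction_tables(cfg, pan$truth)
  perts <- simulate_perturbations(cfg, pred$truth)
  expect_length(perts, 2)
  for (ds in perts) {
    sgn <- switch(pred$truth$regulator_signs[[ds$regulator]],
                  activator = -1, repressor = +1, 0)
    eff <- perturbation_effects(ds, pred$truth$module_gene_ids)
    expect_equal(mean(eff$effect), sgn * 2, tolerance = 0.15)
  }
  # effect_size 0 -> planted effects null
  cfg0 <- small_cfg(noise_sd = 0.1, effect_size_perturbation = 0,
                    n_regulators = 2, n_true_regulators = 2,
                    n_datasets_per_regulator = 1, baseline_log2 = c(6, 10))
  pred0 <- simulate_prediction_tables(cfg0, simulate_panel(cfg0)$truth)
  eff0 <- perturbation_effects(simulate_perturbations(cfg0, pred0$truth)[[1]],
                               pred0$truth$module_gene_ids)
  expect_lt(max(abs(eff0$effect)), 0.5)
  # determinism
  p1 <- simulate_perturbations(cfg, pred$truth)
  expect_identical(lapply(p1, function(d) unclass(d$matrix)),
                   lapply(perts, function(d) unclass(d$matrix)))
})

test_that("species profiles carry the planted rank correlation", {
  # rho_target = 1: exact
  r1 <- simulate_species_profiles(sim_config(seed = 4, rho_target = 1))
  expect_equal(profile_correlation(r1$pair)$estimate, 1)
  # rho_target 0.6 and 0: mean measured rho over replicates within the
  # Monte-Carlo band of the copula oracle
  for (target in c(0.6, 0)) {
    rhos <- vapply(1:300, function(i) {
      sim <- simulate_species_profiles(sim_config(seed = i, rho_target = target,
                                                  n_profile_units = 40))
      profile_correlation(sim$pair)$estimate
    }, 0)
    se <- sd(rhos) / sqrt(length(rhos))
    expect_equal(mean(rhos), target, tolerance = max(0.05, 4 * se))
  }
})
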