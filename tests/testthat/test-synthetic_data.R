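test_that("config validation catches bad settings", {
  expect_error(sim_config(prop_da = 1.2), "prop_da")
  expect_error(sim_config(n = c(5)), "at least 2 groups")
  expect_error(sim_config(n = c(5, 1)), "at least 2 groups")
  expect_error(sim_config(samp_frac_log_range = list(c(0, -1), c(-1, 0))),
               "ordered")
  # scenario presets: disjoint, overlapping, identical per-group ranges
  lg <- sim_config(scenario = "large")$samp_frac_log_range
  expect_true(lg[[2]][2] <= lg[[1]][1])
  sm <- sim_config(scenario = "small")$samp_frac_log_range
  expect_identical(sm[[1]], sm[[2]])
})

test_that("the generator is a deterministic function of its config", {
  cfg <- sim_config(m = 50, n = c(5, 5), seed = 88)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$true_d, b$true_d)
  expect_identical(a$da_labels, b$da_labels)
})

test_that("generated counts match the Poisson-Gamma moments", {
  # E[O] = exp(d) * theta; the Gamma layer forces Var >= mean
  cfg <- sim_config(m = 30, n = c(150, 150), prop_da = 0,
                    base_mean_range = c(100, 400),
                    samp_frac_log_range = list(c(-1, -1), c(-1, -1)),
                    seed = 13)
  sim <- simulate_dataset(cfg)
  counts <- unclass(sim$table)
  expected <- exp(-1) * sim$true_theta[, 1]
  observed <- rowMeans(counts)
  se <- sqrt(apply(counts, 1, var) / ncol(counts))
  expect_true(all(abs(observed - expected) < 4 * se))
  # overdispersion relative to Poisson
  expect_gt(mean(apply(counts, 1, var) / rowMeans(counts)), 1.5)

  # gamma_shape -> infinity approaches pure Poisson: mean near theta
  cfg2 <- sim_config(m = 20, n = c(200, 200), prop_da = 0,
                     base_mean_range = c(50, 100), gamma_shape = 1e6,
                     samp_frac_log_range = list(c(0, 0), c(0, 0)), seed = 14)
  sim2 <- simulate_dataset(cfg2)
  counts2 <- unclass(sim2$table)
  se2 <- sqrt(apply(counts2, 1, var) / ncol(counts2))
  expect_true(all(abs(rowMeans(counts2) - sim2$true_theta[, 1]) < 3.5 * se2))
})

test_that("a null configuration produces no DA labels and balanced groups", {
  cfg <- sim_config(m = 200, n = c(25, 25), prop_da = 0, scenario = "small",
                    seed = 17)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$da_labels == "null"))
  g1 <- unclass(sim$table)[, 1:25]
  g2 <- unclass(sim$table)[, 26:50]
  tt <- t.test(log(rowMeans(g1) + 1), log(rowMeans(g2) + 1))
  expect_gt(tt$p.value, 0.01)
})

test_that("residual diagnostic scores perfect and group-shifted estimates", {
  sim <- simulate_dataset(sim_config(m = 40, n = c(6, 6), seed = 23))
  perfect <- sampling_fraction_residuals(sim, sim$true_d)
  expect_equal(unname(perfect$centered), rep(0, 12))
  expect_equal(perfect$variance, 0)
  expect_equal(perfect$separation, 0)

  # a constant added to one group is pure separation, no centered residual
  shifted <- sim$true_d
  shifted[sim$design$assignment[names(shifted)] == "grp2"] <-
    shifted[sim$design$assignment[names(shifted)] == "grp2"] + 0.7
  r <- sampling_fraction_residuals(sim, shifted)
  expect_equal(unname(r$centered), rep(0, 12), tolerance = 1e-12)
  expect_equal(r$separation, 0.7)
})

test_that("de-biased offsets track the true sampling fractions", {
  sim <- simulate_dataset(sim_config(m = 500, n = c(15, 15),
                                     scenario = "large", seed = 29))
  res <- suppressWarnings(da_test(sim$table, sim$design))
  d_star <- sampling_fraction_estimates(res)
  expect_gt(cor(d_star[names(sim$true_d)], sim$true_d), 0.95)
})

test_that("the FDR/power harness scores discoveries against the truth", {
  cfg <- sim_config(m = 100, n = c(12, 12), prop_da = 0.1,
                    effect_log_range = c(3, 4), seed = 37)
  ev <- suppressWarnings(
    evaluate_fdr_power(cfg, replicates = 5, seed = 37))
  expect_gt(ev$power, 0.9)      # huge effects, comfortable sample size
  expect_lt(ev$fdr, 0.2)
  expect_length(ev$fdr_rep, 5)

  # single replicate: defined point estimates, undefined SEs
  ev1 <- suppressWarnings(evaluate_fdr_power(cfg, replicates = 1, seed = 38))
  expect_true(is.na(ev1$se_fdr))
  # no planted effects: power undefined
  cfg0 <- sim_config(m = 100, n = c(12, 12), prop_da = 0, seed = 39)
  ev0 <- suppressWarnings(evaluate_fdr_power(cfg0, replicates = 2, seed = 39))
  expect_true(is.na(ev0$power))
})

test_that("write_dataset emits a reproducible triplet with a manifest", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(m = 20, n = c(4, 4), seed = 41))
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_counts(paths[1])
  expect_identical(unclass(back), unclass(sim$table))
  manifest <- utils::read.table(paths[4], header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  expect_identical(manifest$value[manifest$key == "seed"], "41")
  # rerunning the config yields identical files
  paths2 <- write_dataset(simulate_dataset(sim$config), dir, "again")
  expect_identical(readLines(paths[1]), readLines(paths2[1]))
})
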