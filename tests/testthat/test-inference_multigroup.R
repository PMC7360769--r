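test_that("de-biasing is the identity on the reference and shifts the rest", {
  sim <- simulate_dataset(sim_config(m = 50, n = c(5, 5, 5), seed = 21))
  res <- suppressWarnings(da_test(sim$table, sim$design, seed = 1))
  est <- res$estimation
  mg <- res$multigroup
  r <- res$design$reference
  expect_equal(mg$mu_star[, r], est$mu_hat[, r])
  ref_samples <- names(res$design$assignment)[res$design$assignment == r]
  expect_equal(mg$d_star[ref_samples], est$d_hat[ref_samples])
  for (j in names(mg$delta_rj)) {
    expect_equal(mg$mu_star[, j], est$mu_hat[, j] + mg$delta_rj[[j]])
  }

  # zero bias estimates give the identity transform
  mg0 <- debias_multigroup(est, c(grp2 = 0, grp3 = 0), r)
  expect_equal(mg0$mu_star, est$mu_hat)
  expect_equal(mg0$d_star, est$d_hat)
  expect_error(debias_multigroup(est, c(grp2 = 0, grp3 = 0), "nope"),
               "reference")
})

test_that("pairwise statistics are standardized differences, antisymmetric", {
  # hand example: means (1, 3), sigma2 (0.5, 0.5) -> W = 2 / 1 = 2
  est <- structure(list(
    mu_hat = matrix(c(1, 3), 1, 2, dimnames = list("t1", c("A", "B"))),
    sigma2_hat = matrix(c(0.5, 0.5), 1, 2,
                        dimnames = list("t1", c("A", "B"))),
    d_hat = c(s1 = 0)), class = "sf_estimation")
  mg <- structure(list(mu_star = est$mu_hat), class = "multigroup_fit")
  W <- pairwise_stats(mg, est)
  expect_equal(unname(W[1, "A|B"]), -2)

  mg_rev <- structure(list(mu_star = est$mu_hat[, c("B", "A"), drop = FALSE]),
                      class = "multigroup_fit")
  W_rev <- pairwise_stats(mg_rev, est)
  expect_equal(unname(W_rev[1, 1]), -unname(W[1, 1]))

  # equal de-biased means give W = 0
  mg_eq <- structure(list(mu_star = matrix(c(2, 2), 1, 2,
                                           dimnames = dimnames(est$mu_hat))),
                     class = "multigroup_fit")
  expect_equal(unname(pairwise_stats(mg_eq, est)[1, 1]), 0)
})

test_that("the simulated max-statistic null matches the closed form at g = 2", {
  W <- matrix(c(0, 0.5, 1, 1.5, 2, 2.5, 50), ncol = 1,
              dimnames = list(paste0("t", 1:7), "A|B"))
  gt <- global_test(W, B = 10000, seed = 123)
  closed <- 2 * pnorm(-abs(W[, 1]))
  expect_equal(unname(gt$p), unname(closed), tolerance = 0.02)
  expect_equal(gt$p[["t7"]], 0)          # no draw exceeds an extreme statistic
  expect_gt(gt$p[["t1"]], 0.99)          # W = 0 sits at the null's floor
  expect_true(all(gt$p_adj >= gt$p))
})

test_that("the global max statistic is more conservative than its best pair", {
  set.seed(9)
  W <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("t", 1:20), c("A|B", "A|C", "B|C")))
  gt <- global_test(W, B = 10000, seed = 77)
  p_best_pair <- 2 * pnorm(-apply(abs(W), 1, max))
  expect_true(all(gt$p >= p_best_pair - 0.02))
})

test_that("the choice of reference group leaves pairwise contrasts invariant", {
  sim <- simulate_dataset(sim_config(m = 500, n = c(15, 15, 15), seed = 31))
  r1 <- suppressWarnings(da_test(sim$table, sim$design, B = 1000, seed = 4))
  d3 <- group_design(sim$design$assignment, levels = sim$design$group_labels,
                     reference = "grp3")
  r3 <- suppressWarnings(da_test(sim$table, d3, B = 1000, seed = 4))
  shared <- intersect(r1$results$taxon_id, r3$results$taxon_id)
  contrast <- function(res, ids) {
    mu <- res$multigroup$mu_star[ids, ]
    cbind(mu[, "grp1"] - mu[, "grp2"], mu[, "grp1"] - mu[, "grp3"],
          mu[, "grp2"] - mu[, "grp3"])
  }
  diff <- abs(contrast(r1, shared) - contrast(r3, shared))
  expect_lt(max(diff), 0.05)
})

test_that("multigroup pipeline controls the FDR under a global null", {
  # two caveats of the simulated null at Bonferroni depth: B must be large
  # relative to m/alpha (the smallest attainable p is 1/B), and n must be
  # large enough that the estimated-variance t-tails of W match the normal
  # reference in the far tail
  set.seed(61)
  cfg <- sim_config(m = 150, n = c(50, 50, 50), prop_da = 0,
                    base_mean_range = c(100, 1000),
                    samp_frac_log_range = list(c(-1.5, -0.5), c(-2, -1),
                                               c(-1.75, -0.75)),
                    seed = 61)
  R <- 50
  fdp <- numeric(R)
  for (r in seq_len(R)) {
    cfg$seed <- 61 + r
    sim <- simulate_dataset(cfg)
    res <- suppressWarnings(da_test(sim$table, sim$design, B = 100000,
                                    seed = 1000 + r))
    n_rej <- sum(res$results$p_adj < 0.05, na.rm = TRUE)
    fdp[r] <- n_rej / max(1, n_rej)  # all rejections are false under the null
  }
  fdr <- mean(fdp)
  se <- sd(fdp) / sqrt(R)
  expect_lte(fdr, 0.05 + 3 * se)
})

test_that("a structural-zero group pattern flows through the multigroup path", {
  sim <- simulate_dataset(sim_config(m = 60, n = c(8, 8, 8), seed = 71))
  counts <- unclass(sim$table)
  counts["taxon1", sim$design$assignment[colnames(counts)] == "grp1"] <- 0
  res <- suppressWarnings(da_test(abundance_table(counts), sim$design,
                                  B = 500, seed = 2))
  row <- res$results[res$results$taxon_id == "taxon1", ]
  expect_true(row$structural_zero_grp1)
  expect_true(row$decided_by_structural_zero)
  # grp2 vs grp3 is still tested for that taxon
  expect_false(is.na(row[["W_grp2|grp3"]]))
  expect_true(is.na(row[["W_grp1|grp2"]]))
  auto <- res$auto_da[res$auto_da$taxon_id == "taxon1", ]
  expect_setequal(auto$group_present, c("grp2", "grp3"))
})
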