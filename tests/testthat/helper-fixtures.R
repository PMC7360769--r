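# Shared fixtures and independent oracles for the test suite.

# small integer count table with named dims
toy_table <- function(counts = matrix(c(5, 1, 8, 2, 4, 9), nrow = 3),
                      taxa = paste0("OTU", seq_len(nrow(counts))),
                      samples = paste0("s", seq_len(ncol(counts)))) {
  dimnames(counts) <- list(taxa, samples)
  abundance_table(counts)
}

toy_design <- function(n1 = 2, n2 = 2, labels = c("A", "B")) {
  ids <- paste0("s", seq_len(n1 + n2))
  group_design(stats::setNames(rep(labels, c(n1, n2)), ids))
}

# delta series built directly from vectors (bypasses estimation)
make_series <- function(delta, nu0_2, ids = paste0("t", seq_along(delta))) {
  structure(list(delta = delta, nu0_2 = nu0_2, taxon_ids = ids,
                 pair = c("g1", "g2")), class = "delta_series")
}

# fixed-classification mixture "fit" for exercising the WLS stage alone
make_fit <- function(classes, l1 = 0, l2 = 0, kappa1 = 0, kappa2 = 0,
                     delta_em = 0) {
  structure(list(delta_em = delta_em, pi = c(1, 0, 0), l1 = l1, l2 = l2,
                 kappa1 = kappa1, kappa2 = kappa2, classes = classes),
            class = "em_fit")
}

# independent WLS oracle: root of the weighted least-squares score in
# delta for a fixed classification (no closed-form mean used)
brute_force_wls <- function(delta, nu0_2, classes, l1, l2, kappa1, kappa2) {
  l <- c(0, l1, l2)[classes + 1]
  v <- nu0_2 + c(0, kappa1, kappa2)[classes + 1]
  score <- function(d) sum((delta - l - d) / v)
  width <- max(abs(delta)) + abs(l1) + abs(l2) + 10
  stats::uniroot(score, c(-width, width), tol = 1e-14)$root
}

# draw a Delta series from the three-component location mixture
simulate_delta_mixture <- function(m, pi, delta, l1, l2, nu0_2, kappa1,
                                   kappa2) {
  comp <- sample(0:2, m, replace = TRUE, prob = pi)
  mean_c <- delta + c(0, l1, l2)[comp + 1]
  sd_c <- sqrt(nu0_2 + c(0, kappa1, kappa2)[comp + 1])
  make_series(stats::rnorm(m, mean_c, sd_c), rep(nu0_2, m))
}

# two-group dataset guaranteed zero-free (for exact invariance checks)
zero_free_dataset <- function(m = 40, n = c(8, 8), seed = 11) {
  cfg <- sim_config(m = m, n = n, prop_da = 0.1,
                    base_mean_range = c(500, 1500), gamma_shape = 10,
                    samp_frac_log_range = list(c(-0.4, 0), c(-0.8, -0.4)),
                    seed = seed)
  sim <- simulate_dataset(cfg)
  stopifnot(all(unclass(sim$table) > 0))
  sim
}
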