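#' Configuration of the Poisson-Gamma simulator
#'
#' The generator draws ecosystem-scale absolute abundances from a Gamma
#' layer around per-group taxon means, then thins them through per-sample
#' sampling fractions with a Poisson layer:
#' A_ijk ~ Gamma(mean theta_ij, shape `gamma_shape`), d_jk ~ Uniform over a
#' per-group log range, O_ijk ~ Poisson(exp(d_jk) * A_ijk). A chosen
#' fraction of taxa is differentially abundant, with log fold changes drawn
#' uniformly from `effect_log_range` and direction split 50/50 so the DA
#' taxa do not add a net load confound beyond the designed one.
#'
#' The `scenario` presets control how strongly the sampling fractions are
#' confounded with group: `"large"` gives disjoint per-group log ranges
#' (group 1 at (-1.5, -0.5), each later group shifted down by 1),
#' `"moderate"` overlapping ranges (shift 0.5), `"small"` identical ranges.
#' Explicit `samp_frac_log_range` (list of per-group `c(lo, hi)`) overrides
#' the preset.
#'
#' @param m Number of taxa.
#' @param n Integer vector of per-group sample sizes (length = number of
#'   groups, each at least 2).
#' @param prop_da Fraction of DA taxa in \[0, 1).
#' @param effect_log_range Range of absolute log fold changes for DA taxa.
#' @param base_mean_range Range of baseline ecosystem means theta_i1.
#' @param gamma_shape Shape of the Gamma layer (smaller = more
#'   overdispersion).
#' @param scenario `"large"`, `"moderate"` or `"small"` sampling-fraction
#'   variability preset.
#' @param samp_frac_log_range Optional list of per-group `c(lo, hi)` log
#'   sampling-fraction ranges, overriding `scenario`.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   config.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(m = 500, n = c(20, 30), prop_da = 0.1,
                       effect_log_range = c(1, 2),
                       base_mean_range = c(50, 500), gamma_shape = 2,
                       scenario = c("large", "moderate", "small"),
                       samp_frac_log_range = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  if (!is.numeric(n) || length(n) < 2 || any(n < 2)) {
    stop("`n` must give at least 2 groups with n_j >= 2", call. = FALSE)
  }
  if (prop_da < 0 || prop_da >= 1) {
    stop("`prop_da` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(effect_log_range[1] <= effect_log_range[2],
            base_mean_range[1] <= base_mean_range[2],
            base_mean_range[1] > 0, gamma_shape > 0)
  g <- length(n)
  if (is.null(samp_frac_log_range)) {
    shift <- switch(scenario, large = 1, moderate = 0.5, small = 0)
    samp_frac_log_range <- lapply(seq_len(g) - 1,
                                  function(j) c(-1.5, -0.5) - shift * j)
  }
  if (length(samp_frac_log_range) != g ||
      any(vapply(samp_frac_log_range, function(r) r[1] > r[2], logical(1)))) {
    stop("`samp_frac_log_range` needs one ordered (lo, hi) per group",
         call. = FALSE)
  }
  structure(list(m = m, n = as.integer(n), prop_da = prop_da,
                 effect_log_range = effect_log_range,
                 base_mean_range = base_mean_range,
                 gamma_shape = gamma_shape, scenario = scenario,
                 samp_frac_log_range = samp_frac_log_range,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Generate a Poisson-Gamma dataset with known truth
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_dataset"`:
#'   \describe{
#'     \item{table}{[abundance_table()] of observed counts.}
#'     \item{design}{[group_design()] with groups `grp1`, `grp2`, ...}
#'     \item{true_d}{per-sample true log sampling fraction d_jk.}
#'     \item{true_theta}{m x g matrix of ecosystem means theta_ij.}
#'     \item{da_labels}{per-taxon truth: `"null"`, `"up"` or `"down"`
#'       (direction of group j vs group 1; matrix for 3+ groups).}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m
  g <- length(config$n)
  N <- sum(config$n)
  labs <- paste0("grp", seq_len(g))
  sample_ids <- paste0("s", seq_len(N))
  grp_of <- rep(labs, config$n)

  theta <- matrix(NA_real_, m, g, dimnames = list(paste0("taxon", 1:m), labs))
  theta[, 1] <- stats::runif(m, config$base_mean_range[1],
                             config$base_mean_range[2])
  n_da <- round(config$prop_da * m)
  da_idx <- if (n_da > 0) sample.int(m, n_da) else integer(0)
  labels <- matrix("null", m, g, dimnames = dimnames(theta))
  for (j in seq_len(g)[-1]) {
    theta[, j] <- theta[, 1]
    if (n_da > 0) {
      u <- stats::runif(n_da, config$effect_log_range[1],
                        config$effect_log_range[2])
      sign <- sample(c(-1, 1), n_da, replace = TRUE)
      theta[da_idx, j] <- theta[da_idx, 1] * exp(sign * u)
      labels[da_idx, j] <- ifelse(sign > 0, "up", "down")
    }
  }

  d <- numeric(N)
  for (j in seq_len(g)) {
    rng <- config$samp_frac_log_range[[j]]
    d[grp_of == labs[j]] <- stats::runif(config$n[j], rng[1], rng[2])
  }
  names(d) <- sample_ids

  shape <- config$gamma_shape
  counts <- matrix(0L, m, N, dimnames = list(rownames(theta), sample_ids))
  for (k in seq_len(N)) {
    th <- theta[, match(grp_of[k], labs)]
    A <- stats::rgamma(m, shape = shape, scale = th / shape)
    counts[, k] <- stats::rpois(m, exp(d[k]) * A)
  }

  da_labels <- if (g == 2) stats::setNames(labels[, 2], rownames(theta)) else labels
  structure(list(
    table = abundance_table(counts),
    design = group_design(stats::setNames(grp_of, sample_ids), levels = labs),
    true_d = d, true_theta = theta, da_labels = da_labels,
    config = config), class = "sim_dataset")
}

#' Sampling-fraction residual diagnostic
#'
#' Measures how well an estimated per-sample log sampling fraction tracks
#' the truth: raw residuals res_jk = d-est_jk - d_jk, centered residuals
#' subtract each group's mean residual. A normalization that removes the
#' group-level bias has a small group-separation score (the largest
#' absolute difference between group means of the raw residuals); a precise
#' one has small centered-residual variance. Use the de-biased offsets
#' `d_star` for the method's own estimate and [tss_log_depth()] for the
#' library-size (total-sum scaling) baseline.
#'
#' @param dataset A `sim_dataset`.
#' @param d_est Named per-sample estimate of the log sampling fraction.
#' @return List: `raw`, `centered`, `variance` (of centered residuals),
#'   `separation` (group-separation score).
#' @export
sampling_fraction_residuals <- function(dataset, d_est) {
  d_true <- dataset$true_d
  if (!all(names(d_true) %in% names(d_est))) {
    stop("d_est is missing sample(s)", call. = FALSE)
  }
  res <- d_est[names(d_true)] - d_true
  grp <- dataset$design$assignment[names(d_true)]
  grp_means <- tapply(res, grp, mean)
  centered <- stats::setNames(as.numeric(res - grp_means[grp]),
                              names(d_true))
  sep <- max(abs(outer(as.numeric(grp_means), as.numeric(grp_means), "-")))
  list(raw = res, centered = centered,
       variance = stats::var(unname(centered)), separation = unname(sep))
}

#' Library-size baseline estimate of the log sampling fraction
#'
#' Total-sum-scaling proxy: the log library size, centered over all
#' samples. Ignores microbial load, so it fails whenever load differs
#' between groups.
#'
#' @param table An [abundance_table()].
#' @return Named per-sample vector.
#' @export
tss_log_depth <- function(table) {
  ld <- log(library_sizes(table))
  ld - mean(ld)
}

#' De-biased sampling-fraction estimates from a fitted analysis
#'
#' Convenience accessor: for a two-group fit, applies the reference-based
#' transform d*_jk = d_jk - delta_rj with the first group as reference so
#' the estimates are comparable across groups (up to one overall constant).
#'
#' @param res A [da_test()] result.
#' @return Named per-sample vector of de-biased log sampling-fraction
#'   estimates.
#' @export
sampling_fraction_estimates <- function(res) {
  stopifnot(inherits(res, "da_test"))
  if (!is.null(res$multigroup)) return(res$multigroup$d_star)
  design <- res$design
  labs <- design$group_labels
  d <- res$estimation$d_hat
  j2 <- labs[labs != design$reference]
  d[group_samples(design, j2)] <- d[group_samples(design, j2)] - res$delta_em
  d
}

#' FDR and power of the full pipeline over simulation replicates
#'
#' Runs the simulator and [da_test()] `replicates` times and scores the
#' discoveries against the generator's truth. A discovery is a taxon with
#' adjusted p below `alpha` (taxa auto-decided by structural zeros count as
#' discoveries). Per replicate the false discovery proportion is
#' FP / max(1, discoveries) and power is TP / number of DA taxa; the
#' summaries are means over replicates with standard errors
#' sd / sqrt(replicates).
#'
#' @param config A [sim_config()] (two groups).
#' @param replicates Number of replicates (at least 10 for SEs to mean
#'   much; 1 allowed, with `NA` SEs).
#' @param alpha Significance level (default 0.05).
#' @param adjust Multiplicity adjustment (default `"bonferroni"`).
#' @param statistic Passed to [da_test()].
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List of class `"fdr_power"`: `fdr`, `power`, `se_fdr`,
#'   `se_power`, and per-replicate vectors `fdr_rep`, `power_rep`.
#' @export
evaluate_fdr_power <- function(config, replicates = 100, alpha = 0.05,
                               adjust = "bonferroni", statistic = "auto",
                               seed = config$seed) {
  stopifnot(replicates >= 1)
  fdr_rep <- power_rep <- numeric(replicates)
  any_da <- config$prop_da > 0
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- as.integer((as.numeric(seed) * 10007 + r) %%
                             .Machine$integer.max)
    sim <- simulate_dataset(cfg)
    res <- da_test(sim$table, sim$design, alpha = alpha, p_adjust = adjust,
                   statistic = statistic)
    truth_da <- sim$da_labels[res$results$taxon_id] != "null"
    found <- !is.na(res$results$p_adj) & res$results$p_adj < alpha
    # taxa dropped as all-group structural zeros never reach the output;
    # DA taxa lost that way count against power
    n_da_total <- sum(sim$da_labels != "null")
    fdr_rep[r] <- sum(found & !truth_da) / max(1, sum(found))
    power_rep[r] <- if (any_da) sum(found & truth_da) / n_da_total else NA_real_
  }
  se <- function(x) {
    if (replicates < 2 || all(is.na(x))) NA_real_
    else stats::sd(x) / sqrt(replicates)
  }
  structure(list(fdr = mean(fdr_rep),
                 power = if (any_da) mean(power_rep) else NA_real_,
                 se_fdr = se(fdr_rep), se_power = se(power_rep),
                 fdr_rep = fdr_rep, power_rep = power_rep,
                 replicates = replicates, alpha = alpha, adjust = adjust),
            class = "fdr_power")
}

#' @export
print.fdr_power <- function(x, ...) {
  cat(sprintf("fdr_power over %d replicates (%s, alpha = %.2g):\n",
              x$replicates, x$adjust, x$alpha))
  cat(sprintf("  FDR   = %.4f (SE %.4f)\n", x$fdr, x$se_fdr))
  cat(sprintf("  power = %.4f (SE %.4f)\n", x$power, x$se_power))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the counts TSV, metadata TSV, per-taxon truth TSV and a manifest
#' recording the full configuration (including the seed), which suffices
#' to reproduce the dataset.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_counts.tsv", "_metadata.tsv",
                                           "_truth.tsv", "_manifest.tsv")))
  write_counts(dataset$table, paths[1])
  meta <- data.frame(sample_id = names(dataset$design$assignment),
                     group = unname(dataset$design$assignment),
                     true_log_sampling_fraction =
                       unname(dataset$true_d[names(dataset$design$assignment)]))
  utils::write.table(meta, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- dataset$da_labels
  truth <- if (is.matrix(lab)) {
    data.frame(taxon_id = rownames(lab), lab, check.names = FALSE)
  } else {
    data.frame(taxon_id = names(lab), da = unname(lab))
  }
  utils::write.table(truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- dataset$config
  manifest <- data.frame(
    key = c("m", "n", "prop_da", "effect_log_range", "base_mean_range",
            "gamma_shape", "scenario", "samp_frac_log_range", "seed"),
    value = c(cfg$m, paste(cfg$n, collapse = ","), cfg$prop_da,
              paste(cfg$effect_log_range, collapse = ","),
              paste(cfg$base_mean_range, collapse = ","),
              cfg$gamma_shape, cfg$scenario,
              paste(vapply(cfg$samp_frac_log_range, paste, "",
                           collapse = ","), collapse = ";"),
              cfg$seed))
  utils::write.table(manifest, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
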