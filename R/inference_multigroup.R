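#' Reference-based de-biasing for three or more groups
#'
#' Each non-reference group j carries a pairwise bias estimate delta_rj
#' (mean log sampling fraction of the reference minus that of group j),
#' obtained from an E-M fit on the taxa testable in both groups of the
#' pair. Group means and offsets are put on the reference group's scale:
#' mu*_ij = mu_ij + delta_rj (identity for j = r) and
#' d*_jk = d_jk - delta_rj (identity for k in r). The de-biased offsets
#' estimate the true log sampling fractions up to one additive constant
#' (the reference group's mean), which is all the data can identify.
#'
#' @param est An `sf_estimation` with variances.
#' @param delta_rj Named numeric vector of bias estimates, one per
#'   non-reference group label.
#' @param reference Reference group label.
#' @return List of class `"multigroup_fit"`: `mu_star` (m x g), `d_star`
#'   (per sample), `delta_rj`, `reference`.
#' @export
debias_multigroup <- function(est, delta_rj, reference) {
  design <- est$design
  labs <- design$group_labels
  if (!reference %in% labs) {
    stop("reference group not in design", call. = FALSE)
  }
  others <- setdiff(labs, reference)
  if (!all(others %in% names(delta_rj))) {
    stop("delta_rj must be named by the non-reference group labels",
         call. = FALSE)
  }
  mu_star <- est$mu_hat
  d_star <- est$d_hat
  for (j in others) {
    mu_star[, j] <- est$mu_hat[, j] + delta_rj[[j]]
    d_star[group_samples(design, j)] <-
      est$d_hat[group_samples(design, j)] - delta_rj[[j]]
  }
  structure(list(mu_star = mu_star, d_star = d_star,
                 delta_rj = delta_rj[others], reference = reference),
            class = "multigroup_fit")
}

#' Pairwise bias-corrected statistics
#'
#' W_{i,jj'} = (mu*_ij - mu*_ij') / sqrt(sigma2_ij + sigma2_ij') for every
#' unordered group pair. Pairs where the taxon is not testable in both
#' groups (or with zero denominator) are `NA`.
#'
#' @param fit A `multigroup_fit` from [debias_multigroup()].
#' @param est The `sf_estimation` with variances.
#' @param testable Optional logical m x g testability matrix.
#' @return Numeric m x n_pairs matrix; columns named `"j|j'"`.
#' @export
pairwise_stats <- function(fit, est, testable = NULL) {
  labs <- colnames(fit$mu_star)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  W <- vapply(pairs, function(pr) {
    denom2 <- est$sigma2_hat[, pr[1]] + est$sigma2_hat[, pr[2]]
    w <- (fit$mu_star[, pr[1]] - fit$mu_star[, pr[2]]) / sqrt(denom2)
    w[!is.na(denom2) & denom2 <= 0] <- NA_real_
    if (!is.null(testable)) w[!(testable[, pr[1]] & testable[, pr[2]])] <- NA_real_
    w
  }, numeric(nrow(fit$mu_star)))
  W <- matrix(W, nrow = nrow(fit$mu_star),
              dimnames = list(rownames(fit$mu_star),
                              vapply(pairs, paste, "", collapse = "|")))
  W
}

#' Max-statistic global test with a simulated null
#'
#' Tests, per taxon, whether any pair of groups differs: the observed
#' statistic is W_i = max over pairs of |W_{i,jj'}|. Its null distribution
#' is built by simulation: per draw, independent standard normals for each
#' pair, combined with the same max-of-absolute rule (a raw-max variant is
#' available via `use_abs = FALSE`). The p-value is the fraction of null
#' draws exceeding the observed statistic (strict inequality; an add-one
#' correction avoiding exact zeros is available). One null sample is shared
#' across all taxa with the same number of available pairs. Bonferroni
#' adjustment is applied across taxa.
#'
#' @param W Pairwise statistic matrix from [pairwise_stats()].
#' @param B Number of null draws (default 1000, minimum 100).
#' @param seed Optional integer seed for the null draws.
#' @param use_abs Combine pairwise draws by max of absolute values
#'   (default) or raw max.
#' @param add_one Use p = (1 + #exceed) / (B + 1) instead of #exceed / B.
#' @return List of class `"global_test"`: `W_global`, `p`, `p_adj`, `B`,
#'   `n_pairs_used`.
#' @export
global_test <- function(W, B = 1000, seed = NULL, use_abs = TRUE,
                        add_one = FALSE) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  avail <- rowSums(!is.na(W))
  W_obs <- apply(W, 1, function(w) {
    if (all(is.na(w))) NA_real_ else max(abs(w), na.rm = TRUE)
  })
  p <- rep(NA_real_, nrow(W))
  for (np in sort(unique(avail[avail > 0]))) {
    draws <- matrix(stats::rnorm(B * np), B, np)
    if (use_abs) draws <- abs(draws)
    null_max <- apply(draws, 1, max)
    idx <- which(avail == np)
    exceed <- vapply(W_obs[idx], function(w) sum(null_max > w), numeric(1))
    p[idx] <- if (add_one) (1 + exceed) / (B + 1) else exceed / B
  }
  names(p) <- rownames(W)
  structure(list(W_global = W_obs, p = p,
                 p_adj = adjust_pvalues(p, "bonferroni"),
                 B = B, n_pairs_used = avail), class = "global_test")
}
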