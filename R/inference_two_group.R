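#' Bias-corrected two-group test statistics
#'
#' For each testable taxon the effect is the bias-corrected log fold change
#' Delta_i - delta-hat. With `statistic = "W"` the bias is the E-M estimate
#' and the standard error is sqrt(sigma2_i1 + sigma2_i2); the statistic is
#' asymptotically standard normal under the null. With `"W_star"` the WLS
#' bias estimate is subtracted instead and its estimation uncertainty is
#' folded into the denominator, which becomes
#' sqrt(sigma2_i1 + sigma2_i2) + sqrt(Var(delta-hat_WLS)) (the printed
#' four-term square root collapses to this sum), a small-sample guard for
#' modest n or a large non-null fraction. `"auto"` picks `"W_star"` when
#' min(n1, n2) < 30 or the fitted non-null mass pi1 + pi2 exceeds 0.5, and
#' `"W"` otherwise.
#'
#' @param series A [delta_series()] for the tested pair.
#' @param fit The [em_fit()] on that series.
#' @param delta_wls,var_wls WLS bias estimate and its variance (from
#'   [wls_delta()] and [var_wls()]).
#' @param statistic `"auto"`, `"W"` or `"W_star"`.
#' @param n_pair Sample sizes of the two groups (used by `"auto"`).
#' @return Data frame: `taxon_id`, `effect`, `se`, `W`, plus the chosen
#'   statistic as attribute `"statistic"`. Taxa with zero standard error
#'   get `NA` statistics with a warning.
#' @export
test_statistics <- function(series, fit, delta_wls, var_wls,
                            statistic = c("auto", "W", "W_star"),
                            n_pair = NULL) {
  statistic <- match.arg(statistic)
  if (statistic == "auto") {
    small_n <- !is.null(n_pair) && min(n_pair) < 30
    many_da <- sum(fit$pi[2:3]) > 0.5
    statistic <- if (small_n || many_da) "W_star" else "W"
  }
  base_se <- sqrt(series$nu0_2)
  if (statistic == "W") {
    effect <- series$delta - fit$delta_em
    se <- base_se
  } else {
    effect <- series$delta - delta_wls
    se <- base_se + sqrt(var_wls)
  }
  zero_se <- se <= 0
  if (any(zero_se)) {
    warning(sum(zero_se), " taxa with zero standard error: W set to NA",
            call. = FALSE)
  }
  W <- ifelse(zero_se, NA_real_, effect / se)
  se[zero_se] <- NA_real_
  out <- data.frame(taxon_id = series$taxon_ids, effect = effect,
                    se = se, W = W, stringsAsFactors = FALSE)
  attr(out, "statistic") <- statistic
  out
}

#' Multiplicity adjustment of p-values
#'
#' Bonferroni (the package default: conservative familywise control, which
#' the method relies on for finite-sample false-discovery control), Holm
#' step-down, or Benjamini-Hochberg step-up. Thin wrapper over
#' [stats::p.adjust()] with results clipped to 1.
#'
#' @param p Vector of p-values in \[0, 1\] (`NA` allowed).
#' @param method `"bonferroni"`, `"holm"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "holm", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", holm = "holm",
                                bh = "BH")[[method]])
}

#' P-values and simultaneous confidence intervals
#'
#' Two-sided normal p-values p_i = 2 (1 - Phi(|W_i|)) and simultaneous
#' (Bonferroni-adjusted) confidence intervals
#' effect_i +/- z_{1 - alpha/(2 m)} * se_i, so the family of intervals has
#' joint coverage 1 - alpha and an interval excludes 0 exactly when the
#' Bonferroni-adjusted test rejects.
#'
#' @param stats_df Output of [test_statistics()].
#' @param alpha Significance level (default 0.05).
#' @param adjust Multiplicity adjustment for `p_adj` (see
#'   [adjust_pvalues()]).
#' @param m Number of tests for the CI multiplier; defaults to the number
#'   of rows.
#' @return `stats_df` with columns `p`, `p_adj`, `ci_lo`, `ci_hi` appended.
#' @export
pvalues_ci <- function(stats_df, alpha = 0.05,
                       adjust = c("bonferroni", "holm", "bh"),
                       m = nrow(stats_df)) {
  stopifnot(alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  p <- 2 * stats::pnorm(-abs(stats_df$W))
  z <- stats::qnorm(1 - alpha / (2 * m))
  stats_df$p <- p
  stats_df$p_adj <- adjust_pvalues(p, adjust)
  stats_df$ci_lo <- stats_df$effect - z * stats_df$se
  stats_df$ci_hi <- stats_df$effect + z * stats_df$se
  stats_df
}
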