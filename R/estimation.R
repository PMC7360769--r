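#' Log-transform an imputed count table
#'
#' Natural log of the (pseudo-count-imputed) counts. Cells belonging to
#' structurally-zero (taxon, group) combinations are excluded: they are set
#' to `NA` and carried as an exclusion mask. Any included cell that is not
#' strictly positive is an error (imputation must run first).
#'
#' @param table An [abundance_table()] after [impute_sampling_zeros()].
#' @param mask Logical m x g structural-zero matrix, or `NULL`.
#' @param design A [group_design()] (required when `mask` is given).
#' @return List of class `"log_abundance"`: `y` (m x N matrix, `NA` at
#'   excluded cells) and `excluded` (logical m x N).
#' @export
log_transform <- function(table, mask = NULL, design = NULL) {
  counts <- unclass(table)
  excluded <- matrix(FALSE, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  if (!is.null(mask)) {
    if (is.null(design)) stop("`design` required when `mask` is given",
                              call. = FALSE)
    for (l in design$group_labels) {
      excluded[mask[, l], group_samples(design, l)] <- TRUE
    }
  }
  bad <- counts <= 0 & !excluded
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive included count at taxon '%s', sample '%s'; impute sampling zeros first",
      rownames(counts)[idx[1]], colnames(counts)[idx[2]]), call. = FALSE)
  }
  y <- log(counts)
  y[excluded] <- NA_real_
  structure(list(y = y, excluded = excluded), class = "log_abundance")
}

#' Least-squares estimates of group means and sample offsets
#'
#' Fits the offset model y_ijk = d_jk + mu_ij + e_ijk by least squares.
#' The per-sample offset (the log sampling fraction up to a per-group
#' constant) is the sample's mean log abundance over taxa minus the group
#' grand mean:
#' d-hat_jk = ybar_.jk - ybar_.j. ; the per-taxon group mean is the
#' within-group sample mean: mu-hat_ij = ybar_ij. . All means run over
#' included (non-excluded) cells only; the group grand mean is the average
#' of the per-sample means, so offsets average to zero within each group
#' exactly.
#'
#' @param y A `log_abundance` from [log_transform()].
#' @param design A [group_design()], aligned with `y`.
#' @return List of class `"sf_estimation"`: `mu_hat` (m x g), `d_hat`
#'   (named per-sample vector), plus bookkeeping used by
#'   [estimate_sigma2()].
#' @export
estimate_mu_d <- function(y, design) {
  ym <- y$y
  labs <- design$group_labels
  d_hat <- stats::setNames(numeric(ncol(ym)), colnames(ym))
  mu_hat <- matrix(NA_real_, nrow(ym), length(labs),
                   dimnames = list(rownames(ym), labs))
  for (l in labs) {
    cols <- group_samples(design, l)
    block <- ym[, cols, drop = FALSE]
    sample_means <- colMeans(block, na.rm = TRUE)
    if (anyNA(sample_means) || any(!is.finite(sample_means))) {
      stop("sample(s) with no included taxa in group ", l, call. = FALSE)
    }
    d_hat[cols] <- sample_means - mean(sample_means)
    mu_hat[, l] <- rowMeans(block, na.rm = TRUE)  # NaN where fully excluded
  }
  structure(list(mu_hat = mu_hat, d_hat = d_hat, design = design),
            class = "sf_estimation")
}

#' Residual variances of the group-mean estimates
#'
#' Mean residual sum of squares of the offset model, on the scale of the
#' variance of the estimated group mean:
#' sigma2-hat_ij = (1/n_ij^2) * sum_k (y_ijk - d-hat_jk - mu-hat_ij)^2,
#' where n_ij is the number of included cells of taxon i in group j (equal
#' to n_j when nothing is excluded). No degrees-of-freedom correction is
#' applied.
#'
#' @param y A `log_abundance`.
#' @param est An `sf_estimation` from [estimate_mu_d()].
#' @param design A [group_design()].
#' @return The `sf_estimation` augmented with `sigma2_hat` (m x g) and
#'   `n_inc` (included cell counts, m x g).
#' @export
estimate_sigma2 <- function(y, est, design) {
  ym <- y$y
  labs <- design$group_labels
  sigma2 <- matrix(NA_real_, nrow(ym), length(labs),
                   dimnames = list(rownames(ym), labs))
  n_inc <- sigma2
  for (l in labs) {
    cols <- group_samples(design, l)
    block <- ym[, cols, drop = FALSE]
    resid <- sweep(block, 2, est$d_hat[cols], "-") - est$mu_hat[, l]
    n_ij <- rowSums(!is.na(block))
    sigma2[, l] <- rowSums(resid^2, na.rm = TRUE) / n_ij^2
    sigma2[n_ij == 0, l] <- NA_real_
    n_inc[, l] <- n_ij
  }
  est$sigma2_hat <- sigma2
  est$n_inc <- n_inc
  est
}

#' Per-taxon mean differences and their null variances for a group pair
#'
#' For the ordered pair (j1, j2): Delta_i = mu-hat_i,j1 - mu-hat_i,j2 and
#' nu0^2_i = sigma2-hat_i,j1 + sigma2-hat_i,j2, restricted to the taxa
#' testable in both groups. Delta is the input of the mixture bias fit.
#'
#' @param est An `sf_estimation` with variances (see [estimate_sigma2()]).
#' @param pair Character vector of two group labels, ordered.
#' @param testable Optional logical m x g matrix from
#'   [structural_zero_decisions()]; when given, only taxa testable in both
#'   groups enter the series.
#' @return List of class `"delta_series"`: `delta`, `nu0_2`, `taxon_ids`,
#'   `pair`.
#' @export
delta_series <- function(est, pair, testable = NULL) {
  stopifnot(length(pair) == 2)
  keep <- rep(TRUE, nrow(est$mu_hat))
  if (!is.null(testable)) {
    keep <- testable[, pair[1]] & testable[, pair[2]]
  }
  keep <- keep & !is.na(est$mu_hat[, pair[1]]) & !is.na(est$mu_hat[, pair[2]])
  delta <- est$mu_hat[keep, pair[1]] - est$mu_hat[keep, pair[2]]
  nu0_2 <- est$sigma2_hat[keep, pair[1]] + est$sigma2_hat[keep, pair[2]]
  structure(list(delta = unname(delta), nu0_2 = unname(nu0_2),
                 taxon_ids = rownames(est$mu_hat)[keep], pair = pair),
            class = "delta_series")
}
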