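#' Settings for the mixture E-M fit
#'
#' @param max_iter Maximum number of E-M iterations (default 100).
#' @param tol Convergence tolerance on the absolute change of the
#'   log-likelihood (default 1e-5).
#' @param init_quantiles Two quantiles of the Delta series used to seed the
#'   down- and up-shifted components (default 0.10 and 0.90).
#' @return List of class `"em_control"`.
#' @export
em_control <- function(max_iter = 100, tol = 1e-5,
                       init_quantiles = c(0.1, 0.9)) {
  stopifnot(max_iter >= 1, tol > 0, length(init_quantiles) == 2,
            init_quantiles[1] < init_quantiles[2])
  structure(list(max_iter = max_iter, tol = tol,
                 init_quantiles = init_quantiles), class = "em_control")
}

# log-densities of the three components at the current parameters:
# component r has mean delta + l_r and variance nu0_2 + kappa_r (l_0 = 0,
# kappa_0 = 0).
em_logdens <- function(delta, nu0_2, par) {
  vapply(1:3, function(r) {
    stats::dnorm(delta, mean = par$delta + par$l[r],
                 sd = sqrt(nu0_2 + par$kappa[r]), log = TRUE)
  }, numeric(length(delta)))
}

em_loglik <- function(delta, nu0_2, par) {
  a <- sweep(em_logdens(delta, nu0_2, par), 2, log(par$pi), "+")
  mx <- apply(a, 1, max)
  sum(mx + log(rowSums(exp(a - mx))))
}

# expected complete-data objective for fixed responsibilities; terms with
# zero responsibility contribute nothing even when log(pi) = -Inf
em_qfun <- function(delta, nu0_2, par, resp) {
  a <- sweep(em_logdens(delta, nu0_2, par), 2, log(par$pi), "+")
  sum(resp[resp > 0] * a[resp > 0])
}

# constrained maximizer of Q over (delta, l1, l2) at fixed kappa and
# responsibilities; l1 <= 0 <= l2. Weighted normal equations give
# delta = T0/S0 and l_r = T_r/S_r - delta; a violated sign constraint pins
# l_r at 0, pooling that component with the null when re-solving delta.
em_update_location <- function(delta_i, nu0_2, par, resp) {
  w <- resp / outer(nu0_2, par$kappa, "+")
  s <- colSums(w)
  t <- colSums(w * delta_i)
  solve_with <- function(pool) {
    # pool: indices of components sharing the null mean (always includes 1)
    d <- sum(t[pool]) / sum(s[pool])
    l <- c(0, 0, 0)
    for (r in setdiff(2:3, pool)) {
      l[r] <- if (s[r] > 0) t[r] / s[r] - d else 0
    }
    list(delta = d, l = l)
  }
  if (s[1] <= 0) return(par[c("delta", "l")])  # no null mass: keep location
  cand <- solve_with(1)
  pool <- 1
  if (cand$l[2] > 0) pool <- c(pool, 2)
  if (cand$l[3] < 0) pool <- c(pool, 3)
  if (length(pool) > 1) {
    cand <- solve_with(pool)
    # re-check the component left free after pooling
    if (cand$l[2] > 0) cand$l[2] <- 0
    if (cand$l[3] < 0) cand$l[3] <- 0
  }
  cand
}

# 1-D maximization of the r-th component's Q contribution over kappa >= 0
em_update_kappa <- function(delta_i, nu0_2, par, resp, r) {
  p <- resp[, r]
  if (sum(p) <= 0) return(par$kappa[r])
  mu_r <- par$delta + par$l[r]
  g <- function(k) {
    v <- nu0_2 + k
    -0.5 * sum(p * (log(v) + (delta_i - mu_r)^2 / v))
  }
  upper <- max(10 * stats::var(delta_i), 1)
  opt <- stats::optimize(g, c(0, upper), maximum = TRUE, tol = 1e-8)
  cand <- c(0, opt$maximum, par$kappa[r])
  cand[which.max(vapply(cand, g, numeric(1)))]
}

#' E-M fit of the three-component Gaussian mixture to mean differences
#'
#' Models the per-taxon mean differences Delta_i as a mixture of a null
#' component centered at the bias delta (taxa equally abundant in the two
#' ecosystems; their apparent difference is pure sampling-fraction bias), a
#' down-shifted component centered at delta + l1 (l1 < 0) and an up-shifted
#' component at delta + l2 (l2 > 0). Component variances are nu0_2 + kappa_r
#' with kappa_r >= 0, so non-null taxa are at least as variable as null
#' ones. Fitting is by generalized E-M: responsibilities from the standard
#' E-step, then blockwise coordinate ascent over mixing proportions,
#' locations (closed form with sign constraints) and kappa (bounded 1-D
#' maximization); every block update is accepted only if it does not
#' decrease the objective, so the log-likelihood trace is non-decreasing.
#'
#' Initialization is deterministic: delta starts at the median of Delta,
#' the shifted components are seeded from the tails below/above the
#' `init_quantiles`, and kappa starts at 0.
#'
#' @param series A [delta_series()].
#' @param control An [em_control()].
#' @return Object of class `"em_fit"`: `delta_em`, `pi` (length 3), `l1`,
#'   `l2`, `kappa1`, `kappa2`, `responsibilities` (m x 3), `classes`
#'   (integer 0/1/2, ties broken toward the null class), `class_sizes`,
#'   `loglik_trace`, `converged`, `iterations`, `taxon_ids`.
#' @export
em_fit <- function(series, control = em_control()) {
  delta_i <- series$delta
  nu0_2 <- pmax(series$nu0_2, 1e-12)
  m <- length(delta_i)
  if (m < 3) stop("need at least 3 taxa to fit the mixture", call. = FALSE)
  if (any(!is.finite(delta_i)) || any(!is.finite(nu0_2))) {
    stop("non-finite Delta or variance in the series", call. = FALSE)
  }

  q <- stats::quantile(delta_i, control$init_quantiles, names = FALSE)
  low <- delta_i < q[1]
  high <- delta_i > q[2]
  d0 <- stats::median(delta_i)
  pi0 <- c(1 - mean(low) - mean(high), mean(low), mean(high))
  pi0 <- pmax(pi0, 1e-8)
  pi0 <- pi0 / sum(pi0)
  l1 <- if (any(low)) min(mean(delta_i[low]) - d0, 0) else 0
  l2 <- if (any(high)) max(mean(delta_i[high]) - d0, 0) else 0
  par <- list(delta = d0, pi = pi0, l = c(0, l1, l2), kappa = c(0, 0, 0))

  trace <- em_loglik(delta_i, nu0_2, par)
  converged <- FALSE
  iter <- 0
  resp <- NULL
  while (iter < control$max_iter) {
    iter <- iter + 1
    # E-step
    a <- sweep(em_logdens(delta_i, nu0_2, par), 2, log(par$pi), "+")
    mx <- apply(a, 1, max)
    resp <- exp(a - mx)
    resp <- resp / rowSums(resp)

    # M-step, blockwise with accept-if-improves
    q_cur <- em_qfun(delta_i, nu0_2, par, resp)

    cand <- par
    cand$pi <- pmax(colMeans(resp), 0)
    cand$pi <- cand$pi / sum(cand$pi)
    q_new <- em_qfun(delta_i, nu0_2, cand, resp)
    if (q_new >= q_cur) {
      par <- cand
      q_cur <- q_new
    }

    loc <- em_update_location(delta_i, nu0_2, par, resp)
    cand <- par
    cand$delta <- loc$delta
    cand$l <- loc$l
    q_new <- em_qfun(delta_i, nu0_2, cand, resp)
    if (q_new >= q_cur) {
      par <- cand
      q_cur <- q_new
    }

    for (r in 2:3) {
      cand <- par
      cand$kappa[r] <- em_update_kappa(delta_i, nu0_2, par, resp, r)
      q_new <- em_qfun(delta_i, nu0_2, cand, resp)
      if (q_new >= q_cur) {
        par <- cand
        q_cur <- q_new
      }
    }

    ll <- em_loglik(delta_i, nu0_2, par)
    trace <- c(trace, ll)
    if (abs(ll - trace[length(trace) - 1]) < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("E-M did not converge in ", control$max_iter,
            " iterations; returning the best fit so far", call. = FALSE)
  }

  # final responsibilities at the accepted parameters
  a <- sweep(em_logdens(delta_i, nu0_2, par), 2, log(par$pi), "+")
  mx <- apply(a, 1, max)
  resp <- exp(a - mx)
  resp <- resp / rowSums(resp)
  classes <- apply(resp, 1, function(p) {
    top <- which(p >= max(p))
    if (1 %in% top) 0L else top[1] - 1L
  })

  structure(list(
    delta_em = par$delta, pi = par$pi,
    l1 = par$l[2], l2 = par$l[3],
    kappa1 = par$kappa[2], kappa2 = par$kappa[3],
    responsibilities = resp, classes = unname(classes),
    class_sizes = vapply(0:2, function(r) sum(classes == r), integer(1)),
    loglik_trace = trace, converged = converged, iterations = iter,
    taxon_ids = series$taxon_ids), class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("em_fit: delta = %.4f; pi = (%.3f, %.3f, %.3f); l = (%.3f, %.3f)\n",
              x$delta_em, x$pi[1], x$pi[2], x$pi[3], x$l1, x$l2))
  cat(sprintf("  class sizes m0/m1/m2 = %d/%d/%d; %d iterations%s\n",
              x$class_sizes[1], x$class_sizes[2], x$class_sizes[3],
              x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# per-taxon class variance (nu0_2 + kappa of the assigned class) and
# location shift (0, l1 or l2) for a fixed classification
wls_parts <- function(series, fit) {
  kap <- c(0, fit$kappa1, fit$kappa2)[fit$classes + 1]
  l <- c(0, fit$l1, fit$l2)[fit$classes + 1]
  list(nu2 = pmax(series$nu0_2, 1e-12) + kap, l = l)
}

#' Weighted-least-squares approximation of the bias
#'
#' Given the E-M classification and the fitted shifts, the bias is
#' re-estimated as a precision-weighted mean of the de-shifted differences:
#' delta-hat_WLS = sum_r sum_{i in C_r} (Delta_i - l_r) / nu_ir^2 divided by
#' the sum of the weights, with l_0 = 0 and nu_ir^2 = nu_i0^2 + kappa_r.
#' Its variance estimator (see [var_wls()]) stands in for the intractable
#' variance of the E-M estimate; the two estimators are very highly
#' correlated.
#'
#' @param series A [delta_series()].
#' @param fit An [em_fit()].
#' @return The scalar WLS bias estimate.
#' @export
wls_delta <- function(series, fit) {
  if (length(series$delta) == 0) stop("empty series", call. = FALSE)
  parts <- wls_parts(series, fit)
  sum((series$delta - parts$l) / parts$nu2) / sum(1 / parts$nu2)
}

#' Variance of the WLS bias estimate
#'
#' Inverse of the summed precisions over the estimated classes,
#' 1 / sum_r sum_{i in C-hat_r} 1 / nu-hat_ir^2, neglecting inter-taxon
#' covariance. On the order of 1/(n * m0): the bias is essentially a mean
#' over the m0 null taxa, each with variance of order 1/n.
#'
#' @inheritParams wls_delta
#' @return The scalar variance estimate.
#' @export
var_wls <- function(series, fit) {
  if (length(series$delta) == 0) stop("empty series", call. = FALSE)
  parts <- wls_parts(series, fit)
  denom <- sum(1 / parts$nu2)
  if (denom <= 0) stop("zero precision denominator", call. = FALSE)
  1 / denom
}
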