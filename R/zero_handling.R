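#' Per-group presence proportions
#'
#' For each taxon i and group j, the fraction of that group's samples in
#' which the taxon was observed at a non-zero count:
#' p-hat_ij = (1/n_j) * sum_k I(O_ijk != 0).
#'
#' @param table An [abundance_table()], aligned to `design`.
#' @param design A [group_design()].
#' @return List of class `"presence_summary"`: `p_hat` (m x g matrix) and
#'   `n` (group sizes).
#' @export
presence_proportions <- function(table, design) {
  labs <- design$group_labels
  p_hat <- vapply(labs, function(l) {
    rowMeans(unclass(table)[, group_samples(design, l), drop = FALSE] != 0)
  }, numeric(nrow(table)))
  p_hat <- matrix(p_hat, nrow = nrow(table),
                  dimnames = list(rownames(table), labs))
  structure(list(p_hat = p_hat, n = design$sizes),
            class = "presence_summary")
}

#' Declare structural zeros
#'
#' A taxon is declared structurally zero (systematically absent) in a group
#' when its presence proportion is zero, or when the lower limit of the
#' normal 95% bound on the presence proportion does not exceed zero:
#' p-hat = 0, or p-hat - z * sqrt(p-hat (1 - p-hat) / n) <= 0.
#'
#' The bound tightens with sample size: at fixed p-hat in (0, 1) there is a
#' threshold n* below which the taxon is declared structural and at or above
#' which it is not.
#'
#' @param summary A `presence_summary` from [presence_proportions()].
#' @param z Critical value of the normal bound (default 1.96, the printed
#'   95% constant).
#' @return Logical m x g matrix, `TRUE` where structurally zero.
#' @examples
#' # boundary cases: p = 0.2, n = 10 is structural; p = 0.5, n = 4 is not
#' ps <- structure(list(p_hat = matrix(c(0.2, 0.5), 2, 1), n = c(g = 10)),
#'                 class = "presence_summary")
#' @export
detect_structural_zeros <- function(summary, z = 1.96) {
  p <- summary$p_hat
  n <- rep(summary$n, each = nrow(p))
  lower <- p - z * sqrt(p * (1 - p) / n)
  mask <- (p == 0) | (lower <= 0)
  dimnames(mask) <- dimnames(p)
  mask
}

#' Automatic decisions implied by structural zeros
#'
#' If a taxon is structurally zero in group j but not in group j', it is
#' declared differentially abundant between j and j' without testing. The
#' taxon remains testable only among the groups where it is present; taxa
#' structurally zero in every group are dropped from the analysis entirely.
#'
#' @param mask Logical m x g matrix from [detect_structural_zeros()].
#' @param design A [group_design()].
#' @return List with:
#'   \describe{
#'     \item{auto_da}{data frame of auto-declared pairs: `taxon_id`,
#'       `group_absent`, `group_present`.}
#'     \item{testable}{logical m x g matrix, `TRUE` where the taxon can be
#'       tested in that group (`!mask`, minus dropped taxa).}
#'     \item{decided}{logical per taxon: at least one auto-declared pair.}
#'     \item{dropped}{logical per taxon: structurally zero in all groups.}
#'   }
#' @export
structural_zero_decisions <- function(mask, design) {
  labs <- design$group_labels
  stopifnot(ncol(mask) == length(labs))
  dropped <- rowSums(mask) == ncol(mask)
  decided <- rowSums(mask) > 0 & !dropped
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  auto <- lapply(pairs, function(pr) {
    differs <- mask[, pr[1]] != mask[, pr[2]]
    if (!any(differs)) return(NULL)
    idx <- which(differs)
    data.frame(taxon_id = rownames(mask)[idx],
               group_absent = ifelse(mask[idx, pr[1]], pr[1], pr[2]),
               group_present = ifelse(mask[idx, pr[1]], pr[2], pr[1]),
               stringsAsFactors = FALSE)
  })
  auto <- do.call(rbind, auto)
  if (is.null(auto)) {
    auto <- data.frame(taxon_id = character(0), group_absent = character(0),
                       group_present = character(0), stringsAsFactors = FALSE)
  }
  testable <- !mask
  testable[dropped, ] <- FALSE
  list(auto_da = auto, testable = testable,
       decided = stats::setNames(decided, rownames(mask)),
       dropped = stats::setNames(dropped, rownames(mask)))
}

#' Impute sampling zeros with a pseudo-count
#'
#' Zeros in groups where a taxon is not structurally zero are treated as
#' sampling zeros (absent from the specimen by chance) and replaced with a
#' small pseudo-count on the raw count scale so that logs are finite.
#' Cells belonging to structurally-zero (taxon, group) combinations are left
#' at zero; downstream estimation excludes them.
#'
#' @param table An [abundance_table()].
#' @param mask Logical m x g structural-zero matrix (or `NULL` for none).
#' @param design A [group_design()].
#' @param pseudo Positive pseudo-count, default 1.
#' @return An [abundance_table()] with sampling zeros imputed.
#' @export
impute_sampling_zeros <- function(table, mask, design, pseudo = 1) {
  if (!is.numeric(pseudo) || length(pseudo) != 1 || pseudo <= 0) {
    stop("`pseudo` must be a positive number", call. = FALSE)
  }
  counts <- unclass(table)
  for (l in design$group_labels) {
    cols <- group_samples(design, l)
    block <- counts[, cols, drop = FALSE]
    zero <- block == 0
    if (!is.null(mask)) zero[mask[, l], ] <- FALSE
    if (any(zero)) {
      block[zero] <- pseudo
      counts[, cols] <- block
    }
  }
  abundance_table(counts)
}
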