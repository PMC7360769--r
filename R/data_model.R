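#' Construct a taxa-by-samples abundance table
#'
#' The central container of the package: a non-negative numeric matrix with
#' taxa in rows and samples in columns, following the microbiome convention.
#' Count tables read from disk must be integer-valued; intermediate tables
#' (for example after pseudo-count imputation) may hold positive reals.
#'
#' @param counts Numeric matrix, taxa in rows, samples in columns. All
#'   entries must be finite and non-negative.
#' @param taxon_ids Character vector of unique taxon identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `colnames(counts)`.
#' @return An object of class `"abundance_table"`: the validated matrix with
#'   `taxon_ids` as rownames and `sample_ids` as colnames.
#' @examples
#' counts <- matrix(c(4, 2, 4, 2), nrow = 2,
#'                  dimnames = list(c("red", "green"), c("A", "B")))
#' tab <- abundance_table(counts)
#' library_sizes(tab)
#' @export
abundance_table <- function(counts, taxon_ids = rownames(counts),
                            sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(taxon_ids) || is.null(sample_ids)) {
    stop("`taxon_ids` and `sample_ids` are required (or set dimnames)",
         call. = FALSE)
  }
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxon_ids) != nrow(counts) ||
      length(sample_ids) != ncol(counts)) {
    stop("id lists do not match matrix dimensions", call. = FALSE)
  }
  dup_t <- unique(taxon_ids[duplicated(taxon_ids)])
  if (length(dup_t) > 0) {
    stop("duplicate taxon id(s): ", paste(dup_t, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts contain missing or non-finite values", call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 taxon_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  dimnames(counts) <- list(taxon_ids, sample_ids)
  structure(counts, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  total counts: %s; zero cells: %.1f%%\n",
              format(sum(x), big.mark = ","), 100 * mean(x == 0)))
  invisible(x)
}

#' @rdname abundance_table
#' @param x An `abundance_table`.
#' @export
library_sizes <- function(x) {
  colSums(unclass(x))
}

#' Microbial load and empirical sampling fractions
#'
#' The sampling fraction of a specimen is the expected fraction of its
#' ecosystem's absolute abundance that was captured in sequencing;
#' empirically it is the library size divided by the microbial load (the
#' total absolute abundance in a unit volume of the ecosystem). These
#' helpers compute both quantities when ecosystem-scale abundances are known
#' (for example in simulations or didactic examples).
#'
#' @param ecosystem Taxa-by-samples matrix of ecosystem absolute abundances.
#' @param observed Taxa-by-samples matrix of observed specimen counts, same
#'   dimensions as `ecosystem`.
#' @return `microbial_load()`: per-sample totals of `ecosystem`.
#'   `sampling_fractions()`: per-sample library size / microbial load.
#' @examples
#' eco <- matrix(c(12, 6, 18, 9), nrow = 2,
#'               dimnames = list(c("red", "green"), c("A", "B")))
#' obs <- matrix(c(4, 2, 4, 2), nrow = 2, dimnames = dimnames(eco))
#' microbial_load(eco)        # 18 27
#' sampling_fractions(obs, eco)  # 1/3 2/9
#' @export
microbial_load <- function(ecosystem) {
  colSums(as.matrix(ecosystem))
}

#' @rdname microbial_load
#' @export
sampling_fractions <- function(observed, ecosystem) {
  observed <- as.matrix(observed)
  ecosystem <- as.matrix(ecosystem)
  stopifnot(all(dim(observed) == dim(ecosystem)))
  colSums(observed) / colSums(ecosystem)
}

#' Construct a group design
#'
#' Maps each sample to one experimental group. Group labels are ordered by
#' first appearance unless `levels` is given; the first label is the default
#' reference group (multigroup de-biasing requires a declared reference).
#'
#' @param assignment Named character vector: names are sample ids, values
#'   are group labels.
#' @param levels Optional character vector fixing the order of group labels.
#' @param reference Optional reference group label; defaults to the first
#'   level.
#' @return An object of class `"group_design"`: list with `assignment`,
#'   `group_labels`, `sizes`, `reference`.
#' @examples
#' gd <- group_design(c(s1 = "MW", s2 = "MW", s3 = "MW", s4 = "VE", s5 = "VE"))
#' gd$sizes
#' @export
group_design <- function(assignment, levels = NULL, reference = NULL) {
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("`assignment` must be named by sample id", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("duplicate sample id(s) in assignment", call. = FALSE)
  }
  assignment <- vapply(assignment, as.character, character(1))
  labs <- if (is.null(levels)) unique(assignment) else as.character(levels)
  if (!all(assignment %in% labs)) {
    stop("assignment contains labels not in `levels`", call. = FALSE)
  }
  if (length(labs) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- vapply(labs, function(l) sum(assignment == l), integer(1))
  if (any(sizes < 2)) {
    stop(sprintf(
      "group(s) with fewer than 2 samples (%s): within-group variance is not estimable",
      paste(labs[sizes < 2], collapse = ", ")), call. = FALSE)
  }
  if (is.null(reference)) reference <- labs[1]
  if (!reference %in% labs) {
    stop("`reference` must be one of the group labels", call. = FALSE)
  }
  structure(list(assignment = assignment, group_labels = labs,
                 sizes = sizes, reference = reference),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("group_design: %d samples in %d groups (reference: %s)\n",
              length(x$assignment), length(x$group_labels), x$reference))
  print(x$sizes)
  invisible(x)
}

group_samples <- function(design, label) {
  names(design$assignment)[design$assignment == label]
}

guess_sep <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (format == "csv") "," else "\t"
}

#' Read a count table from TSV/CSV
#'
#' Expects taxa in rows and samples in columns: a header row of sample ids
#' and a first column of taxon ids. Cells must be non-negative integers;
#' anything else is rejected with the offending row/column named. If your
#' file is samples-in-rows, transpose it explicitly with `transpose = TRUE`
#' (there is deliberately no auto-detection).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"csv"`.
#' @param transpose Set `TRUE` if the file stores samples in rows.
#' @return An [abundance_table()].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv"),
                        transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- guess_sep(path, match.arg(format))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) stop("malformed count table: fewer than 2 columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))),
                 arr.ind = TRUE)
    loc <- if (length(bad) > 0) {
      sprintf(" (row '%s', column '%s')", ids[bad[1, 1]],
              colnames(mat)[bad[1, 2]])
    } else ""
    stop("non-numeric cell in count table", loc, call. = FALSE)
  }
  if (any(mat %% 1 != 0, na.rm = TRUE)) {
    bad <- which(mat %% 1 != 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 ids[bad[1]], colnames(mat)[bad[2]]), call. = FALSE)
  }
  rownames(mat) <- ids
  if (transpose) mat <- t(mat)
  abundance_table(mat)
}

#' Write a count table to TSV/CSV
#'
#' Inverse of [read_counts()]; integer tables round-trip bit-exactly.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @param format `"auto"`, `"tsv"`, or `"csv"`.
#' @export
write_counts <- function(table, path, format = c("auto", "tsv", "csv")) {
  sep <- guess_sep(path, match.arg(format))
  df <- data.frame(taxon_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata and build a group design
#'
#' @param path Path to a TSV/CSV with one row per sample.
#' @param group_column Name of the column holding the group label.
#' @param sample_column Name of the sample-id column; defaults to the first
#'   column.
#' @param format `"auto"`, `"tsv"`, or `"csv"`.
#' @param levels,reference Passed to [group_design()].
#' @param na_action `"drop"` (default) excludes samples with a missing group
#'   label with a warning; `"error"` stops.
#' @return A [group_design()].
#' @export
read_metadata <- function(path, group_column, sample_column = NULL,
                          format = c("auto", "tsv", "csv"),
                          levels = NULL, reference = NULL,
                          na_action = c("drop", "error")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  na_action <- match.arg(na_action)
  sep <- guess_sep(path, match.arg(format))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"",
                          na.strings = c("NA", ""))
  if (is.null(sample_column)) sample_column <- colnames(df)[1]
  for (col in c(sample_column, group_column)) {
    if (!col %in% colnames(df)) {
      stop(sprintf("column '%s' not found; available: %s", col,
                   paste(colnames(df), collapse = ", ")), call. = FALSE)
    }
  }
  ids <- as.character(df[[sample_column]])
  grp <- as.character(df[[group_column]])
  miss <- is.na(grp) | is.na(ids)
  if (any(miss)) {
    if (na_action == "error") {
      stop("missing metadata for sample(s): ",
           paste(ids[miss], collapse = ", "), call. = FALSE)
    }
    warning(sprintf("dropping %d sample(s) with missing metadata: %s",
                    sum(miss), paste(ids[miss], collapse = ", ")),
            call. = FALSE)
    ids <- ids[!miss]
    grp <- grp[!miss]
  }
  group_design(stats::setNames(grp, ids), levels = levels,
               reference = reference)
}

#' Align a count table with a group design
#'
#' Reorders the table's columns to the design's sample order. Under
#' `policy = "intersect"` samples present in only one of the two inputs are
#' dropped with a message; under `"strict"` any mismatch is an error. At
#' least 2 shared samples per group are required.
#'
#' @param table An [abundance_table()].
#' @param design A [group_design()].
#' @param policy `"intersect"` or `"strict"`.
#' @return List with elements `table` and `design`, aligned.
#' @export
align_samples <- function(table, design, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  tab_ids <- colnames(table)
  des_ids <- names(design$assignment)
  shared <- intersect(des_ids, tab_ids)
  if (length(shared) == 0) {
    stop("no shared sample ids between table and design", call. = FALSE)
  }
  extra_tab <- setdiff(tab_ids, des_ids)
  extra_des <- setdiff(des_ids, tab_ids)
  if (policy == "strict" && (length(extra_tab) || length(extra_des))) {
    stop("sample id mismatch under strict policy; table-only: ",
         paste(extra_tab, collapse = ", "), "; design-only: ",
         paste(extra_des, collapse = ", "), call. = FALSE)
  }
  if (length(extra_tab) || length(extra_des)) {
    message(sprintf("align_samples: dropping %d table-only and %d design-only sample(s)",
                    length(extra_tab), length(extra_des)))
  }
  keep <- des_ids[des_ids %in% shared]
  assignment <- design$assignment[keep]
  labs <- design$group_labels[design$group_labels %in% unique(assignment)]
  sizes <- vapply(labs, function(l) sum(assignment == l), integer(1))
  if (any(sizes < 2)) {
    stop("fewer than 2 shared samples in group(s): ",
         paste(labs[sizes < 2], collapse = ", "), call. = FALSE)
  }
  ref <- if (design$reference %in% labs) design$reference else labs[1]
  list(table = abundance_table(unclass(table)[, keep, drop = FALSE]),
       design = group_design(assignment, levels = labs, reference = ref))
}

results_columns <- function(group_labels) {
  c("taxon_id", "effect", "se", "W", "p", "p_adj", "ci_lo", "ci_hi",
    paste0("structural_zero_", group_labels), "decided_by_structural_zero")
}

#' Write per-taxon results to TSV
#'
#' One row per taxon in a stable column order: `taxon_id`, `effect`, `se`,
#' `W`, `p`, `p_adj`, `ci_lo`, `ci_hi`, one `structural_zero_<group>` flag
#' per group, `decided_by_structural_zero`. Missing values are written as
#' `"NA"`; numbers carry 15 significant digits so results round-trip to at
#' least 12.
#'
#' @param results Results data frame (e.g. the `$results` element of a
#'   [da_test()] object).
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- ifelse(is.na(df[[j]]), NA_character_,
                      formatC(df[[j]], digits = 15, format = "g"))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
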