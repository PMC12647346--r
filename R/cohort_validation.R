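#' Background median of a correlation matrix
#'
#' Median over all off-diagonal unordered-pair correlations — the dashed
#' reference line the per-group distributions are compared against.
#' Undefined correlations contribute their stored 0; no exclusion of values
#' equal to 1 is applied here (that exclusion belongs to within-term sets,
#' where trivial duplicates would otherwise dominate tiny terms).
#'
#' @param cm A `correlation_matrix`.
#' @return The median off-diagonal correlation.
#' @export
background_median <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (length(cm$protein_ids) < 2L) stop("need at least 2 proteins")
  stats::median(cm$rho[upper.tri(cm$rho)])
}

.shift_summary <- function(kind, group_values, background, values, excluded) {
  med <- stats::median(values)
  structure(list(kind = kind,
                 group_values = group_values,
                 background_median = background,
                 median_of_groups = med,
                 shift = med - background,
                 values = values,
                 excluded = excluded),
            class = "median_shift_summary")
}

#' @export
print.median_shift_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "median_shift_summary (%s): %d groups (%d excluded)\n",
    "  median of group medians: %.5g\n  background median:       %.5g\n",
    "  shift:                   %+.5g\n"),
    x$kind, nrow(x$group_values), nrow(x$excluded),
    x$median_of_groups, x$background_median, x$shift))
  invisible(x)
}

#' Distribution of per-term correlation medians
#'
#' For every annotation term: restrict the term's protein set to proteins
#' present in the matrix, collect all unordered within-term pair
#' correlations, drop values exactly equal to 1 (equality tested after
#' rounding to `one_digits` decimals, absorbing floating-point images of
#' perfect monotone pairs), and take the median of what remains. Terms with
#' fewer than `min_pairs` surviving values are excluded with a reason. The
#' summary compares the median of these per-term medians against the
#' dataset [background_median()]: functionally coherent annotation shows as
#' a positive shift.
#'
#' @param cm A `correlation_matrix`.
#' @param terms A `term_map` (see [read_term_map()]) or named list of
#'   protein-id vectors.
#' @param min_pairs Minimum surviving pair correlations per term (default 1).
#' @param one_digits Decimal places used when testing equality to 1.
#' @return A `median_shift_summary`; `group_values` has columns `group`,
#'   `n_pairs`, `median_rho`.
#' @export
term_median_distribution <- function(cm, terms, min_pairs = 1L,
                                     one_digits = 12L) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (min_pairs < 1L) stop("'min_pairs' must be >= 1")
  bg <- background_median(cm)
  ids <- cm$protein_ids
  grp <- list(); exc <- list()
  for (tid in names(terms)) {
    members <- intersect(terms[[tid]], ids)
    if (length(members) < 2L) {
      exc[[tid]] <- "fewer than 2 member proteins present in matrix"
      next
    }
    sub <- cm$rho[members, members, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    vals <- vals[round(vals, one_digits) != 1]
    if (length(vals) < min_pairs) {
      exc[[tid]] <- sprintf("only %d pair(s) after excluding rho == 1 (min_pairs = %d)",
                            length(vals), min_pairs)
      next
    }
    grp[[tid]] <- c(n_pairs = length(vals), median_rho = stats::median(vals))
  }
  if (length(grp) == 0L) stop("no term survives the filters")
  gv <- data.frame(group = names(grp),
                   n_pairs = vapply(grp, `[[`, numeric(1), "n_pairs"),
                   median_rho = vapply(grp, `[[`, numeric(1), "median_rho"),
                   stringsAsFactors = FALSE, row.names = NULL)
  ex <- data.frame(group = names(exc),
                   reason = unlist(exc, use.names = FALSE),
                   stringsAsFactors = FALSE)
  if (length(exc) == 0L) ex <- data.frame(group = character(), reason = character())
  .shift_summary("term_medians", gv, bg, gv$median_rho, ex)
}

#' Correlations of annotated protein pairs vs the background
#'
#' Collects the correlation of every pair (e.g. high-confidence
#' synthetic-lethal partners) whose two members are both present in the
#' matrix, and compares the median of those values against the dataset
#' [background_median()]. Pairs with an absent member are reported in
#' `excluded`, never silently dropped.
#'
#' @param cm A `correlation_matrix`.
#' @param pairs A `pair_set` (see [read_pair_list()]).
#' @return A `median_shift_summary`; `group_values` has one row per retained
#'   pair (`group` = "a|b", `n_pairs` = 1, `median_rho` = that pair's rho),
#'   and `values` holds the full rho list for distribution plots.
#' @export
pair_median_shift <- function(cm, pairs) {
  stopifnot(inherits(cm, "correlation_matrix"))
  ids <- cm$protein_ids
  in_a <- pairs$gene_a %in% ids
  in_b <- pairs$gene_b %in% ids
  keep <- in_a & in_b
  if (!any(keep)) stop("no pair has both members in the matrix")
  a <- pairs$gene_a[keep]; b <- pairs$gene_b[keep]
  vals <- cm$rho[cbind(match(a, ids), match(b, ids))]
  gv <- data.frame(group = paste(a, b, sep = "|"), n_pairs = 1L,
                   median_rho = vals, stringsAsFactors = FALSE)
  dropped <- which(!keep)
  ex <- data.frame(
    group = paste(pairs$gene_a[dropped], pairs$gene_b[dropped], sep = "|"),
    reason = ifelse(!in_a[dropped] & !in_b[dropped],
                    "both members absent from matrix",
             ifelse(!in_a[dropped], "gene_a absent from matrix",
                    "gene_b absent from matrix")),
    stringsAsFactors = FALSE)
  .shift_summary("pair_rhos", gv, background_median(cm), vals, ex)
}

#' Write a median-shift summary as TSV files
#'
#' Emits `term_medians.tsv` (or `pair_rhos.tsv` for a pair summary) with the
#' per-group values, and `summary.tsv` with background median, median of
#' group medians and shift — plot-ready inputs for ridge/density plots.
#'
#' @param s A `median_shift_summary`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_median_shift <- function(s, dir) {
  stopifnot(inherits(s, "median_shift_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, paste0(s$kind, ".tsv"))
  .write_tsv(s$group_values, gpath)
  spath <- file.path(dir, "summary.tsv")
  .write_tsv(data.frame(background = s$background_median,
                        median_of_medians = s$median_of_groups,
                        shift = s$shift,
                        n_groups = nrow(s$group_values),
                        n_excluded = nrow(s$excluded)), spath)
  epath <- file.path(dir, "excluded.tsv")
  .write_tsv(s$excluded, epath)
  invisible(c(gpath, spath, epath))
}
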