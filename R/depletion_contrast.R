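#' Replicate differential protein abundance (volcano statistics)
#'
#' Per protein: intensities are transformed as `log2(value + pseudo)`, the
#' log2 fold change is the mean difference between the two conditions
#' (first factor level minus second), and the p-value comes from a
#' two-sided Welch (unequal-variance) two-sample t test on the transformed
#' replicates, vectorised across proteins. Benjamini–Hochberg adjustment is
#' applied across all proteins. When both groups have zero variance the
#' p-value is 0 if the means differ and 1 if they are equal, by convention.
#'
#' @param e A `replicate_experiment` (see [replicate_experiment()]).
#' @param pseudo Pseudo-count added before the log2 transform; default 1
#'   intensity unit.
#' @param conditions Optional length-2 character vector fixing which
#'   condition is the numerator (first) and denominator (second); defaults
#'   to the factor level order.
#' @return An object of class `depletion_result`: data frame with columns
#'   `protein`, `log2fc`, `p_value`, `q_value`; attributes `conditions`,
#'   `n_reps`, `pseudo`.
#' @export
differential_abundance <- function(e, pseudo = 1, conditions = NULL) {
  stopifnot(inherits(e, "replicate_experiment"))
  if (pseudo <= 0) stop("'pseudo' must be > 0")
  lev <- levels(e$condition)
  if (!is.null(conditions)) {
    if (!setequal(conditions, lev))
      stop("'conditions' must be a permutation of: ", paste(lev, collapse = ", "))
    lev <- conditions
  }
  L <- log2(e$intensities + pseudo)
  A <- L[, e$condition == lev[1L], drop = FALSE]
  B <- L[, e$condition == lev[2L], drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  if (na < 2L || nb < 2L) stop("each condition needs at least 2 replicates")
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1L)
  vb <- rowSums((B - mb)^2) / (nb - 1L)
  lfc <- ma - mb
  se2 <- va / na + vb / nb
  df <- se2^2 / (va^2 / (na^2 * (na - 1L)) + vb^2 / (nb^2 * (nb - 1L)))
  t <- lfc / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(protein = e$protein_ids, log2fc = unname(lfc),
                    p_value = unname(p), q_value = unname(q),
                    stringsAsFactors = FALSE)
  attr(out, "conditions") <- lev
  attr(out, "n_reps") <- c(na, nb)
  attr(out, "pseudo") <- pseudo
  class(out) <- c("depletion_result", "data.frame")
  out
}

#' @export
print.depletion_result <- function(x, ...) {
  lev <- attr(x, "conditions"); nr <- attr(x, "n_reps")
  cat(sprintf("depletion_result: %d proteins; %s (n=%d) vs %s (n=%d)\n",
              nrow(x), lev[1L], nr[1L], lev[2L], nr[2L]))
  cat(sprintf("  q <= 0.05: %d proteins\n", sum(x$q_value <= 0.05)))
  invisible(x)
}

#' Aggregate fold change of a protein set
#'
#' Two raised to the arithmetic mean of the members' log2 fold changes —
#' the geometric-mean fold change, the natural aggregate on the
#' multiplicative intensity scale (e.g. the overall fold change of the
#' cohesin subunits after a depletion).
#'
#' @param d A `depletion_result`.
#' @param members Character vector of protein ids.
#' @return The fold change (> 0), with attribute `absent` listing members
#'   not present in `d` (a warning is raised if any).
#' @export
set_fold_change <- function(d, members) {
  stopifnot(inherits(d, "depletion_result"))
  i <- match(members, d$protein)
  absent <- members[is.na(i)]
  i <- i[!is.na(i)]
  if (length(i) == 0L) stop("no set member present in the result")
  if (length(absent))
    warning("absent set members: ", paste(absent, collapse = ", "))
  structure(2^mean(d$log2fc[i]), absent = absent)
}

#' Annotated volcano table
#'
#' Per protein: log2 fold change, `-log10` raw p, BH q, and a significance
#' flag requiring `|log2fc| >= fc_threshold` and `q <= q_threshold`.
#'
#' @param d A `depletion_result`.
#' @param fc_threshold Absolute log2-fold-change threshold (>= 0).
#' @param q_threshold BH-adjusted p-value threshold (>= 0).
#' @param path Optional TSV output path.
#' @return Data frame with columns `protein`, `log2fc`, `neg_log10_p`,
#'   `q_value`, `significant`.
#' @export
volcano_table <- function(d, fc_threshold = 0.5, q_threshold = 0.05,
                          path = NULL) {
  stopifnot(inherits(d, "depletion_result"))
  if (fc_threshold < 0 || q_threshold < 0) stop("thresholds must be >= 0")
  out <- data.frame(
    protein = d$protein,
    log2fc = d$log2fc,
    neg_log10_p = -log10(d$p_value),
    q_value = d$q_value,
    significant = as.integer(abs(d$log2fc) >= fc_threshold &
                               d$q_value <= q_threshold),
    stringsAsFactors = FALSE)
  if (!is.null(path)) .write_tsv(out, path)
  out
}
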