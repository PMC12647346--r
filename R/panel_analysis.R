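#' Subset a correlation matrix to a named protein panel
#'
#' Extracts the submatrix for a user-ordered panel (e.g. the CCAN proteins
#' plus the NDC80 complex) for heatmap-style inspection. Panel members
#' absent from the matrix are reported, never silently dropped; at least two
#' members must be present.
#'
#' @param cm A `correlation_matrix`.
#' @param panel Ordered character vector of protein ids.
#' @return A list of class `panel_subset`: `panel` (requested order),
#'   `present`, `absent`, `rho` and `defined` submatrices in panel order.
#' @export
subset_panel <- function(cm, panel) {
  stopifnot(inherits(cm, "correlation_matrix"))
  present <- panel[panel %in% cm$protein_ids]
  absent <- setdiff(panel, present)
  if (length(present) < 2L)
    stop("fewer than 2 panel members present in the matrix")
  structure(list(panel = panel, present = present, absent = absent,
                 rho = cm$rho[present, present, drop = FALSE],
                 defined = cm$defined[present, present, drop = FALSE]),
            class = "panel_subset")
}

#' @export
print.panel_subset <- function(x, ...) {
  cat(sprintf("panel_subset: %d/%d panel proteins present\n",
              length(x$present), length(x$panel)))
  if (length(x$absent))
    cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

# type-7 quartiles, the documented convention for all boxplot-style stats
.quartiles <- function(v) {
  q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Per-protein correlation range statistics
#'
#' For each panel protein: median and quartiles of its correlations to every
#' other protein in the full matrix — the "range of all correlations"
#' boxplot. Self-correlation is excluded by default. A protein whose
#' correlations are all stored 0 (e.g. undetected everywhere, so undefined)
#' yields (0, 0, 0).
#'
#' @param cm A `correlation_matrix`.
#' @param panel Character vector of protein ids (must be present).
#' @param include_self Include the self-correlation in each protein's set?
#' @return Data frame with columns `protein`, `median`, `q1`, `q3`, `n`.
#' @export
correlation_range_stats <- function(cm, panel, include_self = FALSE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  missing_ids <- setdiff(panel, cm$protein_ids)
  if (length(missing_ids))
    stop("panel proteins absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  rows <- lapply(panel, function(p) {
    v <- cm$rho[p, ]
    if (!include_self) v <- v[names(v) != p]
    q <- .quartiles(v)
    data.frame(protein = p, median = q[["median"]], q1 = q[["q1"]],
               q3 = q[["q3"]], n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-protein abundance range statistics and detection counts
#'
#' For each panel protein: median and quartiles of its zero-imputed
#' per-sample intensities, plus the number of samples in which it is
#' detected (unmasked and strictly above `detection_threshold`). In the
#' sparse regime typical of centromeric proteins in pan-cancer data — most
#' samples lacking the protein — zero imputation forces the median and the
#' quartiles to 0, which is exactly the behaviour summarised here.
#'
#' @param m An [abundance_matrix()].
#' @param panel Character vector of protein ids (must be present).
#' @param detection_threshold Intensity floor; default 0 means any positive
#'   unmasked value counts as detected.
#' @return Data frame with columns `protein`, `median`, `q1`, `q3`,
#'   `detected`, `n_samples`.
#' @export
abundance_range_stats <- function(m, panel, detection_threshold = 0) {
  stopifnot(inherits(m, "abundance_matrix"))
  missing_ids <- setdiff(panel, m$protein_ids)
  if (length(missing_ids))
    stop("panel proteins absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  mi <- impute_missing_as_zero(m)
  rows <- lapply(panel, function(p) {
    v <- mi$values[p, ]
    det <- sum(!m$mask[p, ] & m$values[p, ] > detection_threshold, na.rm = TRUE)
    q <- .quartiles(v)
    data.frame(protein = p, median = q[["median"]], q1 = q[["q1"]],
               q3 = q[["q3"]], detected = det, n_samples = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean undetected-sample count over a panel
#'
#' The headline sparsity figure: the arithmetic mean, over the panel minus
#' `exclusions`, of the number of samples lacking a detectable level of each
#' protein ("an average of N out of M samples lacked detectable levels").
#'
#' @param m An [abundance_matrix()].
#' @param panel Character vector of protein ids.
#' @param exclusions Panel members to leave out (e.g. the few well-detected
#'   ones).
#' @param detection_threshold Passed to [abundance_range_stats()].
#' @return Mean number of undetected samples per retained panel protein.
#' @export
panel_sparsity <- function(m, panel, exclusions = character(),
                           detection_threshold = 0) {
  retained <- setdiff(panel, exclusions)
  if (length(retained) == 0L) stop("no panel proteins left after exclusions")
  st <- abundance_range_stats(m, retained, detection_threshold)
  mean(st$n_samples - st$detected)
}

#' Write panel outputs as TSV files
#'
#' Emits `panel_matrix.tsv` (the submatrix, heatmap-ready),
#' `correlation_ranges.tsv`, `abundance_ranges.tsv` and `absent.tsv` into
#' `dir`.
#'
#' @param cm A `correlation_matrix`.
#' @param m The matching [abundance_matrix()] (or `NULL` to skip abundance
#'   stats).
#' @param panel Ordered protein ids.
#' @param dir Output directory.
#' @param include_self,detection_threshold Passed through to the stats
#'   functions.
#' @return Invisibly, the paths written.
#' @export
write_panel_summary <- function(cm, m, panel, dir, include_self = FALSE,
                                detection_threshold = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sub <- subset_panel(cm, panel)
  paths <- file.path(dir, "panel_matrix.tsv")
  sub_cm <- structure(list(rho = sub$rho, defined = sub$defined,
                           protein_ids = sub$present),
                      class = "correlation_matrix")
  write_correlation_matrix(sub_cm, paths[1L], defined = FALSE)
  cr <- correlation_range_stats(cm, sub$present, include_self)
  p2 <- file.path(dir, "correlation_ranges.tsv"); .write_tsv(cr, p2)
  paths <- c(paths, p2)
  if (!is.null(m)) {
    ab <- abundance_range_stats(m, intersect(sub$present, m$protein_ids),
                                detection_threshold)
    p3 <- file.path(dir, "abundance_ranges.tsv"); .write_tsv(ab, p3)
    paths <- c(paths, p3)
  }
  p4 <- file.path(dir, "absent.tsv")
  .write_tsv(data.frame(protein = sub$absent), p4)
  invisible(c(paths, p4))
}
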