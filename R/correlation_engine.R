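#' Impute zeros in place of missing abundances
#'
#' Replaces every masked cell's value with 0, keeping the mask for
#' provenance. Undetected proteins are thereby treated as absent (intensity
#' zero) rather than unknown, which is what makes all-vs-all correlation of
#' sparse proteome matrices possible: a protein missing from most samples
#' gets a long run of tied zeros instead of dropping those samples pairwise.
#'
#' @param m An [abundance_matrix()].
#' @return The same matrix with masked values set to 0; unmasked cells are
#'   untouched.
#' @export
impute_missing_as_zero <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  m$values[m$mask] <- 0
  m
}

#' Spearman correlation of two vectors
#'
#' Pearson correlation of the average-rank transforms (ties receive average
#' ranks). Returns `NA` when either rank vector is constant, in which case
#' the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A number in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
spearman_pair <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 2L) stop("need at least 2 observations")
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx * dx)
  sy <- sum(dy * dy)
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum(dx * dy) / sqrt(sx * sy)
  max(-1, min(1, r))
}

#' All-vs-all Spearman co-abundance matrix
#'
#' Computes the Spearman correlation between every pair of protein rows of a
#' zero-imputed abundance matrix. Each row is rank-transformed (average
#' ranks), centred and scaled, and the full matrix is obtained as a single
#' crossproduct, so the result is bitwise identical however the pairs might
#' be chunked. Undefined correlations — any pair involving a protein whose
#' imputed vector is constant, e.g. a fully missing protein — are stored as
#' 0 with `defined == FALSE`, matching the convention of imputing zeros into
#' the correlation matrix itself. The diagonal is 1 for non-constant
#' proteins and stored 0 (undefined) otherwise.
#'
#' @param m An [abundance_matrix()].
#' @param impute If `TRUE` (default) [impute_missing_as_zero()] is applied
#'   first; set `FALSE` if `m` is already imputed (NAs then cause an error).
#' @return An object of class `correlation_matrix`: list with `rho`
#'   (symmetric numeric matrix, entries in `[-1, 1]`), `defined` (logical
#'   matrix), `protein_ids`.
#' @export
spearman_matrix <- function(m, impute = TRUE) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (impute) m <- impute_missing_as_zero(m)
  X <- m$values
  if (anyNA(X)) stop("matrix contains NAs; run impute_missing_as_zero() first")
  if (ncol(X) < 2L) stop("need at least 2 samples")
  R <- t(apply(X, 1L, rank))
  R <- R - rowMeans(R)
  ss <- rowSums(R * R)
  ok <- ss > 0
  Z <- R
  Z[ok, ] <- R[ok, , drop = FALSE] / sqrt(ss[ok])
  Z[!ok, ] <- 0
  rho <- tcrossprod(Z)
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- ifelse(ok, 1, 0)
  defined <- outer(ok, ok, `&`)
  rho[!defined] <- 0
  dimnames(rho) <- list(m$protein_ids, m$protein_ids)
  dimnames(defined) <- dimnames(rho)
  structure(list(rho = rho, defined = defined, protein_ids = m$protein_ids),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  n <- length(x$protein_ids)
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf(
    "correlation_matrix: %d proteins (%d undefined); off-diagonal median %.4g\n",
    n, sum(!diag(x$defined)), stats::median(off)))
  invisible(x)
}

#' @export
dim.correlation_matrix <- function(x) dim(x$rho)

#' Write / read a square correlation matrix as TSV
#'
#' Square layout: header row of protein ids, first column of protein ids,
#' 12-significant-digit values. Undefined entries are stored as 0 in the
#' matrix; the defined mask is written alongside as `<path>.defined.tsv`
#' unless `defined = FALSE`.
#'
#' @param cm A `correlation_matrix`.
#' @param path Output path.
#' @param defined Also write the defined mask next to the matrix?
#' @export
write_correlation_matrix <- function(cm, path, defined = TRUE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  cells <- matrix(.fmt_num(cm$rho), nrow = nrow(cm$rho))
  lines <- c(paste(c("protein_id", cm$protein_ids), collapse = "\t"),
             paste(cm$protein_ids, apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  if (defined) {
    dcells <- matrix(ifelse(cm$defined, "1", "0"), nrow = nrow(cm$rho))
    dlines <- c(paste(c("protein_id", cm$protein_ids), collapse = "\t"),
                paste(cm$protein_ids, apply(dcells, 1L, paste, collapse = "\t"),
                      sep = "\t"))
    writeLines(dlines, paste0(path, ".defined.tsv"))
  }
  invisible(path)
}

#' @rdname write_correlation_matrix
#' @param path Path of a square correlation TSV written by
#'   [write_correlation_matrix()].
#' @export
read_correlation_matrix <- function(path) {
  fields <- .read_delim_checked(path, "\t")
  ids <- fields[[1L]][-1L]
  body <- fields[-1L]
  rho <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(length(ids))))
  dimnames(rho) <- list(vapply(body, `[[`, character(1), 1L), ids)
  dpath <- paste0(path, ".defined.tsv")
  if (file.exists(dpath)) {
    dfields <- .read_delim_checked(dpath, "\t")[-1L]
    defined <- t(vapply(dfields, function(f) f[-1L] == "1", logical(length(ids))))
    dimnames(defined) <- dimnames(rho)
  } else {
    defined <- matrix(TRUE, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  }
  structure(list(rho = rho, defined = defined, protein_ids = ids),
            class = "correlation_matrix")
}

#' Long-format export of all unordered correlation pairs
#'
#' One row per unordered protein pair: `protein_a`, `protein_b`, `rho`,
#' `defined`. With `bait` set, only that protein's pairs are written, sorted
#' by rho descending with a 1-based `rank` column — the layout of a
#' ranked-correlation supplementary table, re-rankable for any protein.
#'
#' @param cm A `correlation_matrix`.
#' @param path Output path.
#' @param bait Optional protein id to restrict and rank by.
#' @param include_self Whether the bait's self-correlation is listed when
#'   `bait` is given.
#' @export
write_correlation_long <- function(cm, path, bait = NULL, include_self = TRUE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (is.null(bait)) {
    ut <- which(upper.tri(cm$rho), arr.ind = TRUE)
    df <- data.frame(
      protein_a = cm$protein_ids[ut[, 1L]],
      protein_b = cm$protein_ids[ut[, 2L]],
      rho = cm$rho[ut],
      defined = as.integer(cm$defined[ut]),
      stringsAsFactors = FALSE
    )
  } else {
    r <- rank_partners(cm, bait, include_self = include_self)
    df <- data.frame(protein_a = bait, protein_b = r$partner,
                     rho = r$rho, rank = r$rank, stringsAsFactors = FALSE)
  }
  .write_tsv(df, path)
}
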