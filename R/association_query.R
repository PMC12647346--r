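#' Rank all proteins by correlation to a bait
#'
#' The core guilt-by-association query: every protein in the matrix is
#' ordered by its Spearman correlation to the bait, descending from positive
#' to negative, with no significance cutoff — the rank itself carries the
#' evidence. Undefined correlations participate with their stored value 0.
#' Ties are broken by partner identifier (ascending) so the ranking is fully
#' deterministic and invariant to the input protein order.
#'
#' @param cm A `correlation_matrix` (see [spearman_matrix()]).
#' @param bait Protein id present in the matrix.
#' @param include_self If `TRUE` (default) the bait itself is listed — it
#'   heads its own table at rank 1 when its self-correlation is defined —
#'   and reported ranks are positions out of the full protein pool.
#' @return An object of class `ranked_associations`: a data frame with
#'   columns `partner`, `rho`, `rank` (1-based, dense), and attributes
#'   `bait` and `include_self`.
#' @examples
#' m <- abundance_matrix(matrix(c(1, 2, 3, 3, 2, 1, 1, 3, 2), 3, 3,
#'   byrow = TRUE, dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3"))))
#' rank_partners(spearman_matrix(m), "A")
#' @export
rank_partners <- function(cm, bait, include_self = TRUE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (!bait %in% cm$protein_ids) {
    near <- utils::head(agrep(bait, cm$protein_ids, value = TRUE,
                              ignore.case = TRUE, max.distance = 0.2), 5L)
    stop("unknown bait '", bait, "'",
         if (length(near)) paste0("; did you mean: ",
                                  paste(near, collapse = ", "), "?") else "")
  }
  rho <- cm$rho[bait, ]
  partner <- cm$protein_ids
  if (!include_self) {
    keep <- partner != bait
    rho <- rho[keep]
    partner <- partner[keep]
  }
  ord <- order(-rho, partner, method = "radix")
  out <- data.frame(partner = partner[ord], rho = unname(rho[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "bait") <- bait
  attr(out, "include_self") <- include_self
  class(out) <- c("ranked_associations", "data.frame")
  out
}

#' @export
print.ranked_associations <- function(x, n = 10L, ...) {
  cat(sprintf("ranked_associations for bait '%s' (%d partners%s)\n",
              attr(x, "bait"), nrow(x),
              if (attr(x, "include_self")) ", self included" else ""))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Rank of one partner in a ranked association list
#'
#' @param r A `ranked_associations` object.
#' @param partner Protein id to look up.
#' @return The 1-based rank, e.g. "ranked 32 of 15,312".
#' @export
partner_rank <- function(r, partner) {
  stopifnot(inherits(r, "ranked_associations"))
  i <- match(partner, r$partner)
  if (is.na(i)) stop("partner '", partner, "' not present in the ranking")
  r$rank[i]
}

#' Top-k association table with set-membership highlights
#'
#' Produces the "top 20/25 correlators" report rows: the first `k` entries
#' of a ranking with an extra `tags` column marking membership of each
#' highlight set (e.g. cohesin subunits), comma-separated when a partner is
#' in several sets.
#'
#' @param r A `ranked_associations` object.
#' @param k Number of rows, `1 <= k <= nrow(r)`.
#' @param highlight Named list of protein-id vectors, or `NULL`.
#' @param path Optional path; when given the table is also written as TSV.
#' @return Data frame with columns `rank`, `partner`, `rho`, `tags`.
#' @export
top_k_table <- function(r, k, highlight = NULL, path = NULL) {
  stopifnot(inherits(r, "ranked_associations"))
  if (k < 1L || k > nrow(r)) stop("'k' must be between 1 and ", nrow(r))
  top <- r[seq_len(k), , drop = FALSE]
  tags <- rep("", k)
  for (nm in names(highlight)) {
    hit <- top$partner %in% highlight[[nm]]
    tags[hit] <- ifelse(nzchar(tags[hit]), paste(tags[hit], nm, sep = ","), nm)
  }
  out <- data.frame(rank = top$rank, partner = top$partner, rho = top$rho,
                    tags = tags, stringsAsFactors = FALSE)
  if (!is.null(path)) .write_tsv(out, path)
  out
}
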