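#' Construct a protein-by-sample abundance matrix
#'
#' The central input container of the package: a numeric matrix of intensities
#' with proteins in rows and samples in columns, together with an explicit
#' missingness mask. Cells that were empty or NA in the source table are
#' masked; their stored value is `NA` until [impute_missing_as_zero()] is
#' applied, after which they hold 0 but remain flagged in the mask for
#' provenance.
#'
#' @param values Numeric matrix with unique, non-empty rownames (protein ids)
#'   and colnames (sample ids). Unmasked entries must be finite and >= 0.
#' @param mask Logical matrix of the same dimension; `TRUE` marks a missing
#'   cell. Defaults to `is.na(values)`.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values`, `mask`, `protein_ids`, `sample_ids`.
#' @examples
#' m <- abundance_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("P1", "P2"), c("S1", "S2", "S3"))))
#' m
#' @export
abundance_matrix <- function(values, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop("'values' must have rownames (protein ids) and colnames (sample ids)")
  if (anyDuplicated(pid))
    stop("duplicate protein ids: ", paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("'mask' must be a logical matrix with the same dimensions as 'values'")
  obs <- values[!mask]
  if (any(!is.finite(obs)))
    stop("unmasked values must be finite")
  if (any(obs < 0))
    stop("negative abundance values are not allowed")
  structure(
    list(values = values, mask = mask, protein_ids = pid, sample_ids = sid),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "abundance_matrix: %d proteins x %d samples (%.1f%% missing%s)\n",
    length(x$protein_ids), length(x$sample_ids),
    100 * mean(x$mask),
    if (any(x$mask) && all(x$values[x$mask] == 0, na.rm = TRUE) &&
        !anyNA(x$values)) ", zero-imputed" else ""
  ))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

# shared reader guts: delimited table, first column = row ids, header = col ids
.read_delim_checked <- function(path, sep) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) stop("empty file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged table: line %d has %d fields, expected %d (%s)",
                 bad, nf[bad], nf[1L], path))
  }
  fields
}

#' Read a wide protein-abundance table
#'
#' Reads a TSV or CSV matrix whose first row holds sample ids and whose first
#' column holds protein ids. Empty cells and any token in `missing_tokens`
#' become masked (missing) cells; everything else must parse as a
#' non-negative number. Gzip-compressed files (`*.gz`) are read transparently.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` or `"csv"`.
#' @param missing_tokens Character vector of cell contents treated as missing.
#' @param transpose If `TRUE` the file is samples-in-rows and is transposed
#'   after reading.
#' @return An [abundance_matrix()] (not yet zero-imputed: masked cells are NA).
#' @seealso [write_abundance_table()], [impute_missing_as_zero()]
#' @export
read_abundance_table <- function(path,
                                 dialect = c("tsv", "csv"),
                                 missing_tokens = c("", "NA", "NaN", "null"),
                                 transpose = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  fields <- .read_delim_checked(path, sep)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("table must have at least one sample column")
  sid <- header[-1L]
  body <- fields[-1L]
  if (length(body) == 0L) stop("table has a header but no data rows: ", path)
  pid <- vapply(body, `[[`, character(1), 1L)
  cells <- t(vapply(body, function(f) f[-1L], character(length(sid))))
  if (length(sid) == 1L) cells <- matrix(cells, ncol = 1L)
  miss <- matrix(cells %in% missing_tokens, nrow = nrow(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !miss & is.na(vals)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("cannot parse cell (line %d, column %d): '%s'",
                 i[1L] + 1L, i[2L] + 1L, cells[i[1L], i[2L]]))
  }
  vals[miss] <- NA_real_
  dimnames(vals) <- list(pid, sid)
  if (transpose) vals <- t(vals)
  abundance_matrix(vals)
}

#' Write an abundance matrix back to disk
#'
#' Masked cells are written as the first element of `missing_token`; values
#' are written with 17 significant digits so that
#' `read_abundance_table(write_abundance_table(m))` is an exact round trip.
#'
#' @param m An [abundance_matrix()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param dialect `"tsv"` or `"csv"`.
#' @param missing_token Token written for masked cells.
#' @export
write_abundance_table <- function(m, path, dialect = c("tsv", "csv"),
                                  missing_token = "NA") {
  stopifnot(inherits(m, "abundance_matrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  cells <- matrix(formatC(m$values, digits = 17, format = "g"),
                  nrow = nrow(m$values))
  cells[m$mask] <- missing_token
  lines <- c(
    paste(c("protein_id", m$sample_ids), collapse = sep),
    paste(m$protein_ids, apply(cells, 1L, paste, collapse = sep), sep = sep)
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a term -> protein annotation map
#'
#' Two-column delimited file `(term_id, protein_id)`, e.g. a flattened
#' GAF-derived GO export. Rows are aggregated into one protein set per term;
#' duplicated rows collapse (set semantics). Proteins absent from any
#' abundance matrix are retained here — filtering happens at use time.
#'
#' @param path Path to the table (optionally gzipped).
#' @param header Set `TRUE` if the first line is a header to skip.
#' @param sep Field separator (default tab).
#' @return A named list of character vectors (class `term_map`); names are
#'   term ids, each element the sorted unique protein set.
#' @export
read_term_map <- function(path, header = FALSE, sep = "\t") {
  fields <- .read_delim_checked(path, sep)
  if (header) fields <- fields[-1L]
  if (length(fields) == 0L) stop("term map has no data rows: ", path)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L] + as.integer(header)
    stop(sprintf("malformed term-map line %d: expected 2 fields", bad))
  }
  term <- vapply(fields, `[[`, character(1), 1L)
  prot <- vapply(fields, `[[`, character(1), 2L)
  tm <- lapply(split(prot, term), function(p) sort(unique(p)))
  if (any(!nzchar(term)) || any(!nzchar(prot)))
    stop("term map contains empty term or protein ids")
  structure(tm[unique(term)], class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  cat(sprintf("term_map: %d terms, %d distinct proteins\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read a synthetic-lethal (or other) protein-pair list
#'
#' CSV/TSV with columns `gene_a`, `gene_b`, `evidence_source` (SynLethDB
#' style). Pairs are canonicalised (lexicographically smaller member first),
#' self-pairs dropped with a warning, duplicates collapsed, and only pairs
#' whose evidence source is in `allowed_sources` are kept — mirroring the
#' restriction to high-reliability low-throughput/CRISPR evidence used when
#' benchmarking co-abundance against synthetic lethality.
#'
#' @param path Path to the table (optionally gzipped).
#' @param allowed_sources Character vector of evidence sources to keep, or
#'   `NULL` to keep all.
#' @param sep Field separator (default comma).
#' @return A data frame (class `pair_set`) with columns `gene_a`, `gene_b`,
#'   `evidence_source`; `gene_a < gene_b` in every row.
#' @export
read_pair_list <- function(path, allowed_sources = NULL, sep = ",") {
  fields <- .read_delim_checked(path, sep)
  header <- fields[[1L]]
  need <- c("gene_a", "gene_b", "evidence_source")
  idx <- match(need, header)
  if (anyNA(idx))
    stop("missing required column(s): ", paste(need[is.na(idx)], collapse = ", "))
  body <- fields[-1L]
  a <- vapply(body, `[[`, character(1), idx[1L])
  b <- vapply(body, `[[`, character(1), idx[2L])
  src <- vapply(body, `[[`, character(1), idx[3L])
  pair_set(a, b, src, allowed_sources = allowed_sources)
}

#' Build a validated pair set from vectors
#'
#' @param gene_a,gene_b Character vectors of pair members.
#' @param evidence_source Character vector of evidence labels (recycled).
#' @param allowed_sources Keep only these sources (`NULL` = all).
#' @return A `pair_set` data frame; see [read_pair_list()].
#' @export
pair_set <- function(gene_a, gene_b, evidence_source = "unknown",
                     allowed_sources = NULL) {
  stopifnot(length(gene_a) == length(gene_b))
  src <- rep_len(as.character(evidence_source), length(gene_a))
  self <- gene_a == gene_b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]; src <- src[!self]
  }
  lo <- pmin(gene_a, gene_b)
  hi <- pmax(gene_a, gene_b)
  if (!is.null(allowed_sources)) {
    keep <- src %in% allowed_sources
    lo <- lo[keep]; hi <- hi[keep]; src <- src[keep]
  }
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(gene_a = lo[!dup], gene_b = hi[!dup],
                    evidence_source = src[!dup],
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Read a two-condition replicate experiment
#'
#' TSV with first column `protein_id` and remaining columns named
#' `condition:replicate` (e.g. `CENPCoff:1 ... wt:4`). Exactly two condition
#' labels are required, each with at least two replicates.
#'
#' @param path Path to the table (optionally gzipped).
#' @return A `replicate_experiment`: list with `intensities` (proteins x
#'   replicate columns), `condition` (factor per column), `protein_ids`.
#' @export
read_replicate_experiment <- function(path) {
  m <- read_abundance_table(path, dialect = "tsv")
  cond <- sub(":.*$", "", m$sample_ids)
  replicate_experiment(m$values, cond)
}

#' Construct a replicate experiment from a matrix
#'
#' @param intensities Numeric proteins x replicates matrix (rownames =
#'   protein ids); NAs are not allowed.
#' @param condition Character/factor of length `ncol(intensities)` with
#'   exactly two levels, each appearing at least twice.
#' @return A `replicate_experiment` object.
#' @export
replicate_experiment <- function(intensities, condition) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (anyNA(intensities)) stop("replicate intensities must not contain NA")
  if (is.null(rownames(intensities))) stop("intensities need protein rownames")
  if (anyDuplicated(rownames(intensities))) stop("duplicate protein ids")
  condition <- factor(as.character(condition))
  if (length(condition) != ncol(intensities))
    stop("one condition label per replicate column is required")
  if (nlevels(condition) != 2L)
    stop("exactly two conditions are required, got: ",
         paste(levels(condition), collapse = ", "))
  if (any(table(condition) < 2L))
    stop("each condition needs at least 2 replicates")
  structure(list(intensities = intensities, condition = condition,
                 protein_ids = rownames(intensities)),
            class = "replicate_experiment")
}

#' @export
print.replicate_experiment <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("replicate_experiment: %d proteins; %s\n",
              nrow(x$intensities),
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = " vs ")))
  invisible(x)
}

#' Read a protein-panel file
#'
#' One protein id per line; blank lines and `#` comments are ignored. Order
#' is preserved (panel order drives heatmap/boxplot order downstream).
#'
#' @param path Path to the panel file.
#' @return Character vector of protein ids.
#' @export
read_panel_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

# fixed decimal format for all emitted tables: 12 significant digits
.fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
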