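# shared fixture builders; everything is generated in code, no data files

# abundance matrix from a plain numeric matrix, default ids
toy_abundance <- function(values, proteins = rownames(values),
                          samples = colnames(values)) {
  if (is.null(proteins)) proteins <- sprintf("P%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(values)))
  dimnames(values) <- list(proteins, samples)
  abundance_matrix(values)
}

# hand-built correlation matrix: named list pairs like list(c("A","B",0.8))
make_cm <- function(ids, pairs = list(), defined = NULL) {
  n <- length(ids)
  rho <- diag(n)
  dimnames(rho) <- list(ids, ids)
  for (p in pairs) {
    rho[p[[1L]], p[[2L]]] <- as.numeric(p[[3L]])
    rho[p[[2L]], p[[1L]]] <- as.numeric(p[[3L]])
  }
  if (is.null(defined))
    defined <- matrix(TRUE, n, n, dimnames = dimnames(rho))
  structure(list(rho = rho, defined = defined, protein_ids = ids),
            class = "correlation_matrix")
}

# random abundance matrix with heavy ties (integer-ish values) and masking
random_ties_abundance <- function(n_prot, n_samp, mask_rate = 0.15) {
  vals <- matrix(sample(0:6, n_prot * n_samp, replace = TRUE) +
                   sample(c(0, 0.5), n_prot * n_samp, replace = TRUE),
                 n_prot, n_samp)
  mask <- matrix(runif(n_prot * n_samp) < mask_rate, n_prot, n_samp)
  vals[mask] <- NA_real_
  toy_abundance(vals)
}

# per-pair Spearman oracle on a zero-imputed matrix, via stats::cor
oracle_spearman <- function(ab) {
  X <- impute_missing_as_zero(ab)$values
  n <- nrow(X)
  rho <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- suppressWarnings(stats::cor(X[i, ], X[j, ], method = "spearman"))
    rho[i, j] <- if (is.na(r)) 0 else r
  }
  rho
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
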