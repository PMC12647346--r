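# run code under a fixed Mersenne-Twister seed without touching global RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# Spearman target -> Pearson weight on the shared latent factor: for a
# bivariate normal copula, rho_S = (6/pi) * asin(rho_P / 2)
.spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Specification of a synthetic proteome cohort
#'
#' Describes a cohort with block-correlated protein modules on top of a
#' log-normal intensity background, with either uniform or
#' abundance-dependent (detection-limit-like) missingness. Defaults give a
#' pan-cancer-like desk-scale cohort: 10 modules of 8 proteins at target
#' within-module Spearman 0.7, 200 background proteins, 300 samples.
#'
#' @param n_modules Number of correlated modules.
#' @param module_size Proteins per module (recycled to `n_modules`), each at
#'   least 2.
#' @param rho_within Target within-module Spearman correlation in `[0, 1)`
#'   (recycled to `n_modules`).
#' @param n_background Independent background proteins.
#' @param n_samples Samples (cell lines / patients).
#' @param log_mu_range,log_sd_range Ranges of per-protein log-intensity
#'   location and scale, drawn uniformly.
#' @param missing Missingness model: `list(type = "none")`,
#'   `list(type = "uniform", rate = r)`, or `list(type = "abundance",
#'   floor = f, steepness = s)` where the detection probability of a cell
#'   with log-intensity `x` is `plogis((x - floor) / steepness)`.
#' @param n_decoy_terms,decoy_size Random decoy terms added to the
#'   module-aligned term map.
#' @param n_pairs,within_fraction Synthetic-lethal-like pair list: total
#'   pairs and the fraction drawn within modules.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_modules = 10L, module_size = 8L, rho_within = 0.7,
                        n_background = 200L, n_samples = 300L,
                        log_mu_range = c(4, 8), log_sd_range = c(0.5, 1.5),
                        missing = list(type = "abundance", floor = 4,
                                       steepness = 1.5),
                        n_decoy_terms = 50L, decoy_size = 8L,
                        n_pairs = 200L, within_fraction = 0.8,
                        seed = 1L) {
  module_size <- rep_len(as.integer(module_size), n_modules)
  rho_within <- rep_len(rho_within, n_modules)
  if (n_modules > 0 && any(module_size < 2L)) stop("module sizes must be >= 2")
  if (any(rho_within < 0 | rho_within >= 1)) stop("rho_within must be in [0, 1)")
  if (n_samples < 2L) stop("need at least 2 samples")
  if (n_background < 0L) stop("n_background must be >= 0")
  if (sum(module_size) + n_background < 2L) stop("need at least 2 proteins")
  if (!missing$type %in% c("none", "uniform", "abundance"))
    stop("unknown missingness type: ", missing$type)
  if (missing$type == "uniform" &&
      (missing$rate < 0 || missing$rate >= 1))
    stop("uniform missingness rate must be in [0, 1)")
  structure(list(n_modules = as.integer(n_modules), module_size = module_size,
                 rho_within = rho_within,
                 n_background = as.integer(n_background),
                 n_samples = as.integer(n_samples),
                 log_mu_range = log_mu_range, log_sd_range = log_sd_range,
                 missing = missing, n_decoy_terms = as.integer(n_decoy_terms),
                 decoy_size = as.integer(decoy_size),
                 n_pairs = as.integer(n_pairs),
                 within_fraction = within_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic proteome cohort
#'
#' Gaussian-copula latent-factor construction: each sample draws one latent
#' factor per module; a protein of module m with weight `w_m` has latent
#' value `sqrt(w_m) * factor_m + sqrt(1 - w_m) * noise`, with `w_m`
#' calibrated so the pairwise Spearman correlation within the module hits
#' its target (`rho_S = (6/pi) asin(rho_P / 2)` for bivariate normals; the
#' copula alone determines Spearman). Intensities are
#' `exp(location + scale * latent)`; missingness is applied per the spec's
#' model. Background proteins are independent. A module-aligned term map
#' (one term per module, ids `MODxx`) plus random decoy terms (`RNDxx`),
#' and a pair list with a planted within-module fraction, are emitted with
#' the ground truth.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `abundance` (an [abundance_matrix()], masked
#'   cells NA until imputation), `terms` (a `term_map`), `pairs` (a
#'   `pair_set`), `truth` (list: `module` named integer vector, NA for
#'   background; `module_members`; `pair_within` logical; `mask`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    n_mod_prot <- sum(spec$module_size)
    n_prot <- n_mod_prot + spec$n_background
    n <- spec$n_samples
    pid <- sprintf("P%04d", seq_len(n_prot))
    sid <- sprintf("S%04d", seq_len(n))
    module <- rep(NA_integer_, n_prot)
    module[seq_len(n_mod_prot)] <- rep(seq_len(spec$n_modules),
                                       times = spec$module_size)
    w <- .spearman_to_pearson(spec$rho_within)
    latent <- matrix(stats::rnorm(n_prot * n), n_prot, n)
    if (spec$n_modules > 0L) {
      factors <- matrix(stats::rnorm(spec$n_modules * n), spec$n_modules, n)
      in_mod <- !is.na(module)
      wi <- w[module[in_mod]]
      latent[in_mod, ] <- sqrt(wi) * factors[module[in_mod], , drop = FALSE] +
        sqrt(1 - wi) * latent[in_mod, , drop = FALSE]
    }
    mu <- stats::runif(n_prot, spec$log_mu_range[1L], spec$log_mu_range[2L])
    sdv <- stats::runif(n_prot, spec$log_sd_range[1L], spec$log_sd_range[2L])
    logint <- mu + sdv * latent
    values <- exp(logint)
    mask <- switch(spec$missing$type,
      none = matrix(FALSE, n_prot, n),
      uniform = matrix(stats::runif(n_prot * n) < spec$missing$rate,
                       n_prot, n),
      abundance = {
        p_det <- stats::plogis((logint - spec$missing$floor) /
                                 spec$missing$steepness)
        matrix(stats::runif(n_prot * n) > p_det, n_prot, n)
      })
    values[mask] <- NA_real_
    dimnames(values) <- list(pid, sid)
    dimnames(mask) <- dimnames(values)
    ab <- abundance_matrix(values, mask)

    members <- split(pid[!is.na(module)], module[!is.na(module)])
    terms <- stats::setNames(members,
                             sprintf("MOD%02d", seq_along(members)))
    if (spec$n_decoy_terms > 0L) {
      decoys <- lapply(seq_len(spec$n_decoy_terms), function(i)
        sort(sample(pid, min(spec$decoy_size, n_prot))))
      names(decoys) <- sprintf("RND%02d", seq_len(spec$n_decoy_terms))
      terms <- c(terms, decoys)
    }
    terms <- structure(lapply(terms, sort), class = "term_map")

    pairs <- NULL
    if (spec$n_pairs > 0L) {
      n_within <- round(spec$n_pairs * spec$within_fraction)
      if (spec$n_modules == 0L) n_within <- 0L
      a <- character(0); b <- character(0); within <- logical(0)
      seen <- character(0)
      draw_within <- function() {
        mlist <- members[[sample(length(members), 1L)]]
        sample(mlist, 2L)
      }
      draw_cross <- function() sample(pid, 2L)
      want <- c(rep(TRUE, n_within), rep(FALSE, spec$n_pairs - n_within))
      for (wv in want) {
        for (try in 1:1000) {
          pr <- if (wv) draw_within() else draw_cross()
          key <- paste(sort(pr), collapse = "\r")
          same_mod <- !is.na(module[match(pr[1L], pid)]) &&
            identical(module[match(pr[1L], pid)], module[match(pr[2L], pid)])
          if (!wv && same_mod) next
          if (!key %in% seen) {
            seen <- c(seen, key)
            a <- c(a, pr[1L]); b <- c(b, pr[2L]); within <- c(within, wv)
            break
          }
        }
      }
      if (length(a) < spec$n_pairs)
        warning("placed only ", length(a), " of ", spec$n_pairs,
                " requested pairs (pool exhausted)")
      # pair_set canonicalises member order but keeps row order, and the
      # draws above contain no self-pairs or duplicates, so rows stay 1:1
      pairs <- pair_set(a, b, ifelse(within, "CRISPR", "text-mining"))
    } else {
      within <- logical(0)
    }
    truth <- list(module = stats::setNames(module, pid),
                  module_members = members,
                  pair_within = within,
                  mask = mask)
    list(abundance = ab, terms = terms, pairs = pairs, truth = truth,
         spec = spec)
  })
}

#' Generate a synthetic two-condition depletion experiment
#'
#' Per-protein baseline log2 intensities are drawn uniformly from
#' `baseline_log2`; a random member set gets `log2(fold)` added in the
#' depleted condition; i.i.d. normal replicate noise of sd `noise_sd` is
#' added on the log2 scale; values are exponentiated to intensities.
#' Conditions are labelled `depleted` (numerator) and `wt`.
#'
#' @param n_proteins Total proteins.
#' @param set_size Size of the planted set (`<= n_proteins`).
#' @param fold Planted fold change (> 0) of the set in the depleted
#'   condition; default 1.74.
#' @param n_reps Replicates per condition (>= 2); default 4.
#' @param noise_sd Replicate noise sd on the log2 scale; default 0.2.
#' @param baseline_log2 Range of baseline log2 intensities.
#' @param seed Integer seed.
#' @return List with `experiment` (a `replicate_experiment`) and `members`
#'   (ids of the planted set).
#' @export
generate_depletion <- function(n_proteins, set_size, fold = 1.74,
                               n_reps = 4L, noise_sd = 0.2,
                               baseline_log2 = c(8, 14), seed = 1L) {
  if (set_size > n_proteins) stop("set_size must be <= n_proteins")
  if (n_reps < 2L) stop("need at least 2 replicates per condition")
  if (fold <= 0) stop("fold must be > 0")
  .with_seed(seed, {
    pid <- sprintf("P%04d", seq_len(n_proteins))
    base <- stats::runif(n_proteins, baseline_log2[1L], baseline_log2[2L])
    members <- sort(sample(pid, set_size))
    shift <- ifelse(pid %in% members, log2(fold), 0)
    noise <- matrix(stats::rnorm(n_proteins * 2L * n_reps, sd = noise_sd),
                    n_proteins, 2L * n_reps)
    logm <- cbind(matrix(base + shift, n_proteins, n_reps),
                  matrix(base, n_proteins, n_reps)) + noise
    intens <- 2^logm
    rownames(intens) <- pid
    colnames(intens) <- c(sprintf("depleted:%d", seq_len(n_reps)),
                          sprintf("wt:%d", seq_len(n_reps)))
    e <- replicate_experiment(intens, rep(c("depleted", "wt"), each = n_reps))
    list(experiment = e, members = members)
  })
}

#' Generate an extreme-sparsity detection panel
#'
#' Each cell of a proteins x samples matrix is detected independently with
#' its protein's probability; undetected cells are masked. Detected
#' intensities are log-normal. The default emulates a centromere-protein
#' panel in a large patient cohort: three broadly detected proteins and
#' thirteen detected in only about 69 of 1172 samples, the regime in which
#' zero imputation drives the abundance median and quartiles to 0.
#'
#' @param n_samples Number of samples; default 1172.
#' @param detect_prob Named numeric vector of per-protein detection
#'   probabilities in `[0, 1]`; default is the 16-protein panel described
#'   above (ids `SP01`–`SP16`).
#' @param log_mu,log_sd Log-normal intensity parameters for detected cells.
#' @param seed Integer seed.
#' @return An [abundance_matrix()] with masked (NA) undetected cells and an
#'   attribute `detect_prob`.
#' @export
generate_sparsity_panel <- function(n_samples = 1172L, detect_prob = NULL,
                                    log_mu = 6, log_sd = 1, seed = 1L) {
  if (is.null(detect_prob)) {
    detect_prob <- c(0.90, 0.85, 0.80, rep(69 / 1172, 13L))
    names(detect_prob) <- sprintf("SP%02d", seq_along(detect_prob))
  }
  if (any(detect_prob < 0 | detect_prob > 1))
    stop("detection probabilities must be in [0, 1]")
  if (is.null(names(detect_prob)))
    names(detect_prob) <- sprintf("SP%02d", seq_along(detect_prob))
  .with_seed(seed, {
    n_prot <- length(detect_prob)
    mask <- matrix(stats::runif(n_prot * n_samples) > detect_prob,
                   n_prot, n_samples)
    values <- matrix(exp(stats::rnorm(n_prot * n_samples, log_mu, log_sd)),
                     n_prot, n_samples)
    values[mask] <- NA_real_
    dimnames(values) <- list(names(detect_prob),
                             sprintf("S%04d", seq_len(n_samples)))
    dimnames(mask) <- dimnames(values)
    out <- abundance_matrix(values, mask)
    attr(out, "detect_prob") <- detect_prob
    out
  })
}

#' Write a generated cohort to disk in the package's file formats
#'
#' Emits `abundance.tsv`, `terms.tsv`, `pairs.csv` and
#' `truth_modules.tsv` into `dir`, readable back with the `read_*`
#' functions; re-reading reproduces the generated objects exactly.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "abundance.tsv")
  write_abundance_table(cohort$abundance, p1)
  p2 <- file.path(dir, "terms.tsv")
  tm <- cohort$terms
  writeLines(unlist(lapply(names(tm), function(t)
    paste(t, tm[[t]], sep = "\t"))), p2)
  paths <- c(p1, p2)
  if (!is.null(cohort$pairs)) {
    p3 <- file.path(dir, "pairs.csv")
    writeLines(c("gene_a,gene_b,evidence_source",
                 paste(cohort$pairs$gene_a, cohort$pairs$gene_b,
                       cohort$pairs$evidence_source, sep = ",")), p3)
    paths <- c(paths, p3)
  }
  p4 <- file.path(dir, "truth_modules.tsv")
  tr <- cohort$truth$module
  writeLines(c("protein_id\tmodule",
               paste(names(tr), ifelse(is.na(tr), "NA", tr), sep = "\t")), p4)
  invisible(c(paths, p4))
}
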