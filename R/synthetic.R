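# Synthetic ground-truth data with the statistical structure the analysis
# assumes: herb-specific compound fingerprints, formula intensities that mix
# linearly with the design proportions under multiplicative log-normal noise,
# and a bioactivity response whose reciprocal is linear in a sparse set of
# planted active compounds.

DEFAULT_HERBS <- c("SOP", "SCU", "PHE", "RHE", "DIC", "KOC")

#' Simulate single-herb compound fingerprints
#'
#' Each herb gets its own set of compounds with log-normal base intensities
#' (median 1e5, log-sd 1 — the right order for triple-quadrupole ion counts),
#' retention times uniform on 2-72 min and unit-resolution m/z uniform on
#' 125-580 (the coordinate ranges of the HHCF case-study catalog). A
#' `shared_fraction` of compounds is duplicated into a second herb with the
#' same coordinates but an independent intensity, modelling constituents that
#' occur in more than one botanical drug.
#'
#' @param n_herbs number of herbs.
#' @param compounds_per_herb compounds per herb; scalar or one value per herb.
#'   The default, 68 compounds over 6 herbs, mirrors the case-study catalog
#'   size (31 positive- plus 37 negative-mode features).
#' @param shared_fraction fraction of compounds duplicated into a second herb.
#' @param herb_labels herb names.
#' @param seed optional RNG seed for reproducibility.
#' @return named list of per-herb fingerprints, each a data frame with columns
#'   `compound_id`, `mode`, `rt`, `mz`, `base_intensity`.
#' @export
simulate_fingerprints <- function(n_herbs = 6,
                                  compounds_per_herb = c(12, 11, 11, 11, 11, 12),
                                  shared_fraction = 0,
                                  herb_labels = DEFAULT_HERBS[seq_len(n_herbs)],
                                  seed = NULL) {
  if (n_herbs < 1) stop("n_herbs must be >= 1")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  cps <- rep_len(compounds_per_herb, n_herbs)
  if (any(cps < 1)) stop("compounds_per_herb must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  total <- sum(cps)
  herb_of <- rep(seq_len(n_herbs), cps)
  compounds <- data.frame(
    compound_id = sprintf("C%02d", seq_len(total)),
    mode = sample(c("pos", "neg"), total, replace = TRUE, prob = c(31, 37)),
    rt = stats::runif(total, 2, 72),
    mz = sample(125:580, total, replace = TRUE),
    stringsAsFactors = FALSE
  )
  fps <- lapply(seq_len(n_herbs), function(h) {
    idx <- which(herb_of == h)
    cbind(compounds[idx, , drop = FALSE],
          base_intensity = stats::rlnorm(length(idx), log(1e5), 1))
  })
  names(fps) <- herb_labels
  if (shared_fraction > 0 && n_herbs > 1) {
    n_shared <- round(shared_fraction * total)
    shared <- sample.int(total, n_shared)
    for (ci in shared) {
      h2 <- sample(setdiff(seq_len(n_herbs), herb_of[ci]), 1)
      fps[[h2]] <- rbind(fps[[h2]],
        cbind(compounds[ci, , drop = FALSE],
              base_intensity = stats::rlnorm(1, log(1e5), 1)))
    }
  }
  lapply(fps, function(f) {
    rownames(f) <- NULL
    f[order(f$mode, f$rt, f$mz), , drop = FALSE]
  })
}

#' Mix herb fingerprints into formula intensities
#'
#' Each formula's intensity for compound c is the proportion-weighted sum of
#' the herbs' base intensities, times an i.i.d. multiplicative log-normal
#' error: `X[j, c] = (sum_h p[j, h] * I[c, h]) * exp(e)`, `e ~ N(0, sigma_x^2)`.
#' A compound absent from a herb contributes zero. The catalog is the union of
#' the fingerprint coordinates with the true `source_herbs` recorded; feature
#' ids follow the P/N (rt, mz)-ordered convention of [attribute_sources()].
#'
#' @param design proportion matrix, rows on the simplex, columns named by the
#'   fingerprint herb labels (include the equal-proportion formula as a row if
#'   wanted).
#' @param fingerprints output of [simulate_fingerprints()].
#' @param sigma_x standard deviation of the log-scale intensity noise (>= 0).
#' @param seed optional RNG seed.
#' @return list with `X` (samples x features intensity matrix) and `catalog`
#'   (data frame `feature_id`, `compound_id`, `mode`, `rt`, `mz`,
#'   `source_herbs`).
#' @export
mix_intensities <- function(design, fingerprints, sigma_x = 0.2, seed = NULL) {
  if (sigma_x < 0) stop("sigma_x must be >= 0")
  D <- as.matrix(design)
  if (any(abs(rowSums(D) - 1) > 1e-9)) stop("design rows must sum to 1")
  herbs <- names(fingerprints)
  if (!all(colnames(D) == herbs)) {
    stop("design columns must be named by the fingerprint herbs, in order")
  }
  if (!is.null(seed)) set.seed(seed)
  all_cpd <- unique(do.call(rbind, lapply(fingerprints, function(f) {
    f[, c("compound_id", "mode", "rt", "mz")]
  })))
  all_cpd <- all_cpd[order(all_cpd$mode, all_cpd$rt, all_cpd$mz), , drop = FALSE]
  p_tot <- nrow(all_cpd)
  ids <- character(p_tot)
  for (m in c("pos", "neg")) {
    idx <- which(all_cpd$mode == m)
    ids[idx] <- paste0(if (m == "pos") "P" else "N", seq_along(idx))
  }
  Imat <- matrix(0, p_tot, length(herbs),
                 dimnames = list(all_cpd$compound_id, herbs))
  for (h in herbs) {
    f <- fingerprints[[h]]
    Imat[f$compound_id, h] <- f$base_intensity
  }
  src <- apply(Imat > 0, 1, function(row) paste(sort(herbs[row]), collapse = ";"))
  signal <- D %*% t(Imat)
  noise <- if (sigma_x > 0) {
    exp(matrix(stats::rnorm(length(signal), 0, sigma_x), nrow(signal)))
  } else 1
  X <- signal * noise
  if (is.null(rownames(D))) rownames(D) <- paste0("S", seq_len(nrow(D)))
  dimnames(X) <- list(rownames(D), ids)
  catalog <- data.frame(
    feature_id = ids,
    compound_id = all_cpd$compound_id,
    mode = all_cpd$mode, rt = all_cpd$rt, mz = all_cpd$mz,
    source_herbs = unname(src),
    stringsAsFactors = FALSE
  )
  list(X = X, catalog = catalog)
}

#' Simulate a bioactivity response with reciprocal-linear structure
#'
#' The linear predictor is formed on the autoscaled intensities,
#' `u_j = alpha + sum_c beta_c z[j, c] + e_j` with `e ~ N(0, sigma_y^2)`, and
#' the reported concentration is its reciprocal, `CCL17_j = 1 / u_j` — so the
#' reciprocal transform applied downstream exactly linearises the truth. If
#' any `u_j` falls at or below `u_min = 1e-4` the noise vector is redrawn (up
#' to 100 attempts) to keep the concentration positive and finite.
#'
#' @param X raw intensity matrix (samples x features, feature-id columns).
#' @param active_ids feature ids of the planted active compounds.
#' @param beta effect per active on the autoscaled intensity scale; scalar or
#'   one value per active.
#' @param alpha intercept of the linear predictor; must keep `u` away from 0.
#' @param sigma_y absolute standard deviation of the response noise, or `NULL`
#'   to use `sigma_y_rel * mean(|u|)` of the noiseless predictor.
#' @param sigma_y_rel relative noise level used when `sigma_y` is `NULL`.
#' @param seed optional RNG seed.
#' @return numeric response vector (strictly positive), named by sample.
#' @export
simulate_ccl17 <- function(X, active_ids, beta = 0.5, alpha = 5,
                           sigma_y = NULL, sigma_y_rel = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(active_ids) < 1) stop("need at least one active compound")
  if (!all(active_ids %in% colnames(X))) {
    stop("active_ids must be feature ids of X")
  }
  beta <- rep_len(beta, length(active_ids))
  if (any(beta == 0)) stop("active effects must be non-zero")
  z <- suppressWarnings(autoscale(X))
  if (!all(active_ids %in% colnames(z$data))) {
    stop("an active feature has zero variance and cannot drive the response")
  }
  u0 <- alpha + drop(z$data[, active_ids, drop = FALSE] %*% beta)
  if (is.null(sigma_y)) sigma_y <- sigma_y_rel * mean(abs(u0))
  u_min <- 1e-4
  for (attempt in seq_len(100)) {
    u <- u0 + if (sigma_y > 0) stats::rnorm(length(u0), 0, sigma_y) else 0
    if (all(u > u_min)) {
      return(stats::setNames(1 / u, rownames(X)))
    }
    if (sigma_y == 0) break
  }
  stop("linear predictor not positive after 100 redraws; increase alpha or shrink beta/sigma_y")
}

#' Generate a complete synthetic spectrum-effect dataset
#'
#' Chains the generator end to end: a 12-run, 6-component GLP mixture design
#' (generating vector 1, 3, 4, 9, 12 modulo 13, the table recovered from the
#' HHCF case study) plus the equal-proportion formula as the first row; herb
#' fingerprints; mixed intensities; and a response whose reciprocal is linear
#' in `n_active` planted features with effect `beta` each.
#'
#' @param seed RNG seed governing the whole chain.
#' @param n_active number of planted active compounds.
#' @param beta effect size per active (positive: the compound promotes
#'   response inhibition).
#' @param sigma_x log-scale intensity noise.
#' @param sigma_y_rel response noise relative to the mean linear predictor.
#' @param alpha intercept of the reciprocal-scale linear predictor.
#' @param shared_fraction fraction of compounds occurring in two herbs.
#' @param compounds_per_herb compounds per herb (default: 68 features total).
#' @return an object of class `synthetic_dataset`: list with `design` (13 x 6,
#'   first row the equal formula), `fingerprints`, `X` (13 x p), `catalog`,
#'   `ccl17`, and `truth` (list: `active_ids`, `beta`, `alpha`, `sigma_x`,
#'   `sigma_y`, `seed`).
#' @export
simulate_dataset <- function(seed = 1, n_active = 5, beta = 0.5,
                             sigma_x = 0.2, sigma_y_rel = 0.05, alpha = 5,
                             shared_fraction = 0,
                             compounds_per_herb = c(12, 11, 11, 11, 11, 12)) {
  set.seed(seed)
  lev <- glp_levels(12, c(1, 3, 4, 9, 12), drop_last_row = TRUE)
  varied <- mixture_transform(lev, component_names = DEFAULT_HERBS)
  rownames(varied) <- paste0("V", 1:12)
  design <- rbind(HHCF = rep(1 / 6, 6), varied)
  colnames(design) <- DEFAULT_HERBS
  fps <- simulate_fingerprints(
    n_herbs = 6, compounds_per_herb = compounds_per_herb,
    shared_fraction = shared_fraction, seed = NULL
  )
  mixed <- mix_intensities(design, fps, sigma_x = sigma_x, seed = NULL)
  active_ids <- sort(sample(colnames(mixed$X), n_active))
  beta <- stats::setNames(rep_len(beta, n_active), active_ids)
  z0 <- suppressWarnings(autoscale(mixed$X))
  u0 <- alpha + drop(z0$data[, active_ids, drop = FALSE] %*% beta)
  sigma_y <- sigma_y_rel * mean(abs(u0))
  ccl17 <- simulate_ccl17(mixed$X, active_ids, beta = beta, alpha = alpha,
                          sigma_y = sigma_y, seed = NULL)
  structure(
    list(design = design, fingerprints = fps, X = mixed$X,
         catalog = mixed$catalog, ccl17 = ccl17,
         truth = list(active_ids = active_ids, beta = beta, alpha = alpha,
                      sigma_x = sigma_x, sigma_y = sigma_y, seed = seed)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic spectrum-effect dataset: %d samples x %d features, %d planted active(s)\n",
    nrow(x$X), ncol(x$X), length(x$truth$active_ids)))
  cat("  actives:", paste(x$truth$active_ids, collapse = ", "), "\n")
  invisible(x)
}
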