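# Preprocessing: reciprocal response, autoscaling, MTT viability.

#' Reciprocal of a positive bioactivity response
#'
#' A lower CCL17 concentration means stronger inhibition, so the response is
#' inverted before regression: the reciprocal is strictly order-reversing and
#' makes "larger = more active". Applying it twice returns the original values.
#'
#' @param values positive numeric vector (e.g. CCL17, pg/mL).
#' @param sample_ids optional labels used in error messages; defaults to
#'   `names(values)` or positions.
#' @return numeric vector `1/values`.
#' @export
reciprocal_response <- function(values, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(names(values))) names(values) else as.character(seq_along(values))
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("non-positive response for sample(s): ",
         paste(sample_ids[bad], collapse = ", "))
  }
  out <- 1 / values
  names(out) <- names(values)
  out
}

#' Autoscale a matrix or vector (mean-centre, unit variance)
#'
#' Column-wise `(x - mean) / sd`, with the sample standard deviation (n - 1
#' denominator). Zero-variance columns carry no information on this scale and
#' are dropped with a warning (expected when a compound is absent from every
#' sample); their names are recorded so the same transform can be applied to
#' new rows.
#'
#' @param block numeric matrix (or vector, treated as a single column).
#' @return an object of class `scaled_block`: list with elements `data` (the
#'   scaled matrix, or vector if the input was one), `means`, `sds` (for all
#'   original columns), `kept` (logical), `dropped` (names of dropped columns).
#' @export
autoscale <- function(block) {
  vec <- is.null(dim(block))
  X <- as.matrix(block)
  if (nrow(X) < 2) stop("autoscaling needs at least 2 rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  tol <- 1e-12 * pmax(1, abs(mu))
  kept <- is.finite(sds) & sds > tol
  if (!any(kept)) stop("all columns have zero variance")
  if (any(!kept)) {
    warning(sprintf("dropping %d zero-variance column(s): %s",
                    sum(!kept), paste(colnames(X)[!kept], collapse = ", ")))
  }
  Z <- sweep(sweep(X[, kept, drop = FALSE], 2, mu[kept], "-"), 2, sds[kept], "/")
  out <- list(
    data = if (vec) drop(Z) else Z,
    means = mu, sds = sds, kept = kept,
    dropped = colnames(X)[!kept]
  )
  class(out) <- "scaled_block"
  out
}

#' Apply a stored autoscaling transform to new rows
#'
#' @param scaling a `scaled_block` from [autoscale()].
#' @param newdata numeric matrix (or vector) with the same columns as the
#'   training block; dropped columns are ignored.
#' @return scaled matrix restricted to the retained columns.
#' @export
apply_scaling <- function(scaling, newdata) {
  stopifnot(inherits(scaling, "scaled_block"))
  X <- as.matrix(newdata)
  if (ncol(X) == 1 && length(scaling$means) == 1) colnames(X) <- names(scaling$means)
  if (!is.null(colnames(X))) {
    if (!all(names(scaling$means) %in% colnames(X))) {
      stop("newdata lacks training columns")
    }
    X <- X[, names(scaling$means), drop = FALSE]
  } else if (ncol(X) != length(scaling$means)) {
    stop("newdata column count does not match the training block")
  }
  kept <- scaling$kept
  sweep(sweep(X[, kept, drop = FALSE], 2, scaling$means[kept], "-"),
        2, scaling$sds[kept], "/")
}

#' Undo an autoscaling transform
#'
#' @param scaling a `scaled_block` from [autoscale()].
#' @param scaled scaled matrix or vector over the retained columns.
#' @return values on the original scale.
#' @export
unscale <- function(scaling, scaled) {
  stopifnot(inherits(scaling, "scaled_block"))
  kept <- scaling$kept
  Z <- as.matrix(scaled)
  sweep(sweep(Z, 2, scaling$sds[kept], "*"), 2, scaling$means[kept], "+")
}

#' MTT cell-viability percentage
#'
#' Computed mean-first, as the assay formula states: the mean absorbance of the
#' tested wells divided by the mean absorbance of the control wells, times 100
#' (not the mean of per-well ratios).
#'
#' @param tested absorbance values of treated wells.
#' @param control absorbance values of untreated control wells.
#' @return viability, percent.
#' @export
viability_percent <- function(tested, control) {
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) stop("control mean absorbance must be positive")
  100 * mean(tested) / mc
}
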