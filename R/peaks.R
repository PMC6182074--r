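# LC-MS peak matching and source attribution.
#
# Peaks live in data frames with columns mode ("pos"/"neg"), rt (minutes),
# mz (Thomson, unit resolution) and intensity. A feature catalog is the
# cross-sample aligned peak set with source-herb attribution.

#' Validate and normalise a peak table
#'
#' @param peaks data frame with columns `mode`, `rt`, `mz` and (optionally)
#'   `intensity`.
#' @param require_intensity whether `intensity` must be present.
#' @return the peak table sorted by (mode, rt, mz).
#' @keywords internal
as_peak_table <- function(peaks, require_intensity = TRUE) {
  need <- c("mode", "rt", "mz", if (require_intensity) "intensity")
  missing <- setdiff(need, names(peaks))
  if (length(missing)) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(peaks$mode %in% c("pos", "neg"))) {
    stop("'mode' must be 'pos' or 'neg'")
  }
  if (any(peaks$rt < 0) || any(peaks$mz <= 0)) stop("rt must be >= 0 and mz > 0")
  if (require_intensity && any(peaks$intensity < 0)) stop("intensity must be >= 0")
  peaks[order(peaks$mode, peaks$rt, peaks$mz), , drop = FALSE]
}

#' Match query peaks to reference peaks by RT and m/z tolerance
#'
#' A query peak and a reference peak are candidates when they share the
#' ionization mode, `|rt_q - rt_r| <= rt_tol` and `|mz_q - mz_r| <= mz_tol`.
#' Candidates are ranked by the normalised distance
#' `|drt|/rt_tol + |dmz|/mz_tol` and assigned one-to-one, greedily in ascending
#' distance order; ties are broken by lower query rt, then lower query mz (and
#' then the reference coordinates), so the assignment is deterministic.
#'
#' @param query,reference peak tables (data frames with `mode`, `rt`, `mz`).
#' @param rt_tol retention-time tolerance, minutes (> 0).
#' @param mz_tol m/z tolerance, Thomson (> 0).
#' @return data frame with columns `query`, `reference` (row indices into the
#'   inputs) and `dist` (normalised match distance), one row per matched pair.
#' @export
match_peaks <- function(query, reference, rt_tol = 0.2, mz_tol = 0.5) {
  if (rt_tol <= 0 || mz_tol <= 0) stop("tolerances must be positive")
  empty <- data.frame(query = integer(), reference = integer(), dist = numeric())
  if (nrow(query) == 0 || nrow(reference) == 0) return(empty)
  cand <- NULL
  for (m in intersect(unique(query$mode), unique(reference$mode))) {
    qi <- which(query$mode == m)
    ri <- which(reference$mode == m)
    drt <- abs(outer(query$rt[qi], reference$rt[ri], "-"))
    dmz <- abs(outer(query$mz[qi], reference$mz[ri], "-"))
    ok <- which(drt <= rt_tol & dmz <= mz_tol, arr.ind = TRUE)
    if (nrow(ok)) {
      cand <- rbind(cand, data.frame(
        query = qi[ok[, 1]], reference = ri[ok[, 2]],
        dist = drt[ok] / rt_tol + dmz[ok] / mz_tol
      ))
    }
  }
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  ord <- order(cand$dist, query$rt[cand$query], query$mz[cand$query],
               reference$rt[cand$reference], reference$mz[cand$reference])
  cand <- cand[ord, , drop = FALSE]
  q_used <- logical(nrow(query))
  r_used <- logical(nrow(reference))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    qi <- cand$query[k]
    ri <- cand$reference[k]
    if (!q_used[qi] && !r_used[ri]) {
      keep[k] <- TRUE
      q_used[qi] <- TRUE
      r_used[ri] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute formula peaks to their source botanical drugs
#'
#' Every peak of the mixed-formula peak list becomes a catalog feature. Each
#' herb's single-drug peak list is matched against the formula list with
#' [match_peaks()]; the feature's `source_herbs` collects every herb that
#' yields a match (semicolon-joined), or `"unassigned"` when no herb matches.
#' Feature ids are assigned `P1..Pk` (positive mode) and `N1..Nm` (negative
#' mode) in (rt, mz) order within mode.
#'
#' @param formula_peaks peak table of the mixed formula.
#' @param herb_peaklists named list of per-herb peak tables; names are herb
#'   labels and must be unique.
#' @param rt_tol,mz_tol match tolerances, see [match_peaks()].
#' @return a feature catalog: data frame with columns `feature_id`, `mode`,
#'   `rt`, `mz`, `intensity` (the formula-peak intensity), `source_herbs`.
#' @export
attribute_sources <- function(formula_peaks, herb_peaklists,
                              rt_tol = 0.2, mz_tol = 0.5) {
  if (length(herb_peaklists) < 1) stop("need at least one herb peak list")
  if (is.null(names(herb_peaklists)) || anyDuplicated(names(herb_peaklists)) ||
      any(names(herb_peaklists) == "")) {
    stop("herb_peaklists must be uniquely named by herb label")
  }
  fp <- as_peak_table(formula_peaks)
  sources <- rep(list(character(0)), nrow(fp))
  for (herb in names(herb_peaklists)) {
    hp <- as_peak_table(herb_peaklists[[herb]], require_intensity = FALSE)
    mm <- match_peaks(fp, hp, rt_tol = rt_tol, mz_tol = mz_tol)
    for (qi in mm$query) sources[[qi]] <- c(sources[[qi]], herb)
  }
  src <- vapply(sources, function(s) {
    if (length(s)) paste(sort(s), collapse = ";") else "unassigned"
  }, character(1))
  ids <- character(nrow(fp))
  for (m in c("pos", "neg")) {
    idx <- which(fp$mode == m)   # fp already (mode, rt, mz)-sorted
    ids[idx] <- paste0(if (m == "pos") "P" else "N", seq_along(idx))
  }
  data.frame(
    feature_id = ids, mode = fp$mode, rt = fp$rt, mz = fp$mz,
    intensity = fp$intensity, source_herbs = src,
    stringsAsFactors = FALSE
  )
}

#' Assemble a samples-by-features intensity matrix against a catalog
#'
#' Each sample's peaks are matched to the catalog's (mode, rt, mz) coordinates
#' under the same tolerance rule as [match_peaks()]; matrix entry (j, c) is the
#' intensity of the sample-j peak matched to feature c, or 0 when the feature
#' is absent from that sample. Zero-filling treats absence of evidence as
#' absence; a sample matching no feature at all is kept as a row of zeros with
#' a warning.
#'
#' @param sample_peaklists named list of peak tables, one per sample, in the
#'   desired row order.
#' @param catalog feature catalog as from [attribute_sources()].
#' @param rt_tol,mz_tol match tolerances.
#' @return numeric matrix, samples by features, with sample ids as row names
#'   and feature ids as column names.
#' @export
assemble_intensity_matrix <- function(sample_peaklists, catalog,
                                      rt_tol = 0.2, mz_tol = 0.5) {
  if (nrow(catalog) == 0) stop("catalog is empty")
  if (is.null(names(sample_peaklists))) stop("sample_peaklists must be named")
  X <- matrix(0, length(sample_peaklists), nrow(catalog),
              dimnames = list(names(sample_peaklists), catalog$feature_id))
  ref <- catalog[, c("mode", "rt", "mz")]
  for (j in seq_along(sample_peaklists)) {
    sp <- as_peak_table(sample_peaklists[[j]])
    mm <- match_peaks(sp, ref, rt_tol = rt_tol, mz_tol = mz_tol)
    if (nrow(mm) == 0) {
      warning(sprintf("sample '%s' matched no catalog feature; row left zero",
                      names(sample_peaklists)[j]))
      next
    }
    X[j, mm$reference] <- sp$intensity[mm$query]
  }
  X
}
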