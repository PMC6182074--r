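# Mixture uniform designs from good-lattice-point (GLP) level tables.
#
# An n-run, s-component mixture design is built in two steps: an n x (s-1)
# integer level table whose columns are permutations of 1..n (the GLP
# construction), and the inverse-power simplex transform that maps each level
# row to a composition on the simplex.

#' Round half away from zero (half-up for positive values)
#'
#' Printed percentage tables in the mixture-design literature use conventional
#' rounding (0.5 rounds up), not banker's rounding, so `round()` is not
#' appropriate when reproducing them.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Good-lattice-point design levels
#'
#' Constructs the integer level table of a uniform design by the
#' good-lattice-point method: `levels[i, j] = ((i * h_j - 1) mod N) + 1` for
#' runs `i = 1..n` and generating-vector elements `h_j`. Each column is a
#' permutation of `1..n` provided `gcd(h_j, N) = 1`.
#'
#' When too few integers below `n` are coprime with `n` (e.g. `n = 12`, where
#' only 1, 5, 7, 11 qualify), the standard remedy is to run the construction
#' modulo `N = n + 1` over `n + 1` rows and drop the last row, which is always
#' the constant row `(n + 1, ..., n + 1)`; set `drop_last_row = TRUE` for this.
#'
#' @param n number of runs (at least 2).
#' @param generating_vector distinct positive integers, one per design factor;
#'   each must be coprime with the modulus (`n`, or `n + 1` when
#'   `drop_last_row` is set) so its column is a permutation.
#' @param drop_last_row construct over `n + 1` rows modulo `n + 1` and drop the
#'   all-`(n+1)` final row.
#' @return integer matrix, `n` rows by `length(generating_vector)` columns,
#'   every column a permutation of `1..n`.
#' @examples
#' glp_levels(12, c(1, 3, 4, 9, 12), drop_last_row = TRUE)
#' @export
glp_levels <- function(n, generating_vector, drop_last_row = FALSE) {
  n <- as.integer(n)
  h <- as.integer(generating_vector)
  if (is.na(n) || n < 2) stop("'n' must be an integer >= 2")
  if (length(h) < 1 || anyNA(h) || any(h < 1)) {
    stop("'generating_vector' must contain positive integers")
  }
  if (anyDuplicated(h)) stop("'generating_vector' entries must be distinct")
  N <- if (drop_last_row) n + 1L else n
  bad <- h[vapply(h, function(hj) gcd_int(hj, N) != 1L, logical(1))]
  if (length(bad)) {
    stop(sprintf(
      "generating_vector entries not coprime with %d: %s (column would not be a permutation)",
      N, paste(bad, collapse = ", ")
    ))
  }
  lev <- outer(seq_len(n), h, function(i, hj) ((i * hj - 1L) %% N) + 1L)
  if (anyDuplicated(t(lev))) stop("duplicate columns in level table")
  storage.mode(lev) <- "integer"
  colnames(lev) <- paste0("f", seq_along(h))
  lev
}

# Euclid; base R has no integer gcd.
gcd_int <- function(a, b) {
  while (b != 0L) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Inverse-power simplex transform of a level table
#'
#' Maps each row of a GLP level table to a composition of `s` mixture
#' proportions. Levels are first centred onto the unit hypercube,
#' `c = (2 * level - 1) / (2 * n)`, then transformed by
#' \deqn{x_k = (1 - c_k^{1/(s-k)}) \prod_{j<k} c_j^{1/(s-j)}, \quad
#'       x_s = \prod_{j=1}^{s-1} c_j^{1/(s-j)},}
#' which places every row exactly on the simplex (the products telescope, so
#' rows sum to 1 up to floating point).
#'
#' @param levels integer level matrix as from [glp_levels()], `n` rows by
#'   `s - 1` columns.
#' @param component_names optional character vector of `s` component labels.
#' @return numeric matrix of proportions, `n` rows by `s` columns, each row
#'   summing to 1.
#' @examples
#' lev <- glp_levels(12, c(1, 3, 4, 9, 12), drop_last_row = TRUE)
#' design <- mixture_transform(lev,
#'   component_names = c("SOP", "SCU", "PHE", "RHE", "DIC", "KOC"))
#' rowSums(design)
#' @export
mixture_transform <- function(levels, component_names = NULL) {
  levels <- as.matrix(levels)
  n <- nrow(levels)
  m <- ncol(levels)
  s <- m + 1L
  if (s < 2) stop("need at least one level column (s >= 2)")
  if (any(levels < 1) || any(levels > n)) {
    stop("levels must lie in 1..n (n = number of rows)")
  }
  if (!is.null(component_names) && length(component_names) != s) {
    stop(sprintf("'component_names' must have length %d", s))
  }
  cc <- (2 * levels - 1) / (2 * n)
  x <- matrix(0, n, s)
  for (i in seq_len(n)) {
    g <- 1
    for (k in seq_len(s - 1L)) {
      ck <- cc[i, k]^(1 / (s - k))
      x[i, k] <- (1 - ck) * g
      g <- g * ck
    }
    x[i, s] <- g
  }
  rownames(x) <- rownames(levels)
  colnames(x) <- if (is.null(component_names)) paste0("x", seq_len(s)) else component_names
  x
}

#' Convert a mixture design to an integer percent table
#'
#' Each proportion is multiplied by 100 and rounded half-up, with no
#' renormalisation: row sums of the percent table may drift to 99 or 101, as
#' printed mixture tables do.
#'
#' @param design numeric matrix of proportions (rows on the simplex).
#' @return integer matrix of percentages.
#' @export
to_percent <- function(design) {
  design <- as.matrix(design)
  if (any(design < 0) || any(design > 1)) stop("proportions must lie in [0, 1]")
  p <- round_half_up(100 * design)
  storage.mode(p) <- "integer"
  p
}

#' Recover GLP levels from a printed percent table
#'
#' Inverts [mixture_transform()] sequentially: from the first column,
#' `c_1 = (1 - x_1)^(s-1)`; each later `c_k` follows from `x_k` divided by the
#' accumulated product of the already-recovered factors. Each recovered `c` is
#' snapped to the nearest grid point `(2k - 1)/(2n)`; a row whose raw value
#' lies farther than half the grid spacing `1/(2n)` from any grid point is not
#' consistent with an `n`-level design and is rejected.
#'
#' Accepts either an integer percent table (row sums near 100) or an exact
#' proportion matrix (row sums near 1).
#'
#' @param percents numeric matrix, `n` rows by `s` columns, of percentages (or
#'   proportions).
#' @param n number of design levels (defaults to the row count).
#' @return integer level matrix, `n` rows by `s - 1` columns, such that
#'   `to_percent(mixture_transform(recover_levels(P)))` reproduces `P` when
#'   `P` came from an `n`-level design.
#' @export
recover_levels <- function(percents, n = nrow(percents)) {
  x <- as.matrix(percents)
  s <- ncol(x)
  if (s < 2) stop("need at least two components")
  if (mean(rowSums(x)) > 1.5) x <- x / 100  # percent-scale input
  grid <- (2 * seq_len(n) - 1) / (2 * n)
  lev <- matrix(NA_integer_, nrow(x), s - 1L)
  for (i in seq_len(nrow(x))) {
    g <- 1
    for (k in seq_len(s - 1L)) {
      ck_raw <- (1 - x[i, k] / g)^(s - k)
      j <- which.min(abs(grid - ck_raw))
      if (abs(grid[j] - ck_raw) > 1 / (2 * n) + 1e-9) {
        stop(sprintf(
          "row %d, factor %d: value %.4f not consistent with a design on %d levels",
          i, k, ck_raw, n
        ))
      }
      lev[i, k] <- j
      g <- g * grid[j]^(1 / (s - k))
    }
  }
  rownames(lev) <- rownames(percents)
  colnames(lev) <- paste0("f", seq_len(s - 1L))
  lev
}
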