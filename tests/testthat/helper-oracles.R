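# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: least squares goes through the SVD, assignment
# through exhaustive enumeration, cross-validation through literal refits.

# Minimum-norm least-squares solution via the SVD pseudoinverse.
minnorm_ls <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > tol * sv$d[1]
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

# Exhaustive one-to-one assignment minimising total normalised distance under
# the tolerance gate. Exponential; only for small, sparse instances.
brute_force_assignment <- function(query, reference, rt_tol, mz_tol) {
  cand <- vector("list", nrow(query))
  dmat <- matrix(Inf, nrow(query), nrow(reference))
  for (qi in seq_len(nrow(query))) {
    for (ri in seq_len(nrow(reference))) {
      if (query$mode[qi] == reference$mode[ri] &&
          abs(query$rt[qi] - reference$rt[ri]) <= rt_tol &&
          abs(query$mz[qi] - reference$mz[ri]) <= mz_tol) {
        dmat[qi, ri] <- abs(query$rt[qi] - reference$rt[ri]) / rt_tol +
          abs(query$mz[qi] - reference$mz[ri]) / mz_tol
      }
    }
    cand[[qi]] <- which(is.finite(dmat[qi, ]))
  }
  best <- list(cost = Inf, pairs = NULL)
  recurse <- function(qi, used, pairs, cost) {
    if (qi > nrow(query)) {
      n_best <- if (is.null(best$pairs)) -1L else nrow(best$pairs)
      n_cur <- nrow(pairs)
      # maximise match count, then minimise total distance
      if (n_cur > n_best || (n_cur == n_best && cost < best$cost)) {
        best <<- list(cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    for (ri in cand[[qi]]) {
      if (!used[ri]) {
        used[ri] <- TRUE
        recurse(qi + 1L, used,
                rbind(pairs, data.frame(query = qi, reference = ri)),
                cost + dmat[qi, ri])
        used[ri] <- FALSE
      }
    }
    recurse(qi + 1L, used, pairs, cost)  # leave qi unmatched
  }
  recurse(1L, logical(nrow(reference)),
          data.frame(query = integer(), reference = integer()), 0)
  p <- best$pairs
  p[order(p$query), , drop = FALSE]
}

# Random peak table with coordinates spread widely enough that tolerance
# conflicts are rare (matching instances stay assignment-unambiguous).
random_peaks <- function(n, mode = c("pos", "neg")) {
  data.frame(
    mode = sample(mode, n, replace = TRUE),
    rt = runif(n, 0, 70),
    mz = sample(125:580, n, replace = TRUE),
    intensity = rlnorm(n, log(1e5), 1),
    stringsAsFactors = FALSE
  )
}

# Random composition rows (uniform on the simplex by normalised exponentials).
random_simplex <- function(n, s) {
  g <- matrix(rexp(n * s), n, s)
  g / rowSums(g)
}

# Reference percent table of the case-study design (loaded once per run).
case_design_percent <- function() {
  d <- hhcf_design_percent()
  m <- as.matrix(d[, -1])
  rownames(m) <- d$run
  m
}
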