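test_that("tolerance matching is one-to-one and agrees with exhaustive assignment", {
  # berberine-style scenario: close RT, same nominal mass
  q <- data.frame(mode = "pos", rt = 52.87, mz = 336, intensity = 1e6)
  r <- data.frame(mode = "pos", rt = 52.80, mz = 336)
  m <- match_peaks(q, r, rt_tol = 0.2, mz_tol = 0.5)
  expect_equal(nrow(m), 1L)
  expect_equal(m$query, 1L)

  # empty reference, mode mismatch, bad tolerance
  expect_equal(nrow(match_peaks(q, r[0, ])), 0L)
  r_neg <- transform(r, mode = "neg")
  expect_equal(nrow(match_peaks(q, r_neg)), 0L)
  expect_error(match_peaks(q, r, rt_tol = 0), "positive")

  set.seed(11)
  for (rep in 1:10) {
    qq <- random_peaks(20)
    rr <- random_peaks(20)
    got <- match_peaks(qq, rr, rt_tol = 0.5, mz_tol = 0.5)
    want <- brute_force_assignment(qq, rr, rt_tol = 0.5, mz_tol = 0.5)
    expect_equal(got[order(got$query), c("query", "reference")], want,
                 ignore_attr = TRUE)
    # one-to-one on both sides
    expect_false(anyDuplicated(got$query) > 0)
    expect_false(anyDuplicated(got$reference) > 0)
  }
})

test_that("enlarging tolerances never reduces the match count, and matching is symmetric", {
  set.seed(23)
  qq <- random_peaks(40)
  rr <- random_peaks(40)
  n1 <- nrow(match_peaks(qq, rr, rt_tol = 0.2, mz_tol = 0.5))
  n2 <- nrow(match_peaks(qq, rr, rt_tol = 1.0, mz_tol = 0.5))
  n3 <- nrow(match_peaks(qq, rr, rt_tol = 1.0, mz_tol = 2.0))
  expect_true(n1 <= n2 && n2 <= n3)

  fwd <- match_peaks(qq, rr, rt_tol = 0.3, mz_tol = 0.5)
  rev <- match_peaks(rr, qq, rt_tol = 0.3, mz_tol = 0.5)
  expect_setequal(paste(fwd$query, fwd$reference),
                  paste(rev$reference, rev$query))
})

test_that("source attribution flags shared and unmatched peaks correctly", {
  formula <- data.frame(
    mode = c("neg", "neg", "pos"),
    rt = c(5.35, 30.0, 52.87),
    mz = c(125, 400, 336),
    intensity = c(5e5, 2e5, 8e5)
  )
  herbs <- list(
    RHE = data.frame(mode = c("neg", "neg"), rt = c(5.33, 30.02), mz = c(125, 400)),
    PHE = data.frame(mode = c("pos", "neg"), rt = c(52.80, 29.95), mz = c(336, 400))
  )
  cat <- attribute_sources(formula, herbs, rt_tol = 0.2, mz_tol = 0.5)
  expect_identical(cat$feature_id, c("N1", "N2", "P1"))  # (rt, mz) order in mode
  expect_identical(cat$source_herbs[cat$mz == 125], "RHE")        # pyrogallol case
  expect_identical(cat$source_herbs[cat$mz == 400], "PHE;RHE")    # shared compound
  expect_identical(cat$source_herbs[cat$mode == "pos"], "PHE")    # berberine case

  # a formula peak with no herb match is flagged
  lonely <- rbind(formula, data.frame(mode = "neg", rt = 60, mz = 500, intensity = 1e4))
  cat2 <- attribute_sources(lonely, herbs)
  expect_identical(cat2$source_herbs[cat2$mz == 500], "unassigned")

  expect_error(attribute_sources(formula, unname(herbs)), "named")
})

test_that("synthetic fingerprints are attributed exactly and matrices reassemble", {
  fps <- simulate_fingerprints(seed = 5)
  herb_lists <- lapply(fps, function(f) {
    data.frame(mode = f$mode, rt = f$rt, mz = f$mz, intensity = f$base_intensity)
  })
  design <- matrix(rep(1 / 6, 6), 1, dimnames = list("HHCF", names(fps)))
  mixed <- mix_intensities(design, fps, sigma_x = 0, seed = 1)
  formula_peaks <- data.frame(
    mode = mixed$catalog$mode, rt = mixed$catalog$rt, mz = mixed$catalog$mz,
    intensity = drop(mixed$X)
  )
  cat <- attribute_sources(formula_peaks, herb_lists)
  # zero jitter: attribution equals the generating compound -> herb map
  key <- order(cat$mode, cat$rt, cat$mz)
  key0 <- order(mixed$catalog$mode, mixed$catalog$rt, mixed$catalog$mz)
  expect_identical(cat$source_herbs[key], mixed$catalog$source_herbs[key0])

  # a sample identical to the catalog's defining coordinates reassembles exactly,
  # and jitter within half-tolerance leaves the matrix unchanged
  ds <- simulate_dataset(seed = 8)
  rows <- lapply(rownames(ds$X), function(s) {
    data.frame(mode = ds$catalog$mode, rt = ds$catalog$rt, mz = ds$catalog$mz,
               intensity = ds$X[s, ds$catalog$feature_id])
  })
  names(rows) <- rownames(ds$X)
  X1 <- assemble_intensity_matrix(rows, ds$catalog)
  expect_equal(X1, ds$X, tolerance = 1e-12)

  set.seed(99)
  jit <- lapply(rows, function(pp) {
    transform(pp, rt = rt + runif(nrow(pp), -0.09, 0.09),
              mz = mz + runif(nrow(pp), -0.2, 0.2))
  })
  X2 <- assemble_intensity_matrix(jit, ds$catalog)
  expect_equal(X2, X1, tolerance = 1e-12)

  # zero-fill conservation: matrix total never exceeds total peak intensity
  expect_lte(sum(X2), sum(vapply(jit, function(pp) sum(pp$intensity), numeric(1))) + 1e-9)

  # a sample with no matching peaks warns and stays zero
  far <- list(S1 = data.frame(mode = "pos", rt = 100, mz = 1000, intensity = 1))
  expect_warning(X3 <- assemble_intensity_matrix(far, ds$catalog), "no catalog feature")
  expect_true(all(X3 == 0))
})
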