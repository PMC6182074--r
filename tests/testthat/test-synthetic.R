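test_that("fingerprint generation is deterministic and correctly sized", {
  f1 <- simulate_fingerprints(seed = 42)
  f2 <- simulate_fingerprints(seed = 42)
  expect_identical(f1, f2)
  expect_named(f1, c("SOP", "SCU", "PHE", "RHE", "DIC", "KOC"))
  expect_equal(sum(vapply(f1, nrow, integer(1))), 68)

  # shared_fraction 0: all (mode, rt, mz) coordinates distinct across herbs
  coords <- do.call(rbind, lapply(f1, function(f) f[, c("mode", "rt", "mz")]))
  expect_equal(nrow(unique(coords)), 68)

  # sharing duplicates coordinates into a second herb with a new intensity
  fs <- simulate_fingerprints(shared_fraction = 0.25, seed = 42)
  coords_s <- do.call(rbind, lapply(fs, function(f) f[, c("compound_id", "mode", "rt", "mz")]))
  expect_gt(nrow(coords_s), 68)
  expect_equal(length(unique(coords_s$compound_id)), 68)

  expect_error(simulate_fingerprints(shared_fraction = 1.5), "shared_fraction")
})

test_that("noise-free mixing is exactly linear in the design proportions", {
  fps <- simulate_fingerprints(seed = 1)
  # one-hot run recovers that herb's base intensities exactly
  onehot <- matrix(0, 1, 6, dimnames = list("only_RHE", names(fps)))
  onehot[1, "RHE"] <- 1
  mixed <- mix_intensities(onehot, fps, sigma_x = 0)
  rhe <- fps$RHE
  got <- mixed$X[1, mixed$catalog$feature_id[match(rhe$compound_id, mixed$catalog$compound_id)]]
  expect_equal(unname(got), rhe$base_intensity, tolerance = 1e-12)

  # rank of a noise-free 13-sample matrix cannot exceed the herb count
  ds0 <- simulate_dataset(seed = 2, sigma_x = 0, sigma_y_rel = 0)
  expect_lte(qr(ds0$X)$rank, 6)
  # linearity: mixing the mean design row gives the mean of the mixed rows
  fpsb <- ds0$fingerprints
  mid <- matrix(colMeans(ds0$design), 1, dimnames = list("mid", colnames(ds0$design)))
  Xmid <- mix_intensities(mid, fpsb, sigma_x = 0)$X
  expect_equal(drop(Xmid), colMeans(ds0$X), tolerance = 1e-12)

  # log-normal noise keeps everything strictly positive
  ds <- simulate_dataset(seed = 3)
  expect_true(all(ds$X > 0))
  expect_identical(dim(ds$X), c(13L, 68L))
  expect_error(mix_intensities(onehot, fps, sigma_x = -1), "sigma_x")
})

test_that("the response is reciprocal-linear in the planted actives", {
  ds <- simulate_dataset(seed = 11, sigma_y_rel = 0)
  z <- suppressWarnings(autoscale(ds$X))$data
  u <- ds$truth$alpha + drop(z[, ds$truth$active_ids] %*% ds$truth$beta)
  # algebraic round trip: reciprocal of the response equals the predictor
  expect_equal(unname(1 / ds$ccl17), unname(u), tolerance = 1e-12)
  expect_true(all(ds$ccl17 > 0))

  # single positive active, no noise: response decreases with its abundance
  ds1 <- simulate_dataset(seed = 12, n_active = 1, sigma_y_rel = 0)
  z_act <- suppressWarnings(autoscale(ds1$X))$data[, ds1$truth$active_ids]
  expect_identical(order(ds1$ccl17), rev(order(z_act)))

  # all-zero effects are rejected, constant response comes from beta -> 0 limit
  expect_error(simulate_ccl17(ds$X, ds$truth$active_ids, beta = 0), "non-zero")
  almost0 <- simulate_ccl17(ds$X, ds$truth$active_ids, beta = 1e-12,
                            alpha = 5, sigma_y = 0)
  expect_equal(unname(almost0), rep(1 / 5, 13), tolerance = 1e-9)

  # an unsatisfiable positivity constraint aborts with a diagnostic
  expect_error(
    simulate_ccl17(ds$X, ds$truth$active_ids, beta = 5, alpha = 0, sigma_y = 0),
    "not positive"
  )
})

test_that("the full generator chain is deterministic under a fixed seed", {
  d1 <- simulate_dataset(seed = 77)
  d2 <- simulate_dataset(seed = 77)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(seed = 78)
  expect_false(identical(d1$X, d3$X))
})
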