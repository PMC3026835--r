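test_that("symmetric ring gives identically zero baseline-subtracted coupling", {
  ch <- toy_chain("ring", 12)
  model <- suppressWarnings(gnm(ch, 7))
  ct <- total_coupling(model)
  expect_lt(max(abs(ct)), 1e-10)
  raw <- total_coupling(model, baseline = FALSE)
  expect_lt(diff(range(raw)), 1e-10) # equal entries before subtraction
})

test_that("closed-form coupling equals the direct double loop", {
  ch <- toy_chain("random_coil", 25, seed = 6)
  model <- gnm(ch, 7)
  n <- 25
  u <- model$vectors[, n]
  lam <- model$values[n]
  brute <- vapply(seq_len(n), function(i) sum((u[i] - u)^2), numeric(1))
  ct <- total_coupling(model, baseline = FALSE)
  expect_lt(max(abs(ct - lam * brute)), 1e-10)
})

test_that("coupling is invariant under eigenvector sign flip", {
  ch <- toy_chain("random_coil", 20, seed = 12)
  model <- gnm(ch, 7)
  flipped <- model
  flipped$vectors[, 20] <- -flipped$vectors[, 20]
  expect_equal(total_coupling(model), total_coupling(flipped))
})

test_that("mode_rank counts down from the largest eigenvalue and validates", {
  ch <- toy_chain("random_coil", 10, seed = 2)
  model <- gnm(ch, 7)
  u2 <- model$vectors[, 9] # second largest
  ct2 <- total_coupling(model, mode_rank = 2, mode_weight = "none",
                        baseline = FALSE)
  brute <- vapply(1:10, function(i) sum((u2[i] - u2)^2), numeric(1))
  expect_equal(unname(ct2), brute, tolerance = 1e-10)
  expect_error(total_coupling(model, mode_rank = 10), "nonzero")
})

test_that("mode weight rescales but never reorders a single-mode profile", {
  ch <- toy_chain("clustered", 40, seed = 5)
  model <- gnm(ch, 7)
  a <- total_coupling(model, mode_weight = "lambda")
  b <- total_coupling(model, mode_weight = "inv-lambda")
  c3 <- total_coupling(model, mode_weight = "none")
  expect_equal(order(a), order(b))
  expect_equal(a / max(a), c3 / max(c3), tolerance = 1e-10)
})

test_that("fast-mode coupling equals the rank-1 distance-fluctuation row sum", {
  ch <- toy_chain("random_coil", 18, seed = 7)
  model <- gnm(ch, 7)
  n <- 18
  lam <- model$values[n]
  df_top <- distance_fluctuation(model, mode_subset = n) # lambda^-1 weighted
  ct <- total_coupling(model, mode_weight = "lambda", baseline = FALSE)
  expect_lt(max(abs(ct - lam^2 * rowSums(df_top))), 1e-10)
})

test_that("station machinery: defaults, degenerate averaging, normalization", {
  ch <- toy_chain("clustered", 35, seed = 3)
  prof <- coupling_profile(ch)
  expect_equal(prof$stations, c(6.9, 6.975, 7.05, 7.125, 7.2))
  expect_true(all(prof$averaged_ct >= 0 & prof$averaged_ct <= 1))
  expect_equal(max(prof$averaged_ct), 1)
  expect_true(all(prof$per_station_ct >= 0))
  expect_equal(unname(prof$averaged_ct[prof$residue_ids == prof$hub]), 1)

  # single station equals the normalized single-station coupling
  p1 <- coupling_profile(ch, station_min = 7.0, n_stations = 1)
  ct <- total_coupling(gnm(ch, 7.0))
  expect_equal(unname(p1$averaged_ct), unname(ct / max(ct)), tolerance = 1e-12)

  # averaging identical stations changes nothing
  p3 <- coupling_profile(ch, station_min = 7.0, station_max = 7.0 + 1e-12,
                         n_stations = 3)
  expect_equal(p3$averaged_ct, p1$averaged_ct, tolerance = 1e-9)
})

test_that("clustered toys put the hub inside the dense cluster", {
  for (s in c(3, 17, 23)) {
    ch <- toy_chain("clustered", 40, seed = s)
    prof <- suppressWarnings(coupling_profile(ch))
    expect_gt(prof$hub, 40 - 8)
    # independent check: power-iteration dominant mode of a shifted
    # Kirchhoff localizes on the same residue at the central station
    k <- build_kirchhoff(ch, 7.05)
    shifted <- k + diag(1, nrow(k)) # strictly dominant largest eigenvalue
    u <- oracle_power_vector(shifted)
    ctp <- vapply(seq_len(40), function(i) sum((u[i] - u)^2), numeric(1))
    expect_gt(which.max(ctp), 40 - 8)
  }
})

test_that("hub is stable under rigid motion and renumbering", {
  ch <- toy_chain("clustered", 40, seed = 13)
  prof <- coupling_profile(ch)
  moved <- transform_chain(ch, seed = 99)
  expect_equal(coupling_profile(moved)$hub, prof$hub)
  shifted <- ch
  shifted$resno <- ch$resno + 100L
  expect_equal(coupling_profile(shifted)$hub, prof$hub + 100L)
})

test_that("find_peaks handles monotone, flat and interior-peak profiles", {
  mk_prof <- function(v, ids = seq_along(v)) {
    structure(list(residue_ids = as.integer(ids), averaged_ct = v),
              class = "coupling_profile")
  }
  mono <- mk_prof(seq(0, 1, length.out = 8))
  pk <- find_peaks(mono)
  expect_equal(pk$residue, 8L) # maximal terminus only
  expect_equal(nrow(find_peaks(mk_prof(rep(0, 10)))), 0L)

  v <- c(0, 0.2, 0, 0.05, 1, 0.3, 0.6, 0)
  pk <- find_peaks(mk_prof(v))
  expect_equal(pk$residue, c(5L, 7L, 2L)) # sorted by descending height
  expect_equal(pk$height, c(1, 0.6, 0.2))
  # below min_height_fraction is dropped
  v2 <- c(0, 0.01, 0, 1, 0)
  expect_equal(find_peaks(mk_prof(v2))$residue, 4L)
  # numbering gap: residue before the gap is compared to one neighbour only
  v3 <- c(0.1, 0.5, 0.4, 0.3, 0.9)
  pk3 <- find_peaks(mk_prof(v3, ids = c(1, 2, 3, 10, 11)))
  expect_true(all(c(2L, 11L) %in% pk3$residue))
})
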