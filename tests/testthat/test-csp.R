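test_that("weighted CSP matches the closed form", {
  free <- mk_peaklist(1:2, c("A", "G"), c(8.00, 8.30), c(120.0, 109.0))
  bound <- mk_peaklist(1:2, c("A", "G"), c(8.10, 8.30), c(120.5, 109.0),
                       label = "1:2", ratio = 2)
  prof <- compute_csp(free, bound, csp_params(alpha_n = 0.14))
  expect_equal(prof$data$value[1], sqrt(0.10^2 + (0.14 * 0.50)^2),
               tolerance = 1e-12)
  expect_identical(prof$data$value[2], 0)
  expect_equal(prof$params$alpha_n, 0.14)
})

test_that("CSP handles one-sided residues and disjoint lists", {
  free <- mk_peaklist(1:3, c("A", "G", "L"), c(8.0, 8.3, 8.1),
                      c(120, 109, 122))
  bound <- mk_peaklist(2:3, c("G", "L"), c(8.3, 8.2), c(109, 122),
                       ratio = 1)
  prof <- compute_csp(free, bound)
  expect_equal(prof$data$flag[prof$data$residue_index == 1], "missing")
  other <- mk_peaklist(9L, "V", 8.0, 121, ratio = 1)
  expect_error(compute_csp(free, other), "share no residue")
})

test_that("CSP is symmetric in free/bound and scales linearly", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 8
    h0 <- runif(n, 7.5, 9)
    n0 <- runif(n, 105, 130)
    dh <- rnorm(n, 0, 0.1)
    dn <- rnorm(n, 0, 0.5)
    a <- mk_peaklist(1:n, rep("A", n), h0, n0)
    b <- mk_peaklist(1:n, rep("A", n), h0 + dh, n0 + dn, ratio = 1)
    ab <- compute_csp(a, b)$data$value
    ba <- compute_csp(peak_list(b$entries), peak_list(a$entries, "x", 1))$data$value
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_true(all(ab >= 0))
    k <- runif(1, 0, 3)
    bk <- mk_peaklist(1:n, rep("A", n), h0 + k * dh, n0 + k * dn, ratio = 1)
    expect_equal(compute_csp(a, bk)$data$value, k * ab, tolerance = 1e-9)
  }
})

test_that("intensity ratios report broadening states", {
  free <- mk_peaklist(1:4, c("A", "G", "L", "V"), c(8, 8.3, 8.1, 8.2),
                      c(120, 109, 122, 121), intensity = c(1e6, 1e6, 1e6, 0))
  bound <- mk_peaklist(1:2, c("A", "G"), c(8, 8.3), c(120, 109),
                       intensity = c(1e6, 2e5), ratio = 2)
  prof <- compute_intensity_ratio(free, bound)
  d <- prof$data
  expect_equal(d$value[d$residue_index == 1], 1.0)
  expect_equal(d$value[d$residue_index == 2], 0.2)
  # present free, absent bound: broadened beyond detection
  expect_equal(d$flag[d$residue_index == 3], "broadened_out")
  expect_identical(d$value[d$residue_index == 3], 0)
  # zero free intensity cannot be divided
  expect_equal(d$flag[d$residue_index == 4], "invalid")
})

test_that("sliding-window smoothing averages over residue numbering", {
  tr <- residue_profile("x", 1:3, c(1, 2, 3))
  sm <- smooth_track(tr, 3)
  expect_equal(sm$data$value, c(1.5, 2, 2.5))  # ends truncate
  # constant stays constant, window 1 is the identity
  const <- residue_profile("x", 1:7, rep(4.2, 7))
  expect_equal(smooth_track(const, 5)$data$value, rep(4.2, 7))
  expect_equal(smooth_track(tr, 1)$data$value, tr$data$value)
  expect_error(smooth_track(tr, 2), "odd")
})

test_that("numbering gaps break the smoothing window; missing excluded", {
  # indices 1,2,4: the gap at 3 isolates residue 4
  tr <- residue_profile("x", c(1L, 2L, 4L), c(1, 2, 10))
  sm <- smooth_track(tr, 3)
  expect_equal(sm$data$value, c(1.5, 1.5, 10))
  # missing neighbour drops out of mean and divisor
  tr2 <- residue_profile("x", 1:3, c(1, NA, 3))
  sm2 <- smooth_track(tr2, 3)
  expect_equal(sm2$data$value[c(1, 3)], c(1, 3))
  expect_true(is.na(sm2$data$value[2]))
  expect_equal(sm2$data$flag[2], "missing")
})

test_that("smoothing preserves the mean of gap-free tracks up to ends", {
  set.seed(7)
  v <- rnorm(40)
  tr <- residue_profile("x", 1:40, v)
  sm <- smooth_track(tr, 3)
  interior <- 2:39
  # interior smoothed mean equals a weighted mean of the original values;
  # check the global mean moves by less than the end-effect bound
  expect_lt(abs(mean(sm$data$value) - mean(v)), 2 * max(abs(v)) / 40)
  # idempotent only for window 1
  expect_identical(smooth_track(sm, 1)$data$value, sm$data$value)
  expect_false(isTRUE(all.equal(smooth_track(sm, 3)$data$value,
                                sm$data$value)))
})

test_that("noiseless synthetic CSP grows monotonically with molar ratio", {
  sim <- generate_titration(noiseless_config(), seed = 5)
  free <- sim$series$points[[1]]
  contact <- sim$ground_truth$contact_residues
  prev <- NULL
  for (j in 2:4) {
    prof <- compute_csp(free, sim$series$points[[j]])
    v <- prof$data$value[match(contact, prof$data$residue_index)]
    obs <- !is.na(v)
    if (!is.null(prev)) {
      both <- obs & !is.na(prev)
      expect_true(all(v[both] > prev[both]))
    }
    prev <- v
  }
})
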