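test_that("a planted run above the adaptive threshold is the only patch", {
  set.seed(2)
  idx <- 1:150
  val <- rep(0.01, 150) + rnorm(150, 0, 0.001)
  val[113:117] <- 0.20
  tr <- residue_profile("csp", idx, val)
  patches <- detect_patches(tr, params = patch_params())
  expect_equal(nrow(patches), 1)
  expect_equal(patches$start_index, 113L)
  expect_equal(patches$end_index, 117L)
  expect_equal(patches$tracks, "csp")
  expect_gt(patches$peak_value, 0.19)
})

test_that("flat tracks yield no patches", {
  tr <- residue_profile("csp", 1:60, rep(0.02, 60))
  expect_equal(nrow(detect_patches(tr)), 0)
})

test_that("gap merging and minimum-length rules apply", {
  p <- patch_params(csp_threshold_mode = "fixed", csp_fixed_cutoff = 0.1,
                    min_len = 3, max_gap = 1)
  val <- rep(0, 30)
  val[c(10, 11, 13, 14)] <- 0.3  # two runs of 2 with a single gap
  tr <- residue_profile("csp", 1:30, val)
  patches <- detect_patches(tr, params = p)
  expect_equal(nrow(patches), 1)
  expect_equal(c(patches$start_index, patches$end_index), c(10L, 14L))
  expect_equal(patches$length, 5L)
  # an isolated pair is below min_len
  val2 <- rep(0, 30)
  val2[c(20, 21)] <- 0.3
  expect_equal(nrow(detect_patches(residue_profile("csp", 1:30, val2),
                                   params = p)), 0)
  # max_gap = 0 keeps the runs apart and drops both
  p0 <- patch_params(csp_threshold_mode = "fixed", csp_fixed_cutoff = 0.1,
                     min_len = 3, max_gap = 0)
  expect_equal(nrow(detect_patches(tr, params = p0)), 0)
})

test_that("broadened-out residues count as significant", {
  csp <- residue_profile("csp", 1:40, rep(0.01, 40))
  rat <- residue_profile("intensity_ratio", 1:40,
                         c(rep(1, 19), 0, 0, 0, rep(1, 18)),
                         flag = c(rep("ok", 19), rep("broadened_out", 3),
                                  rep("ok", 18)))
  patches <- detect_patches(csp, rat,
                            patch_params(csp_threshold_mode = "fixed",
                                         csp_fixed_cutoff = 0.5))
  expect_equal(nrow(patches), 1)
  expect_equal(c(patches$start_index, patches$end_index), c(20L, 22L))
  expect_equal(patches$n_missing, 3L)
  expect_match(patches$tracks, "intensity_ratio")
})

test_that("patch lists are deterministic, disjoint and sorted", {
  set.seed(99)
  for (rep in 1:15) {
    val <- abs(rnorm(120, 0, 0.004))
    k <- sample(3:110, 1)
    val[k:(k + sample(2:7, 1))] <- runif(1, 0.1, 0.3)
    tr <- residue_profile("csp", 1:120, val)
    a <- detect_patches(tr)
    b <- detect_patches(tr)
    expect_identical(as.data.frame(a), as.data.frame(b))
    if (nrow(a) > 1) {
      expect_true(all(diff(a$start_index) > 0))
      expect_true(all(a$start_index[-1] > a$end_index[-nrow(a)]))
    }
    expect_true(all(a$length >= 3))
  }
})

test_that("all-missing input warns and returns no patches", {
  tr <- residue_profile("csp", 1:10, rep(NA_real_, 10))
  expect_warning(p <- detect_patches(tr), "missing")
  expect_equal(nrow(p), 0)
})

test_that("patch comparison classifies shared and condition-specific patches", {
  mk <- function(s, e) tibble::tibble(start_index = s, end_index = e,
                                      length = e - s + 1L, tracks = "csp",
                                      peak_value = 0.2, mean_value = 0.15,
                                      n_missing = 0L)
  same <- compare_patch_sets(mk(113L, 117L), mk(113L, 117L))
  expect_true(all(same$status == "shared"))
  expect_equal(same$overlap_residues, c(5L, 5L))
  # a patch present in one condition only (methylation-dependent contact)
  lost <- compare_patch_sets(mk(164L, 174L), mk(integer(0), integer(0))[0, ])
  expect_equal(lost$status, "a_only")
  part <- compare_patch_sets(mk(10L, 15L), mk(14L, 20L))
  expect_true(all(part$status == "shared"))
  expect_equal(part$overlap_residues, c(2L, 2L))
})

test_that("planted patches are recovered with few spurious calls", {
  jacs <- c()
  n_false <- c()
  sens <- c()
  for (seed in 1:8) {
    sim <- generate_titration(sim_config(), seed = seed)
    res <- analyze_titration(sim$series)
    rep <- answer_key_report(sim$ground_truth, res$patches)
    jacs <- c(jacs, rep$patch_jaccard)
    n_false <- c(n_false, rep$n_false)
    sens <- c(sens, rep$sensitivity)
  }
  expect_gte(median(sens), 0.9)
  expect_true(all(jacs >= 0.6))
  expect_lte(median(n_false), 1)
})
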