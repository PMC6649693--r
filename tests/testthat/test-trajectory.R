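mk_traj <- function(ratios, h, n, idx = 1L) {
  structure(list(residue_index = idx, residue_code = "A",
                 points = tibble::tibble(molar_ratio = ratios, shift_h = h,
                                         shift_n = n,
                                         intensity = rep(1e6, length(h))),
                 n_observed = sum(!is.na(h) & !is.na(n))),
            class = "peak_trajectory")
}

test_that("collinear points are linear with zero deviation", {
  tr <- mk_traj(c(0, 0.5, 1), 8 + c(0, 0.05, 0.1), 120 + c(0, 0.25, 0.5))
  call <- classify_trajectory(tr, noise_sd = 0.001)
  expect_equal(call$label, "linear")
  expect_lt(call$max_deviation, 1e-12)
  # all-coincident points degenerate gracefully
  same <- mk_traj(c(0, 1, 2), rep(8, 3), rep(120, 3))
  expect_equal(classify_trajectory(same, 0.001)$label, "linear")
})

test_that("fewer than three observed points is insufficient", {
  tr <- mk_traj(c(0, 0.5, 1), c(8, NA, 8.1), c(120, NA, 120.5))
  expect_equal(classify_trajectory(tr, 0.001)$label, "insufficient")
})

test_that("a vanished endpoint is labelled broadened_out", {
  tr <- mk_traj(c(0, 0.5, 1, 2), c(8, 8.02, 8.05, NA),
                c(120, 120.1, 120.3, NA))
  call <- classify_trajectory(tr, 0.001)
  expect_equal(call$label, "broadened_out")
  expect_equal(call$n_observed, 3)
})

test_that("TLS deviation matches the exhaustive angle-scan oracle", {
  set.seed(31)
  for (rep in 1:25) {
    m <- sample(3:5, 1)
    x <- rnorm(m, 8, 0.05)
    y <- 0.14 * rnorm(m, 120, 0.4)
    got <- cspmap:::tls_max_deviation(x, y)
    want <- tls_maxdev_scan(x, y)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("deviation is scale-equivariant and rotation-invariant", {
  set.seed(8)
  x <- rnorm(4, 0, 0.05)
  y <- rnorm(4, 0, 0.05)
  d0 <- cspmap:::tls_max_deviation(x, y)
  for (k in c(0.5, 2, 7)) {
    expect_equal(cspmap:::tls_max_deviation(k * x, k * y), k * d0,
                 tolerance = 1e-10)
  }
  for (th in c(0.3, 1.2, 2.5)) {
    xr <- cos(th) * x - sin(th) * y
    yr <- sin(th) * x + cos(th) * y
    expect_equal(cspmap:::tls_max_deviation(xr, yr), d0, tolerance = 1e-10)
  }
})

test_that("noise-only trajectories are gated by path length", {
  set.seed(12)
  for (rep in 1:20) {
    tr <- mk_traj(c(0, 0.5, 1, 2), 8 + rnorm(4, 0, 0.001),
                  120 + rnorm(4, 0, 0.001))
    call <- classify_trajectory(tr, noise_sd = 0.001)
    expect_false(call$label == "nonlinear" && call$path_length <= 0.004)
  }
})

test_that("two-site geometry produces non-collinear trajectories", {
  sim <- generate_titration(discrimination_config(two_site = TRUE, noise = 0),
                            seed = 4)
  calls <- classify_trajectories(sim$series, noise_sd = 0.001)
  obs <- calls[calls$label %in% c("linear", "nonlinear"), ]
  expect_gt(nrow(obs), 150)
  # noiseless curvature from the weak second site exceeds 3x the nominal
  # noise for essentially every residue
  expect_gte(mean(obs$label == "nonlinear"), 0.95)
  # single-site noiseless control: exactly collinear
  sim1 <- generate_titration(discrimination_config(two_site = FALSE,
                                                   noise = 0), seed = 4)
  calls1 <- classify_trajectories(sim1$series, noise_sd = 0.001)
  obs1 <- calls1[calls1$label %in% c("linear", "nonlinear"), ]
  expect_true(all(obs1$label == "linear"))
  expect_lt(max(obs1$max_deviation), 1e-12)
})

test_that("series extraction preserves point order and missingness", {
  sim <- generate_titration(sim_config(), seed = 21)
  trajs <- extract_trajectories(sim$series)
  free_idx <- sim$series$points[[1]]$entries$residue_index
  expect_equal(length(trajs), length(free_idx))
  t1 <- trajs[[1]]
  expect_equal(t1$points$molar_ratio, c(0, 0.5, 1, 2))
  # a residue dropped at some ratio keeps a missing row there
  dropped <- sim$ground_truth$dropped_by_ratio
  ratios <- names(dropped)
  hit <- NULL
  for (j in seq_along(dropped)) {
    cand <- intersect(dropped[[j]], free_idx)
    if (length(cand) > 0) {
      hit <- c(cand[1], j)
      break
    }
  }
  if (!is.null(hit)) {
    tr <- trajs[[match(hit[1], free_idx)]]
    expect_true(is.na(tr$points$shift_h[hit[2]]))
    expect_lt(tr$n_observed, nrow(tr$points))
  }
})
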