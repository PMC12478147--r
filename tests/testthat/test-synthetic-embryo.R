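# Synthetic embryo generator: determinism, presets, ground truth.

test_that("generation is deterministic under a fixed seed", {
  p <- generator_params(n_nuclei = 60L, n_rows = 3L, n_timepoints = 8L,
                        seed = 11L)
  s1 <- generate_tracks(p)
  s2 <- generate_tracks(p)
  expect_identical(s1$tracks, s2$tracks)
  s3 <- generate_tracks(generator_params(n_nuclei = 60L, n_rows = 3L,
                                         n_timepoints = 8L, seed = 12L))
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("the static preset freezes all noise-free positions", {
  p <- generator_preset("static", n_nuclei = 40L, n_rows = 2L,
                        n_timepoints = 6L, noise_sigma = 0)
  sim <- generate_tracks(p)
  sp <- split(sim$tracks, sim$tracks$track_id)
  for (tr in sp) {
    expect_lt(max(abs(tr$x_um - tr$x_um[1L])), 1e-12)
    expect_lt(max(abs(tr$z_um - tr$z_um[1L])), 1e-12)
  }
})

test_that("ground-truth areas follow the contraction schedule exactly", {
  sim <- generate_tracks(generator_params(n_nuclei = 100L, n_rows = 5L,
                                          n_timepoints = 30L,
                                          noise_sigma = 0, seed = 0L))
  tr <- sim$truth
  for (r in 1:5) {
    z <- tr[tr$row == r, ]
    expect_equal(z$A[nrow(z)] / z$A[1L], 0.6, tolerance = 1e-10)
  }
  # inner rows start contracting earlier than outer rows
  t_s1 <- max(2L, round(0.6 * 30))
  a3 <- tr$A[tr$row == 3L]
  a5 <- tr$A[tr$row == 5L]
  expect_lt(a3[t_s1 + 4L] / a3[1L], a5[t_s1 + 4L] / a5[1L])
})

test_that("the S1 flow shows the divergent length signature in ground truth", {
  sim <- generate_tracks(generator_params(noise_sigma = 0,
                                          n_timepoints = 40L,
                                          s1_fraction = 1,
                                          contraction_final = 1))
  tr <- sim$truth
  expect_true(all(diff(tr$L[tr$row == 1L]) < 0))
  expect_true(all(diff(tr$L[tr$row == 5L]) > 0))
  R3 <- tr$R[tr$row == 3L]
  expect_lt(max(abs(R3 / R3[1L] - 1)), 0.05)
})

test_that("ground_truth_metrics validates its indices", {
  sim <- generate_tracks(generator_params(n_nuclei = 40L, n_rows = 2L,
                                          n_timepoints = 4L))
  expect_equal(nrow(ground_truth_metrics(sim, 1L, 2L)), 1L)
  expect_error(ground_truth_metrics(sim, 9L, 1L),
               class = "morphoring_index_error")
})

test_that("inconsistent generator parameters are rejected", {
  expect_error(generator_params(n_nuclei = 4L, n_rows = 5L),
               class = "morphoring_params_error")
  expect_error(generator_params(noise_sigma = -1),
               class = "morphoring_params_error")
  expect_error(generator_params(u_band = 0.05, row_spacing = 0.1),
               class = "morphoring_params_error")
})
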