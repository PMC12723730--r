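test_that("two-tensor fit recovers population-weighted tensors exactly at zero noise", {
  fx <- make_fixture(n_vectors_per_domain = 30, seed = 4)
  rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors, p_minor = 0.3)
  f <- rdc_fit(rd, list(fx$conformer1, fx$conformer2), jackknife = FALSE)
  expect_equal(unname(f$tensors[[1]]$elements),
               unname(0.7 * fx$tensors[[1]]$elements), tolerance = 1e-9)
  expect_equal(unname(f$tensors[[2]]$elements),
               unname(0.3 * fx$tensors[[2]]$elements), tolerance = 1e-9)
  expect_false(f$degenerate)
  expect_equal(f$q_rms, 0, tolerance = 1e-9)
  expect_lte(f$q_rms, rdc_fit(rd, fx$conformer1, jackknife = FALSE)$q_rms)
})

test_that("populations are exact for all mixing fractions at zero noise", {
  fx <- make_fixture(n_vectors_per_domain = 30, seed = 4)
  for (p in seq(0.05, 0.95, by = 0.05)) {
    rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors, p_minor = p)
    f <- rdc_fit(rd, list(fx$conformer1, fx$conformer2), jackknife = FALSE)
    expect_equal(unname(f$populations[2]), p, tolerance = 1e-9)
  }
  # pure states
  rd0 <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors, p_minor = 0)
  f0 <- rdc_fit(rd0, list(fx$conformer1, fx$conformer2), jackknife = FALSE)
  expect_lt(generalized_order(f0$tensors[[2]]),
            1e-8 * generalized_order(f0$tensors[[1]]))
  expect_equal(unname(f0$populations), c(1, 0), tolerance = 1e-8)
})

test_that("population extraction handles equal and one-sided tensors", {
  s <- random_tensor(5)
  fit <- list(tensors = list(s, s))
  expect_equal(unname(tensor_populations(fit$tensors)), c(0.5, 0.5),
               ignore_attr = TRUE)
  z <- saupe_tensor(rep(0, 5))
  expect_equal(unname(tensor_populations(list(s, z))), c(1, 0),
               ignore_attr = TRUE)
  expect_error(tensor_populations(list(z, z)), "zero")
  # constructed p = 0.16 with shared intrinsic magnitude
  fx <- make_fixture(n_vectors_per_domain = 25, seed = 6)
  rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors, p_minor = 0.16)
  f <- rdc_fit(rd, list(fx$conformer1, fx$conformer2), jackknife = FALSE)
  expect_equal(unname(f$populations[2]), 0.16, tolerance = 1e-6)
})

test_that("degeneracy guard rejects at and above the closed threshold", {
  mk <- function(da1, da2) {
    list(tensors = list(as_saupe_tensor(diag(c(-1, -1, 2)) * da1),
                        as_saupe_tensor(diag(c(-1, -1, 2)) * da2)),
         reference_da = 1)
  }
  expect_false(degeneracy_guard(mk(0.5, 0.5)))      # sum = Da_ref
  expect_true(degeneracy_guard(mk(1, 1)))           # boundary: sum = 2 Da_ref
  expect_true(degeneracy_guard(mk(5, -5)))          # opposing giants
  expect_false(degeneracy_guard(mk(0.9, 0.9)))
})

test_that("near-identical conformer pairs are flagged, never silently fit", {
  fx <- make_fixture(n_vectors_per_domain = 30, seed = 7)
  rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors,
                   p_minor = 0.2, sigma_rdc = 0.5, seed = 8)
  # conformer 2 differing by a 0.5-degree rotation only
  v2 <- rotate_vectors(fx$conformer1, rotation_about_axis(fx$axis, 0.5),
                       residues = fx$domain_b$residues)
  f <- suppressWarnings(rdc_fit(rd, list(fx$conformer1, v2),
                                jackknife = FALSE))
  expect_true(f$degenerate)
  # strictly identical conformers: rank collapses, flagged
  fid <- suppressWarnings(rdc_fit(rd, list(fx$conformer1, fx$conformer1),
                                  jackknife = FALSE))
  expect_true(fid$degenerate)
  expect_lt(fid$rank, 9)
})

test_that("model selection prefers two states only when the data support them", {
  fx <- make_fixture(n_vectors_per_domain = 40, seed = 9)
  # strong two-state signal, low noise
  rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors,
                   p_minor = 0.3, sigma_rdc = 0.3, seed = 10)
  single <- rdc_fit(rd, fx$conformer1, jackknife = FALSE)
  two <- rdc_fit(rd, list(fx$conformer1, fx$conformer2), jackknife = FALSE)
  ms <- model_selection(single, two)
  expect_equal(ms$preferred, "two-state")
  expect_gt(ms$aic_delta, 0)
  expect_lt(ms$f_significance, 0.05)
  # equal residual sums: penalty-only difference, AIC delta = -10
  ms0 <- model_selection(single, single)
  expect_equal(ms0$aic_delta, -10)
  expect_equal(ms0$preferred, "single")
  expect_gt(ms0$f_significance, 0.99)
})

test_that("grid landscape is flat for rigid same-axis rotations (equivalence theorem)", {
  fx <- make_fixture(n_vectors_per_domain = 25, seed = 11)
  # uniform weights (uncertainty proportional to scale) keep the nested
  # least-squares comparison exact on the unweighted q_rms scale
  rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors,
                   p_minor = 0.2, sigma_rdc = 0.5, seed = 12,
                   uncertainty = rdc_scales()[fx$conformer1$type])
  gs <- grid_search_two_state(rd, fx$conformer1, fx$domain_b$residues,
                              fx$axis, major_range = c(-1, 1),
                              minor_range = c(15, 45),
                              major_step = 1, minor_step = 7.5)
  ok <- !gs$grid$degenerate
  expect_gt(sum(ok), 5)
  expect_lt(diff(range(gs$grid$q2[ok])), 1e-10)
  expect_lt(diff(range(gs$grid$q2_jk[ok])), 1e-10)
  # two-tensor fit never beats single fit by less than zero
  expect_true(all(gs$grid$delta_q[ok] >= -1e-12))
  # population map is exact at the true node (0, 30) at zero noise
  rd0 <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors, p_minor = 0.2)
  gs0 <- grid_search_two_state(rd0, fx$conformer1, fx$domain_b$residues,
                               fx$axis, major_range = c(0, 0),
                               minor_range = c(15, 45),
                               major_step = 1, minor_step = 7.5)
  node <- gs0$grid[gs0$grid$r_major == 0 & gs0$grid$r_minor == 30, ]
  expect_equal(node$p_minor, 0.2, tolerance = 1e-8)
  expect_equal(node$q2, 0, tolerance = 1e-9)
  expect_s3_class(gs0, "rdc_grid")
  expect_gt(gs0$optimum$delta_q_sigma, 0)
})

test_that("a wholly degenerate grid raises an error", {
  fx <- make_fixture(n_vectors_per_domain = 20, seed = 13)
  rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors,
                   p_minor = 0.2, sigma_rdc = 0.5, seed = 14)
  expect_error(
    suppressWarnings(grid_search_two_state(
      rd, fx$conformer1, fx$domain_b$residues, fx$axis,
      major_range = c(0, 0), minor_range = c(0.2, 0.6),
      major_step = 1, minor_step = 0.2)),
    "no resolvable two-state region")
})
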