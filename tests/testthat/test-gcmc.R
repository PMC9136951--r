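# The GCMC sampler: acceptance rules, equilibrium Adams value,
# reproducibility, conservation, and the ideal-gas stationary law.

test_that("equilibrium Adams value follows beta mu_ex + ln(V/V_std)", {
  p <- adams_parameters(T = 300, mu_ex = 0, V_std = 30)
  roi <- roi_cuboid(c(0, 0, 0), c(30, 1, 1))      # V = 30 = V_std
  expect_equal(equilibrium_adams(p, roi), 0)
  # calibrated excess chemical potential with the buried-site ROI box
  p2 <- adams_parameters(T = 300, mu_ex = -25.9, V_std = 30)
  roi2 <- roi_cuboid(c(50, 50, 50), c(10.9, 14.0, 12.3))
  expect_equal(equilibrium_adams(p2, roi2), -6.24729134, tolerance = 1e-6)
  # doubling the ROI volume adds exactly ln 2
  roi3 <- roi_cuboid(c(50, 50, 50), c(21.8, 14.0, 12.3))
  expect_equal(equilibrium_adams(p2, roi3) - equilibrium_adams(p2, roi2),
               log(2), tolerance = 1e-12)
  expect_error(equilibrium_adams(p2, 0), "positive")
})

test_that("insertion/deletion acceptance probabilities follow the Adams rules", {
  p0 <- adams_parameters(B = 0, T = 300)
  expect_equal(insertion_acceptance(0, 0, p0), 1)
  expect_equal(deletion_acceptance(1, 0, p0), 1)
  expect_equal(insertion_acceptance(3, Inf, p0), 0)
  expect_error(deletion_acceptance(0, 0, p0), "at least one")
  # hand-evaluated: N = 4, dU = -10 kJ/mol, B = -6.25, T = 300
  p <- adams_parameters(B = -6.25, T = 300)
  expect_equal(insertion_acceptance(4, -10, p), 0.0212720898,
               tolerance = 1e-8)
  # probabilities stay in [0, 1] and deletion vanishes as B grows
  for (B in seq(-10, 10, by = 2.5)) {
    pB <- adams_parameters(B = B, T = 300)
    for (dU in c(-20, 0, 20)) {
      expect_gte(insertion_acceptance(2, dU, pB), 0)
      expect_lte(insertion_acceptance(2, dU, pB), 1)
      expect_gte(deletion_acceptance(2, dU, pB), 0)
      expect_lte(deletion_acceptance(2, dU, pB), 1)
    }
  }
  pdel <- vapply(seq(0, 12, by = 3), function(B)
    deletion_acceptance(3, 1, adams_parameters(B = B, T = 300)), numeric(1))
  expect_true(all(diff(pdel) <= 0))
})

test_that("a fixed seed reproduces a run bit-for-bit", {
  cfg <- random_test_config(n_water = 2, seed = 5)
  p <- adams_parameters(B = -8, T = 300)
  t1 <- run_gcmc(cfg, p, move_mix(), n_moves = 2000, record_every = 10,
                 seed = 123)
  t2 <- run_gcmc(cfg, p, move_mix(), n_moves = 2000, record_every = 10,
                 seed = 123)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$final$positions, t2$final$positions)
  t3 <- run_gcmc(cfg, p, move_mix(), n_moves = 2000, record_every = 10,
                 seed = 124)
  expect_false(identical(t1$records$N, t3$records$N))
})

test_that("a mix without insertions/deletions conserves N exactly", {
  cfg <- random_test_config(n_water = 3, seed = 11)
  p <- adams_parameters(B = 0, T = 300)
  mix <- move_mix(insert = 0, delete = 0, translate = 0.5, rotate = 0.5)
  tr <- run_gcmc(cfg, p, mix, n_moves = 3000, record_every = 10, seed = 1)
  expect_true(all(tr$records$N == 3L))
  # translations never carry a water out of the ROI
  expect_true(all(roi_contains(cfg$roi, tr$final$positions)))
})

test_that("acceptance counters are monotone and consistent with attempts", {
  cfg <- random_test_config(n_water = 1, seed = 2)
  p <- adams_parameters(B = -7, T = 300)
  tr <- run_gcmc(cfg, p, move_mix(), n_moves = 5000, record_every = 50,
                 seed = 9)
  for (col in c("acc_insert", "acc_delete", "acc_translate", "acc_rotate")) {
    expect_true(all(diff(tr$records[[col]]) >= 0))
  }
  expect_true(all(tr$counters$accepted <= tr$counters$attempted))
  expect_true(all(tr$records$N >= 0))
})

test_that("the ideal (non-interacting) system samples Poisson(e^B)", {
  cfg <- water_configuration(
    simulation_box(c(30, 30, 30), cutoff = 10),
    interaction_sites(matrix(numeric(0), 0, 3)),
    load_water_model("ideal"),
    roi = roi_sphere(c(15, 15, 15), 3)
  )
  B <- 1.0
  tr <- run_gcmc(cfg, adams_parameters(B = B, T = 300), move_mix(),
                 n_moves = 3e4, record_every = 5, seed = 17)
  N <- tr$records$N[-(1:1200)]
  se <- block_se(N, 25)
  expect_lt(abs(mean(N) - ideal_mean_N(B)), 3 * se)
})

test_that("the running energy matches a fresh total at the end of a run", {
  cfg <- random_test_config(n_water = 2, seed = 21)
  p <- adams_parameters(B = -9, T = 300)
  tr <- run_gcmc(cfg, p, move_mix(), n_moves = 4000, record_every = 4000,
                 seed = 31)
  expect_equal(utils::tail(tr$records$U_total, 1), total_energy(tr$final),
               tolerance = 1e-6)
})
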