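# Pairwise energetics: LJ/Coulomb values, cutoff and hard-core contracts,
# locality of move energy changes.

box50 <- simulation_box(c(50, 50, 50), cutoff = 12)

test_that("pair energies reproduce LJ landmarks and Coulomb's law", {
  a <- list(x = 0, y = 0, z = 0, charge = 0, sigma = 3.2, epsilon = 0.5)
  b <- list(x = 3.2, y = 0, z = 0, charge = 0, sigma = 3.2, epsilon = 0.5)
  expect_equal(pair_energy(a, b, box50), 0, tolerance = 1e-12)
  b$x <- 2^(1 / 6) * 3.2
  expect_equal(pair_energy(a, b, box50), -0.5, tolerance = 1e-12)
  # unit point charges at 1 A: the Coulomb constant itself
  qa <- list(x = 0, y = 0, z = 0, charge = 1, sigma = 0, epsilon = 0)
  qb <- list(x = 1, y = 0, z = 0, charge = 1, sigma = 0, epsilon = 0)
  expect_equal(pair_energy(qa, qb, box50), 138.935458, tolerance = 1e-9)
  # mixed sigmas combine by Lorentz-Berthelot
  c1 <- list(x = 0, y = 0, z = 0, charge = 0, sigma = 2.0, epsilon = 1.0)
  c2 <- list(x = 2.75, y = 0, z = 0, charge = 0, sigma = 3.5, epsilon = 0.25)
  expect_equal(pair_energy(c1, c2, box50), 0, tolerance = 1e-10)
})

test_that("cutoff, hard core and minimum image behave as contracted", {
  a <- list(x = 1, y = 1, z = 1, charge = 0.5, sigma = 3.0, epsilon = 0.3)
  b <- list(x = 1 + 12.0001, y = 1, z = 1, charge = -0.5, sigma = 3.0,
            epsilon = 0.3)
  expect_identical(pair_energy(a, b, box50), 0)           # beyond cutoff
  b$x <- 1 + 1e-8
  expect_identical(pair_energy(a, b, box50), Inf)         # hard core
  # minimum image: 49 A apart in a 50 A box is 1 A
  qa <- list(x = 0.5, y = 25, z = 25, charge = 1, sigma = 0, epsilon = 0)
  qb <- list(x = 49.5, y = 25, z = 25, charge = 1, sigma = 0, epsilon = 0)
  expect_equal(pair_energy(qa, qb, box50), 138.935458, tolerance = 1e-9)
  # symmetry is exact
  expect_identical(pair_energy(qa, qb, box50), pair_energy(qb, qa, box50))
})

test_that("water interaction energies match the brute-force all-pairs sum", {
  cfg <- random_test_config(n_water = 3, seed = 42)
  # total from per-water decomposition vs independent all-pairs loop
  expect_equal(total_energy(cfg), brute_total_energy(cfg), tolerance = 1e-8)
  # U_ww double counts each pair: total ww = half the sum over waters
  e <- vapply(1:3, function(i) water_interaction_energy(cfg, i), numeric(2))
  cfg_nohost <- water_configuration(cfg$box,
                                    interaction_sites(matrix(numeric(0), 0, 3)),
                                    cfg$model, cfg$positions,
                                    cfg$orientations, cfg$roi)
  expect_equal(sum(e["U_sw", ]) + 0.5 * sum(e["U_ww", ]), total_energy(cfg),
               tolerance = 1e-10)
  expect_equal(0.5 * sum(e["U_ww", ]), brute_total_energy(cfg_nohost),
               tolerance = 1e-8)
  # single water, no hosts
  cfg1 <- water_configuration(cfg$box,
                              interaction_sites(matrix(numeric(0), 0, 3)),
                              cfg$model, cfg$positions[1, , drop = FALSE],
                              cfg$orientations[1, , drop = FALSE], cfg$roi)
  expect_equal(unname(water_interaction_energy(cfg1, 1)), c(0, 0))
})

test_that("move energy changes equal full-system energy differences", {
  cfg <- random_test_config(n_water = 3, seed = 7)
  u0 <- total_energy(cfg)
  set.seed(99)
  # insertion
  p_new <- as.vector(roi_sample(cfg$roi, 1))
  q_new <- as.vector(random_quaternions(1))
  dU <- move_delta_energy(cfg, gc_move("insert", position = p_new,
                                       orientation = q_new))
  cfg_ins <- water_configuration(cfg$box, cfg$host, cfg$model,
                                 rbind(cfg$positions, p_new),
                                 rbind(cfg$orientations, q_new), cfg$roi)
  expect_equal(dU, total_energy(cfg_ins) - u0, tolerance = 1e-8)
  # deletion
  dU <- move_delta_energy(cfg, gc_move("delete", index = 2))
  cfg_del <- water_configuration(cfg$box, cfg$host, cfg$model,
                                 cfg$positions[-2, ], cfg$orientations[-2, ],
                                 cfg$roi)
  expect_equal(dU, total_energy(cfg_del) - u0, tolerance = 1e-8)
  # translation and rotation
  p2 <- cfg$positions[1, ] + c(0.2, -0.1, 0.15)
  dU <- move_delta_energy(cfg, gc_move("translate", index = 1,
                                       position = p2))
  cfg_tr <- cfg; cfg_tr$positions[1, ] <- p2
  expect_equal(dU, total_energy(cfg_tr) - u0, tolerance = 1e-8)
  q2 <- as.vector(random_quaternions(1))
  dU <- move_delta_energy(cfg, gc_move("rotate", index = 1,
                                       orientation = q2))
  cfg_rot <- cfg; cfg_rot$orientations[1, ] <- q2
  expect_equal(dU, total_energy(cfg_rot) - u0, tolerance = 1e-8)
  # trivial cases: far insertion and isolated deletion cost nothing
  far <- water_configuration(box50, interaction_sites(matrix(numeric(0), 0, 3)),
                             cfg$model, matrix(c(5, 5, 5), 1),
                             random_quaternions(1),
                             roi_cuboid(c(25, 25, 25), c(48, 48, 48)))
  expect_equal(move_delta_energy(far, gc_move("insert",
                                              position = c(45, 45, 45),
                                              orientation = c(1, 0, 0, 0))), 0)
  expect_equal(move_delta_energy(far, gc_move("delete", index = 1)), 0)
})

test_that("energies are invariant under rigid translation (non-periodic)", {
  model <- load_water_model("tip4p")
  box <- simulation_box(c(100, 100, 100), periodic = FALSE, cutoff = 12)
  roi <- roi_cuboid(c(50, 50, 50), c(20, 20, 20))
  set.seed(3)
  pos <- roi_sample(roi, 4)
  q <- random_quaternions(4)
  cfg <- water_configuration(box, interaction_sites(matrix(numeric(0), 0, 3)),
                             model, pos, q, roi)
  shift <- c(3.7, -2.1, 5.5)
  cfg2 <- water_configuration(box, cfg$host, model,
                              sweep(pos, 2, shift, "+"), q,
                              roi_cuboid(c(50, 50, 50) + shift, c(20, 20, 20)))
  expect_equal(total_energy(cfg), total_energy(cfg2), tolerance = 1e-8)
})

test_that("water models validate geometry, neutrality and parameter files", {
  m3 <- load_water_model("tip3p")
  expect_equal(m3$rho0, 0.0329)
  expect_equal(sum(m3$sites$charge), 0, tolerance = 1e-12)
  # O-H bond length is the rigid TIP3P value
  expect_equal(sqrt(sum(m3$geometry[2, ]^2)), 0.9572, tolerance = 1e-4)
  m4 <- load_water_model("tip4p")
  expect_equal(m4$rho0, 0.0332)
  expect_equal(nrow(m4$sites), 4)
  expect_true("water_virtual" %in% m4$sites$kind)
  # a charged model is rejected
  bad <- m3$sites
  bad$charge[1] <- bad$charge[1] + 1e-3
  expect_error(water_model("bad", 0.033, bad), "neutral")
  # ROI must fit in the periodic cell
  expect_error(
    water_configuration(simulation_box(c(30, 30, 30), cutoff = 10),
                        interaction_sites(matrix(numeric(0), 0, 3)),
                        m3, roi = roi_sphere(c(2, 15, 15), 3)),
    "primary"
  )
})
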