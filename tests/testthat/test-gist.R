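# GIST: binning conventions, energy conservation, entropy estimators,
# free-energy assembly and density maps.

tip3p <- load_water_model("tip3p")

frame1 <- function(X, Q = NULL, U_sw = NULL, U_ww = NULL) {
  X <- matrix(X, ncol = 3)
  n <- nrow(X)
  if (is.null(Q)) Q <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  if (is.null(U_sw)) U_sw <- numeric(n)
  if (is.null(U_ww)) U_ww <- numeric(n)
  list(positions = X, orientations = Q, U_sw = U_sw, U_ww = U_ww)
}

test_that("binning uses half-open voxels and drops out-of-grid waters", {
  g <- gist_grid(c(0, 0, 0), 0.5, c(4, 4, 4))
  # exactly on an internal boundary -> higher-index voxel
  expect_equal(voxel_index(g, matrix(c(0.5, 0, 0), 1)), 2L)
  expect_equal(voxel_index(g, matrix(c(0, 0, 0), 1)), 1L)
  expect_equal(voxel_index(g, matrix(c(1.99, 1.99, 1.99), 1)), 64L)
  expect_true(is.na(voxel_index(g, matrix(c(2.0, 0, 0), 1))))  # outside
  gf <- gist_frames(list(frame1(c(0.6, 0.6, 0.6)),
                         frame1(c(5, 5, 5))), tip3p)
  obs <- bin_waters(gf, g)
  expect_equal(nrow(obs), 1)
  expect_equal(attr(obs, "n_dropped"), 1)
  r <- gist_analysis(gf, g, n_boot = 0)
  expect_equal(sum(r$N_k), 1)
})

test_that("voxel energies conserve the direct totals exactly", {
  g <- gist_grid(c(0, 0, 0), 0.5, c(6, 6, 6))
  set.seed(8)
  frames <- lapply(1:20, function(i) {
    n <- sample(1:5, 1)
    X <- matrix(runif(3 * n, 0.1, 2.9), n, 3)
    frame1(X, U_sw = rnorm(n, -20, 5), U_ww = rnorm(n, -10, 3))
  })
  gf <- gist_frames(frames, tip3p)
  r <- gist_analysis(gf, g, n_boot = 0)
  tot_sw <- sum(vapply(frames, function(f) sum(f$U_sw), numeric(1))) / 20
  tot_ww <- sum(vapply(frames, function(f) sum(f$U_ww), numeric(1))) / 2 / 20
  expect_equal(sum(r$Esw), tot_sw, tolerance = 1e-10)
  expect_equal(sum(r$Eww), tot_ww, tolerance = 1e-10)
  expect_equal(sum(r$N_k), sum(vapply(frames, function(f)
    nrow(f$positions), numeric(1))))
  # two waters in different voxels, one frame: each voxel gets half the pair
  gf2 <- gist_frames(list(frame1(rbind(c(0.2, 0.2, 0.2), c(1.7, 1.7, 1.7)),
                                 U_ww = c(-8, -8))), tip3p)
  r2 <- gist_analysis(gf2, g, n_boot = 0)
  expect_equal(sort(r2$Eww[r2$Eww != 0]), c(-4, -4))
})

test_that("translational entropy follows the uniform-voxel formula", {
  g <- gist_grid(c(0, 0, 0), 0.5, c(2, 2, 2))
  expect_equal(voxel_translational_entropy(0, g, 100, tip3p$rho0), 0)
  # exactly bulk density: N_k = rho0 * V_k * n_frames
  nf <- 1 / (tip3p$rho0 * 0.125)        # makes N_k = 1 exactly bulk
  expect_equal(voxel_translational_entropy(1, g, nf, tip3p$rho0), 0,
               tolerance = 1e-12)
  # rho_k = 2 rho0: cross-check against the discretised integral
  # -kB T rho0 int_voxel g ln g dV with constant g = 2
  N_k <- 16; n_frames <- N_k / (2 * tip3p$rho0 * 0.125)
  got <- voxel_translational_entropy(N_k, g, n_frames, tip3p$rho0, T = 300)
  oracle <- -kB_test * 300 * tip3p$rho0 * 0.125 * 2 * log(2)
  expect_equal(got / n_frames * n_frames, got)   # vectorised scalar
  expect_equal(got, oracle * 1, tolerance = 1e-12)
  # localisation (rho_k > rho0) is unfavourable: -T dS > 0
  expect_lt(voxel_translational_entropy(N_k, g, n_frames, tip3p$rho0, 300), 0)
})

test_that("the NN orientational estimator has the right limits", {
  set.seed(4)
  # uniform orientations: per-molecule -T dS within 0.5 kJ/mol of 0 at n=500
  Q <- random_quaternions(500)
  est <- orientational_entropy_nn(Q)
  expect_lt(abs(kB_test * 300 * est$dS_per_molecule), 0.5)
  # concentration makes the entropy strictly unfavourable and monotone
  ds <- vapply(c(0.6, 0.3, 0.15), function(s)
    orientational_entropy_nn(concentrated_quaternions(800, sd_angle = s))$dS_per_molecule,
    numeric(1))
  expect_true(all(ds < 0))
  expect_true(all(diff(ds) < 0))
  # n = 1: zero with the insufficient-observations flag
  e1 <- orientational_entropy_nn(matrix(c(1, 0, 0, 0), 1))
  expect_true(e1$insufficient)
  expect_equal(e1$dS_per_molecule, 0)
  # duplicated orientations are floored and counted, not NaN
  Qd <- rbind(Q[1:5, ], Q[1, ])
  ed <- orientational_entropy_nn(Qd)
  expect_gte(ed$degenerate, 2)
  expect_true(is.finite(ed$H))
})

test_that("voxel free energies assemble and are grid-translation invariant", {
  g <- gist_grid(c(0, 0, 0), 0.5, c(6, 6, 6))
  pk <- data.frame(x = 1.3, y = 1.3, z = 1.3, sd = 0.15,
                   waters_per_frame = 0.8, sd_angle = 0.3)
  gf <- make_gist_frames(synthetic_gist_spec(bulk_scale = 0, peaks = pk),
                         g, n_frames = 150, seed = 5)
  r <- gist_analysis(gf, g, n_boot = 10)
  expect_equal(r$dG, r$Esw + r$Eww - r$TdStrans - r$TdSorient)
  expect_true(all(r$dG[r$N_k == 0] == 0))
  expect_named(r$roi_se, c("Esw", "Eww", "TdStrans", "TdSorient", "dG"))
  # the planted ordered peak is entropically unfavourable at its voxel
  k <- voxel_index(g, matrix(c(1.3, 1.3, 1.3), 1))
  expect_gt(-r$TdSorient[k], 0)
  expect_gt(-r$TdStrans[k], 0)
  # shifting the grid by one whole voxel keeps the ROI totals (same waters)
  g2 <- gist_grid(c(-0.5, -0.5, -0.5), 0.5, c(8, 8, 8))
  r2 <- gist_analysis(gf, g2, n_boot = 0)
  expect_equal(r2$roi_totals$Esw, r$roi_totals$Esw, tolerance = 1e-6)
  expect_equal(r2$roi_totals$dG, r$roi_totals$dG, tolerance = 1e-6)
})

test_that("density maps normalise to rho0 and round-trip through DX", {
  g <- gist_grid(c(1, 2, 3), 0.5, c(3, 4, 5))
  # a single stationary water: one-voxel peak of 1/(V_k rho0)
  gf <- gist_frames(lapply(1:25, function(i) frame1(c(1.2, 2.2, 3.2))),
                    tip3p)
  r <- gist_analysis(gf, g, n_boot = 0)
  m <- density_map(r)
  k <- voxel_index(g, matrix(c(1.2, 2.2, 3.2), 1))
  expect_equal(m$values[k], 1 / (0.125 * tip3p$rho0), tolerance = 1e-9)
  expect_equal(sum(m$values > 0), 1)
  # DX write/read identity
  path <- tempfile(fileext = ".dx")
  set.seed(2)
  vals <- runif(prod(g$dims))
  write_dx(vals, g, path)
  back <- read_dx(path)
  expect_equal(back$values, vals, tolerance = 1e-6)
  expect_equal(back$grid$dims, g$dims)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-9)
  expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-9)
})

test_that("uniform bulk water at rho0 gives near-zero entropy totals", {
  g <- gist_grid(c(0, 0, 0), 0.5, c(4, 4, 4))
  gf <- make_gist_frames(synthetic_gist_spec(bulk_scale = 1), g,
                         n_frames = 200, seed = 9)
  r <- gist_analysis(gf, g, n_boot = 0)
  expect_lt(abs(r$roi_totals$TdStrans), 0.8)
  expect_lt(abs(r$roi_totals$TdSorient), 0.8)
  # occupancy histogram consistent with Poisson(rho0 V_k n_frames)
  lam <- tip3p$rho0 * 0.125 * 200
  cnt <- r$N_k
  brk <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  obs <- table(cut(cnt, brk))
  p <- c(dpois(0, lam), dpois(1, lam), dpois(2, lam),
         1 - ppois(2, lam))
  chi <- suppressWarnings(stats::chisq.test(as.vector(obs), p = p))
  expect_gt(chi$p.value, 0.01)
})
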