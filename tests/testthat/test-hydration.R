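# Hydration-comparison statistics: equilibration fits, clustering,
# Tanimoto, crystal recovery, rank tests and site pairing.

test_that("equilibration fits recover noiseless parameters and t_eq", {
  tr <- make_occupancy_trace(2, 6, 0.5, noise_sd = 0, n_points = 200,
                             n_repeats = 1, seed = 1)
  f <- fit_equilibration(tr)
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_equal(f$b, 6, tolerance = 1e-6)
  expect_equal(f$k_rate, 0.5, tolerance = 1e-6)
  # threshold identity: t_eq = (1/k) ln(b / (0.05 (a + b))) = 2 ln 15
  expect_equal(f$t_eq, 2 * log(15), tolerance = 1e-6)
  expect_equal(f$t_eq, 5.41610040, tolerance = 1e-6)
  # constant trace: b ~ 0, t_eq = 0, N_eq = a
  tc <- occupancy_trace(seq(0, 10, length.out = 50), rep(3, 50))
  fc <- fit_equilibration(tc)
  expect_lt(fc$b, 1e-6)
  expect_equal(fc$t_eq, 0)
  expect_equal(fc$N_eq, 3, tolerance = 1e-9)
  expect_error(fit_equilibration(occupancy_trace(1:5, rep(1, 5))), "10")
})

test_that("wet starts fit as instantaneously equilibrated, dry starts do not", {
  dry <- fit_equilibration(make_occupancy_trace(0.2, 7.8, 0.4,
                                                noise_sd = 0.3, seed = 2))
  wet <- fit_equilibration(make_occupancy_trace(8, 0, 0.4,
                                                noise_sd = 0.3, seed = 3))
  expect_gt(dry$t_eq, 1)
  expect_equal(wet$t_eq, 0)
  expect_lt(abs(wet$N_eq - 8), 0.3)
})

test_that("clustering obeys the same-frame exclusion and occupancy filter", {
  # one stationary water
  fr <- replicate(100, matrix(c(4, 5, 6), 1, 3), simplify = FALSE)
  cs <- cluster_waters(fr)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$occupancy, 1)
  expect_equal(unlist(cs$clusters[1, c("x", "y", "z")], use.names = FALSE),
               c(4, 5, 6))
  # two waters 1.0 A apart in the SAME frame stay separate clusters
  fr2 <- list(rbind(c(0, 0, 0), c(1, 0, 0)))
  cs2 <- cluster_waters(list(rbind(c(0, 0, 0), c(1, 0, 0))),
                        occupancy_min = 0)
  expect_equal(nrow(cs2$clusters), 2)
  # across frames the same two points merge
  cs3 <- cluster_waters(list(matrix(c(0, 0, 0), 1, 3),
                             matrix(c(1, 0, 0), 1, 3)), occupancy_min = 0)
  expect_equal(nrow(cs3$clusters), 1)
  expect_equal(cs3$clusters$occupancy, 1)       # both frames contribute
  # occupancy filter drops rare sites unless disabled
  fr4 <- c(replicate(9, matrix(c(0, 0, 0), 1, 3), simplify = FALSE),
           list(rbind(c(0, 0, 0), c(9, 9, 9))))
  expect_equal(nrow(cluster_waters(fr4, occupancy_min = 0.3)$clusters), 1)
  expect_equal(nrow(cluster_waters(fr4, occupancy_min = 0)$clusters), 2)
  # no waters at all: empty set, not an error
  expect_equal(nrow(cluster_waters(list(matrix(numeric(0), 0, 3)))$clusters), 0)
})

test_that("clustering agrees with a brute-force average-linkage oracle", {
  set.seed(31)
  for (case in 1:8) {
    n_frames <- sample(2:3, 1)
    frames <- lapply(seq_len(n_frames), function(f) {
      n <- sample(1:2, 1)
      matrix(runif(3 * n, 0, 6), n, 3)
    })
    X <- do.call(rbind, frames)
    if (nrow(X) < 2) next
    frame_id <- rep(seq_along(frames), vapply(frames, nrow, integer(1)))
    got <- cluster_waters(frames, cutoff = 2.4, occupancy_min = 0)
    oracle_memb <- brute_average_linkage(X, frame_id, 2.4)
    expect_equal(nrow(got$clusters), max(oracle_memb))
    # compare centroid multisets
    oc <- t(vapply(split(seq_len(nrow(X)), oracle_memb), function(idx)
      colMeans(X[idx, , drop = FALSE]), numeric(3)))
    gc <- as.matrix(got$clusters[, c("x", "y", "z")])
    expect_equal(gc[order(gc[, 1], gc[, 2]), , drop = FALSE],
                 oc[order(oc[, 1], oc[, 2]), , drop = FALSE],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("Tanimoto similarity has its identities and arithmetic", {
  set.seed(5)
  A <- matrix(runif(9, 0, 10), 3, 3)
  expect_equal(tanimoto_similarity(A, A), 1)
  B <- A + 100
  expect_equal(tanimoto_similarity(A, B), 0)
  # a = 3, b = 4, c = 2 -> 2 / (3 + 4 - 2) = 0.4
  A3 <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  B4 <- rbind(c(0.5, 0, 0), c(5.5, 0, 0), c(20, 0, 0), c(30, 0, 0))
  expect_equal(tanimoto_similarity(A3, B4, match_dist = 1.4), 0.4)
  # symmetry
  expect_equal(tanimoto_similarity(B4, A3), tanimoto_similarity(A3, B4))
  # empties
  E <- matrix(numeric(0), 0, 3)
  expect_equal(as.numeric(tanimoto_similarity(E, E)), 1)
  expect_true(attr(tanimoto_similarity(E, E), "both_empty"))
  expect_equal(tanimoto_similarity(A, E), 0)
})

test_that("crystal recovery steps exactly at the planted displacements", {
  crystal <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  centroids <- rbind(c(0.3, 0, 0), c(10, 0.9, 0), c(20, 0, 1.7))
  # thresholds straddle the planted displacement radii 0.3 / 0.9 / 1.7
  r <- crystal_recovery(centroids, crystal,
                        thresholds = c(0, 0.25, 0.35, 0.85, 0.95, 1.65,
                                       1.75, 2))
  expect_equal(r$fraction, c(0, 0, 1, 1, 2, 2, 3, 3) / 3, tolerance = 1e-12)
  expect_true(all(diff(r$fraction) >= 0))
  # coincident sites recover at threshold 0; far sites never
  r0 <- crystal_recovery(crystal, crystal)
  expect_true(all(r0$fraction == 1))
  r_far <- crystal_recovery(centroids + 50, crystal)
  expect_true(all(r_far$fraction == 0))
  expect_error(crystal_recovery(centroids, matrix(numeric(0), 0, 3)),
               "crystal")
})

test_that("rank-test comparisons match a hand-computed fixture", {
  # ranks 1..10 split 1-5 / 6-10 without ties: H = 12/110 (45+320) - 33
  x <- c(1, 2, 3, 4, 5); y <- c(6, 7, 8, 9, 10)
  set.seed(6)
  r <- compare_N_distributions(list(a = x, b = y))
  expect_equal(r$H["a", "b"], 6.8181818182, tolerance = 1e-9)
  expect_true(r$p["a", "b"] < 0.05)         # permutation p for small n
  expect_equal(r$p["a", "a"], 1)
  expect_equal(unname(diag(r$H)), c(0, 0))
  expect_true(isSymmetric(r$p))
  # degenerate: identical constant series
  rd <- compare_N_distributions(list(u = rep(2, 8), v = rep(2, 8)))
  expect_equal(rd$p["u", "v"], 1)
  # subsampling thins each series
  expect_error(compare_N_distributions(list(a = x, b = y),
                                       subsample_every = 2), "5 values")
})

test_that("shifted occupancy distributions are detected with high power", {
  set.seed(77)
  hits <- 0
  for (rep in 1:60) {
    x <- rpois(100, 6)
    y <- rpois(100, 8)            # shift of 2 waters
    r <- compare_N_distributions(list(a = x, b = y))
    if (r$p["a", "b"] < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.95)
  expect_equal(p_stars_vec <- waternet:::p_stars(c(5e-4, 5e-3, 0.03, 0.07, 0.5)),
               c("***", "**", "*", ".", ""))
})

test_that("site pairing scores identical, perturbed and unpairable inputs", {
  set.seed(12)
  A <- data.frame(x = runif(6, 0, 20), y = runif(6, 0, 20),
                  z = runif(6, 0, 20), value = rnorm(6, -15, 5))
  expect_equal(pair_and_score_sites(A, A)[c("R", "MAD", "Max", "MRD")],
               list(R = 1, MAD = 0, Max = 0, MRD = 0))
  # two-site arithmetic fixture
  a2 <- data.frame(x = c(0, 10), y = 0, z = 0, value = c(-10, -20))
  b2 <- data.frame(x = c(0.2, 10.2), y = 0, z = 0, value = c(-12, -18))
  s <- pair_and_score_sites(a2, b2)
  expect_equal(s$MAD, 2)
  expect_equal(s$Max, 2)
  expect_equal(s$MRD, (2 / 12 + 2 / 20) / 2, tolerance = 1e-12)
  expect_equal(s$n_paired, 2)
  # beyond the pairing distance: informative error
  expect_error(pair_and_score_sites(a2, transform(b2, x = x + 5)),
               "nearest")
})
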