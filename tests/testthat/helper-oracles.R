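# Independent oracles used by the tests.  Each reimplements the quantity it
# checks by a different route than the package (brute force, closed form or
# direct summation) so that agreement is evidence, not tautology.

kB_test <- 0.0083144626
coulomb_test <- 138.935458

# Brute-force total energy: loop over every site pair of every water/host,
# minimum image, plain cutoff, LJ (Lorentz-Berthelot) + Coulomb.
brute_total_energy <- function(config) {
  sites <- list()
  host <- config$host
  for (i in seq_len(nrow(host))) {
    sites[[length(sites) + 1]] <- list(
      xyz = c(host$x[i], host$y[i], host$z[i]), q = host$charge[i],
      sig = host$sigma[i], eps = host$epsilon[i], mol = 0L)
  }
  for (w in seq_len(n_waters(config))) {
    ws <- water_sites(config, w)
    for (s in seq_len(nrow(ws$xyz))) {
      sites[[length(sites) + 1]] <- list(
        xyz = ws$xyz[s, ], q = ws$charge[s], sig = ws$sigma[s],
        eps = ws$epsilon[s], mol = w)
    }
  }
  u <- 0
  L <- config$box$lengths
  for (i in seq_along(sites)) {
    for (j in seq_along(sites)) {
      if (j <= i) next
      a <- sites[[i]]; b <- sites[[j]]
      if (a$mol == b$mol && a$mol != 0L) next          # same molecule
      if (a$mol == 0L && b$mol == 0L) next             # host-host excluded
      d <- a$xyz - b$xyz
      if (config$box$periodic) d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r > config$box$cutoff) next
      if (a$q != 0 && b$q != 0) u <- u + coulomb_test * a$q * b$q / r
      if (a$eps > 0 && b$eps > 0) {
        sg <- (a$sig + b$sig) / 2
        e <- sqrt(a$eps * b$eps)
        u <- u + 4 * e * ((sg / r)^12 - (sg / r)^6)
      }
    }
  }
  u
}

# Naive O(n^3) average-linkage agglomeration with same-frame exclusion:
# repeatedly merge the pair of clusters with the smallest average
# point-to-point modified distance while that distance is <= cutoff.
brute_average_linkage <- function(X, frame_id, cutoff) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  same <- outer(frame_id, frame_id, "==")
  diag(same) <- FALSE
  D[same] <- 1e6
  groups <- as.list(seq_len(n))
  repeat {
    if (length(groups) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        d <- mean(D[groups[[i]], groups[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > cutoff) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  memb
}

# canonical form of a partition: sorted list of sorted member sets
partition_signature <- function(memb) {
  parts <- split(seq_along(memb), memb)
  parts <- lapply(parts, sort)
  paste(sort(vapply(parts, paste, character(1), collapse = ",")),
        collapse = "|")
}

# Histogram entropy oracle for orientations sampled with a uniform rotation
# axis: reduces to a 1D histogram over the rotation angle psi relative to
# the mode, weighted against the Haar marginal (1 - cos psi)/pi.
hist_orientational_entropy <- function(Q, mode = c(1, 0, 0, 0), n_bins = 60) {
  psi <- 2 * acos(pmin(1, abs(Q %*% mode)))
  br <- seq(0, pi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(psi, br, rightmost.closed = TRUE), n_bins)
  pb <- counts / length(psi)
  haar <- diff(br - sin(br)) / pi
  nz <- pb > 0
  -sum(pb[nz] * log(pb[nz] / haar[nz]))
}

# ideal-gas grand-canonical closed form: N ~ Poisson(e^B)
ideal_mean_N <- function(B) exp(B)

# block mean / block SE for autocorrelated series
block_se <- function(x, n_blocks = 20) {
  bm <- tapply(x, cut(seq_along(x), n_blocks, labels = FALSE), mean)
  stats::sd(bm) / sqrt(n_blocks)
}

# small random water configuration for energetics tests
random_test_config <- function(n_water = 3, seed = 1, model = NULL,
                               with_host = TRUE) {
  set.seed(seed)
  if (is.null(model)) model <- load_water_model("tip3p")
  box <- simulation_box(c(25, 25, 25), cutoff = 9)
  roi <- roi_sphere(c(12.5, 12.5, 12.5), 4)
  host <- if (with_host) {
    interaction_sites(matrix(c(10.5, 12.5, 12.5,
                               14.5, 12.5, 12.5), 2, 3, byrow = TRUE),
                      charge = c(0.2, -0.2), sigma = 3.0, epsilon = 0.4)
  } else {
    interaction_sites(matrix(numeric(0), 0, 3))
  }
  pos <- roi_sample(roi, n_water)
  q <- random_quaternions(n_water)
  water_configuration(box, host, model, pos, q, roi)
}
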