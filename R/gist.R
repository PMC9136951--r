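# Grid-based inhomogeneous solvation theory (GIST).
#
# Trajectory frames of water positions/orientations are binned onto a
# regular grid of cubic voxels (0.5 A spacing by default).  Per voxel k:
#   E_sw(k)      = (1/N_frame) sum_{obs in k} U_sw(i)
#   E_ww(k)      = (1/N_frame) sum_{obs in k} U_ww(i)/2
#   dS_trans(k)  = -kB (N_k/N_frame) ln(rho_k/rho0),  rho_k = N_k/(V_k N_frame)
#   dS_orient(k) = kB (N_k/N_frame) (H_k - ln pi^2)
#   dG(k)        = E_sw + E_ww - T (dS_trans + dS_orient)
# with H_k the first-nearest-neighbour entropy estimate of the pooled
# orientational distribution in voxel k (quaternion metric, total
# orientation-space volume pi^2 on the double cover).  All quantities are
# per-frame averages, so ROI sums are directly comparable between runs.

#' Define a GIST grid
#'
#' Voxels are cubes of side `spacing`; voxel `(i, j, k)` (0-based) covers the
#' half-open box `[origin + i h, origin + (i+1) h)` in each dimension, so an
#' observation exactly on a boundary belongs to the higher-index voxel.
#'
#' @param origin 3-vector: corner of voxel (0,0,0), Angstrom.
#' @param spacing voxel edge length, Angstrom (default 0.5).
#' @param dims 3 integer voxel counts.
#' @param roi_mask optional logical vector (length `prod(dims)`, x-fastest
#'   linear order) marking the voxels that belong to the region of interest;
#'   default all.
#' @return object of class `gist_grid`.
#' @export
gist_grid <- function(origin, spacing = 0.5, dims, roi_mask = NULL) {
  origin <- as.numeric(origin); dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(dims) == 3, spacing > 0,
            all(dims >= 1))
  nvox <- prod(dims)
  if (is.null(roi_mask)) roi_mask <- rep(TRUE, nvox)
  stopifnot(length(roi_mask) == nvox)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 voxel_volume = spacing^3, roi_mask = roi_mask),
            class = "gist_grid")
}

#' Linear voxel index of points (x-fastest order)
#'
#' @param grid a [gist_grid()].
#' @param X `n x 3` matrix of positions.
#' @return integer vector of 1-based linear voxel indices; `NA` for points
#'   outside the grid.
#' @export
voxel_index <- function(grid, X) {
  X <- matrix(X, ncol = 3)
  i <- floor((X[, 1] - grid$origin[1]) / grid$spacing)
  j <- floor((X[, 2] - grid$origin[2]) / grid$spacing)
  k <- floor((X[, 3] - grid$origin[3]) / grid$spacing)
  ok <- i >= 0 & i < grid$dims[1] & j >= 0 & j < grid$dims[2] &
    k >= 0 & k < grid$dims[3]
  out <- rep(NA_integer_, nrow(X))
  out[ok] <- 1L + i[ok] + grid$dims[1] * (j[ok] + grid$dims[2] * k[ok])
  out
}

#' Voxel centre coordinates
#' @param grid a [gist_grid()].
#' @param index 1-based linear indices (default all).
#' @return `n x 3` matrix.
#' @export
voxel_centers <- function(grid, index = seq_len(prod(grid$dims))) {
  idx0 <- index - 1L
  i <- idx0 %% grid$dims[1]
  j <- (idx0 %/% grid$dims[1]) %% grid$dims[2]
  k <- idx0 %/% (grid$dims[1] * grid$dims[2])
  cbind(grid$origin[1] + (i + 0.5) * grid$spacing,
        grid$origin[2] + (j + 0.5) * grid$spacing,
        grid$origin[3] + (k + 0.5) * grid$spacing)
}

#' Bundle trajectory frames for GIST analysis
#'
#' @param frames list of frames, each a list with `positions` (n x 3 water
#'   oxygen positions), `orientations` (n x 4 unit quaternions), `U_sw` and
#'   `U_ww` (per-water interaction energies, kJ/mol; `U_ww` counts each
#'   water-water pair from both sides, exactly as
#'   [water_interaction_energy()] returns it).
#' @param model a [water_model()] (supplies the bulk density `rho0`).
#' @param T temperature, Kelvin.
#' @return object of class `gist_frames`.
#' @export
gist_frames <- function(frames, model, T = 300) {
  stopifnot(length(frames) >= 1, inherits(model, "water_model"))
  for (f in frames) {
    n <- nrow(f$positions)
    stopifnot(!is.null(f$positions), !is.null(f$orientations),
              nrow(f$orientations) == n,
              length(f$U_sw) == n, length(f$U_ww) == n)
    if (n > 0 && any(abs(sqrt(rowSums(f$orientations^2)) - 1) > 1e-9)) {
      stop("orientation quaternions must be unit norm within 1e-9")
    }
  }
  structure(list(frames = frames, n_frames = length(frames),
                 model = model, T = T),
            class = "gist_frames")
}

#' Compute GIST frames from a GCMC trace
#'
#' Recomputes per-water solute-water and water-water energies for every
#' recorded frame of a [run_gcmc()] trace using the energetics of the
#' configuration the trace was run on.
#'
#' @param trace a `gc_trace` with recorded frames.
#' @param config the [water_configuration()] the sampler was started from
#'   (supplies host sites, box and water model).
#' @return a [gist_frames()] object.
#' @export
gist_frames_from_trace <- function(trace, config) {
  if (!length(trace$frames)) stop("trace has no recorded frames")
  frames <- lapply(trace$frames, function(fr) {
    cfg <- water_configuration(config$box, config$host, config$model,
                               fr$positions, fr$orientations, config$roi)
    n <- n_waters(cfg)
    U <- matrix(0, n, 2)
    for (i in seq_len(n)) U[i, ] <- water_interaction_energy(cfg, i)
    list(positions = fr$positions, orientations = fr$orientations,
         U_sw = U[, 1], U_ww = U[, 2])
  })
  gist_frames(frames, config$model, trace$params$T)
}

#' Assign water observations to voxels
#'
#' @param frames a [gist_frames()].
#' @param grid a [gist_grid()].
#' @return data frame with one row per in-grid observation
#'   (`frame, water, voxel, U_sw, U_ww`) plus attribute `n_dropped`, the
#'   count of observations outside the grid.
#' @export
bin_waters <- function(frames, grid) {
  rows <- lapply(seq_along(frames$frames), function(fi) {
    f <- frames$frames[[fi]]
    n <- nrow(f$positions)
    if (n == 0) return(NULL)
    v <- voxel_index(grid, f$positions)
    data.frame(frame = fi, water = seq_len(n), voxel = v,
               U_sw = f$U_sw, U_ww = f$U_ww)
  })
  obs <- do.call(rbind, rows)
  if (is.null(obs)) {
    obs <- data.frame(frame = integer(0), water = integer(0),
                      voxel = integer(0), U_sw = numeric(0),
                      U_ww = numeric(0))
  }
  dropped <- sum(is.na(obs$voxel))
  obs <- obs[!is.na(obs$voxel), , drop = FALSE]
  attr(obs, "n_dropped") <- dropped
  obs
}

# volume of a geodesic ball of rotation-angle radius d in orientation space
# (total volume pi^2 on the quaternion double cover); series for small d.
orientation_ball_volume <- function(d) {
  ifelse(d < 1e-2, pi * d^3 / 6 * (1 - d^2 / 20), pi * (d - sin(d)))
}

# nearest-neighbour rotation angles within a pooled set of quaternions,
# computed blockwise via cross products (handles 1e4+ observations).
nn_orientation_distance <- function(Q, block = 512L) {
  n <- nrow(Q)
  stopifnot(n >= 2)
  d <- numeric(n)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dot <- abs(tcrossprod(Q[idx, , drop = FALSE], Q))  # |q_i . q_j|
    dot[cbind(seq_along(idx), idx)] <- -Inf            # exclude self
    d[idx] <- 2 * acos(pmin(1, apply(dot, 1, max)))
  }
  d
}

#' Nearest-neighbour orientational entropy of a set of orientations
#'
#' First-nearest-neighbour (Kozachenko-Leonenko) estimate of the entropy of
#' an orientational distribution, relative to the uniform distribution:
#' `H = mean(ln((n-1) V(d_i))) + gamma` with `V(d) = pi (d - sin d)` the
#' geodesic-ball volume at the NN rotation angle `d_i`, and gamma the
#' Euler-Mascheroni constant.  The return value is `(H - ln pi^2)`, i.e. the
#' per-molecule excess entropy in units of kB (0 for uniform orientations,
#' negative for ordered ones).
#'
#' @param Q `n x 4` matrix of unit quaternions (n >= 2; with n < 2 the value
#'   is 0 with the `insufficient` flag set).
#' @param d_floor duplicate orientations (`d = 0`) are floored at this
#'   rotation angle (radians) and counted in the `degenerate` attribute.
#' @return list with `dS_per_molecule` (units of kB), `H` (nats), `n`,
#'   `degenerate` (count of floored NN distances), `insufficient` flag.
#' @export
orientational_entropy_nn <- function(Q, d_floor = 1e-6) {
  n <- if (is.null(nrow(Q))) 0L else nrow(Q)
  if (n < 2) {
    return(list(dS_per_molecule = 0, H = NA_real_, n = n, degenerate = 0L,
                insufficient = TRUE))
  }
  d <- nn_orientation_distance(Q)
  degen <- sum(d < d_floor)
  d <- pmax(d, d_floor)
  gamma <- -digamma(1)
  H <- mean(log((n - 1) * orientation_ball_volume(d))) + gamma
  list(dS_per_molecule = H - log(pi^2), H = H, n = n, degenerate = degen,
       insufficient = FALSE)
}

#' Translational solvation entropy per voxel
#'
#' `T dS_trans(k) = -kB T (N_k/N_frame) ln(rho_k/rho0)` with
#' `rho_k = N_k/(V_k N_frame)`; identically 0 for empty voxels (the
#' `x ln x -> 0` convention) and at bulk density.
#'
#' @param N_k vector of total observation counts per voxel.
#' @param grid a [gist_grid()].
#' @param n_frames number of frames.
#' @param rho0 bulk number density, A^-3.
#' @param T temperature, Kelvin.
#' @return vector of `T dS_trans` per voxel, kJ/mol.
#' @export
voxel_translational_entropy <- function(N_k, grid, n_frames, rho0, T = 300) {
  stopifnot(rho0 > 0, n_frames >= 1)
  rho <- N_k / (grid$voxel_volume * n_frames)
  out <- numeric(length(N_k))
  nz <- N_k > 0
  out[nz] <- -wn_constants$kB * T * (N_k[nz] / n_frames) * log(rho[nz] / rho0)
  out
}

#' Full GIST analysis of a frame set
#'
#' @param frames a [gist_frames()].
#' @param grid a [gist_grid()].
#' @param n_blocks frame blocks for the bootstrap standard errors of the ROI
#'   totals.
#' @param n_boot bootstrap replicates (0 disables the bootstrap).
#' @return object of class `gist_result` with per-voxel vectors `N_k`,
#'   `rho`, `Esw`, `Eww`, `TdStrans`, `TdSorient`, `dG`, the ROI totals,
#'   bootstrap SEs, and bookkeeping counters.
#' @export
gist_analysis <- function(frames, grid, n_blocks = 10, n_boot = 20) {
  obs <- bin_waters(frames, grid)
  res <- gist_fields(frames, grid, obs)
  se <- NULL
  if (n_boot > 0 && frames$n_frames >= n_blocks) {
    blocks <- split(seq_len(frames$n_frames),
                    cut(seq_len(frames$n_frames), n_blocks, labels = FALSE))
    tot <- matrix(NA_real_, n_boot, 5,
                  dimnames = list(NULL, c("Esw", "Eww", "TdStrans",
                                          "TdSorient", "dG")))
    for (b in seq_len(n_boot)) {
      pick <- unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)])
      sub <- gist_frames(frames$frames[pick], frames$model, frames$T)
      r <- gist_fields(sub, grid, bin_waters(sub, grid))
      tot[b, ] <- unlist(r$roi_totals[colnames(tot)])
    }
    se <- apply(tot, 2, stats::sd)
  }
  res$roi_se <- se
  res
}

# core per-voxel field computation shared with the bootstrap
gist_fields <- function(frames, grid, obs) {
  nvox <- prod(grid$dims)
  nf <- frames$n_frames
  T <- frames$T
  N_k <- numeric(nvox)
  Esw <- numeric(nvox)
  Eww <- numeric(nvox)
  if (nrow(obs)) {
    tab <- tapply(rep(1, nrow(obs)), obs$voxel, sum)
    N_k[as.integer(names(tab))] <- tab
    e1 <- tapply(obs$U_sw, obs$voxel, sum)
    Esw[as.integer(names(e1))] <- e1 / nf
    e2 <- tapply(obs$U_ww, obs$voxel, sum)
    Eww[as.integer(names(e2))] <- 0.5 * e2 / nf
  }
  rho <- N_k / (grid$voxel_volume * nf)
  TdStrans <- voxel_translational_entropy(N_k, grid, nf, frames$model$rho0, T)
  TdSorient <- numeric(nvox)
  degenerate <- 0L
  insufficient <- 0L
  occupied <- which(N_k > 0)
  if (length(occupied)) {
    # pool orientations per voxel
    qmats <- vector("list", nf)
    vlist <- vector("list", nf)
    for (fi in seq_len(nf)) {
      f <- frames$frames[[fi]]
      if (!nrow(f$positions)) next
      v <- voxel_index(grid, f$positions)
      ok <- !is.na(v)
      qmats[[fi]] <- f$orientations[ok, , drop = FALSE]
      vlist[[fi]] <- v[ok]
    }
    allQ <- do.call(rbind, qmats)
    allv <- unlist(vlist)
    by_vox <- split(seq_along(allv), allv)
    for (kc in names(by_vox)) {
      k <- as.integer(kc)
      Q <- allQ[by_vox[[kc]], , drop = FALSE]
      est <- orientational_entropy_nn(Q)
      if (est$insufficient) {
        insufficient <- insufficient + 1L
      } else {
        degenerate <- degenerate + est$degenerate
        TdSorient[k] <- wn_constants$kB * T * (N_k[k] / nf) *
          est$dS_per_molecule
      }
    }
  }
  dG <- Esw + Eww - TdStrans - TdSorient
  mask <- grid$roi_mask
  roi_totals <- list(
    N = sum(N_k[mask]), Esw = sum(Esw[mask]), Eww = sum(Eww[mask]),
    TdStrans = sum(TdStrans[mask]), TdSorient = sum(TdSorient[mask]),
    dG = sum(dG[mask])
  )
  structure(list(grid = grid, n_frames = nf, T = T,
                 rho0 = frames$model$rho0,
                 N_k = N_k, rho = rho, Esw = Esw, Eww = Eww,
                 TdStrans = TdStrans, TdSorient = TdSorient, dG = dG,
                 roi_totals = roi_totals,
                 counters = list(dropped = attr(obs, "n_dropped"),
                                 degenerate_orientations = degenerate,
                                 insufficient_voxels = insufficient)),
            class = "gist_result")
}

#' Normalised density map from a GIST result
#'
#' @param result a `gist_result`.
#' @return object of class `gist_map`: the grid plus the field
#'   `rho_k / rho0` (1 in bulk-like voxels), writable with [write_dx()].
#' @export
density_map <- function(result) {
  structure(list(grid = result$grid, values = result$rho / result$rho0,
                 name = "water density rho/rho0"),
            class = "gist_map")
}

#' @export
print.gist_result <- function(x, ...) {
  cat("GIST result on", paste(x$grid$dims, collapse = " x "),
      "voxels, spacing", x$grid$spacing, "A,", x$n_frames, "frames\n")
  t <- x$roi_totals
  cat(sprintf("  ROI totals (kJ/mol): Esw %.3f  Eww %.3f  -TdStrans %.3f  -TdSorient %.3f  dG %.3f\n",
              t$Esw, t$Eww, -t$TdStrans, -t$TdSorient, t$dG))
  if (!is.null(x$roi_se)) {
    cat("  bootstrap SE (dG):", signif(x$roi_se[["dG"]], 3), "kJ/mol\n")
  }
  invisible(x)
}
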