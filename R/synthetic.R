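# Synthetic toy systems with known ground truth: host cavities with a small
# number of favourable water sites, voxelised density fields with planted
# peaks, and noisy exponential hydration-relaxation traces.  Everything is
# reproducible from an explicit seed; planted parameters are carried on the
# returned objects for recovery tests.

#' Specify a toy host cavity
#'
#' A spherical shell of weak Lennard-Jones wall sites encloses a small
#' cavity containing `n_hotspots` attractive LJ sites (favourable water
#' positions).  An optional "ligand" blocker sterically occludes the first
#' `blocked` hotspots, emulating a bound ligand that displaces part of the
#' water network (the apo/holo toggle).
#'
#' Hotspot well depths default to values that put per-water binding free
#' energies in the few-to-20 kJ/mol range, so titration curves are
#' non-trivial but resolvable at desk scale.
#'
#' @param n_hotspots number of favourable sites (default 4, tetrahedral).
#' @param hotspot_depth LJ well depth (kJ/mol) felt by a water oxygen at a
#'   hotspot (converted internally through Lorentz-Berthelot combining).
#' @param hotspot_radius radial distance of hotspots from the cavity centre,
#'   Angstrom.
#' @param shell_radius,n_shell cavity wall geometry.
#' @param blocked number of hotspots occluded by the blocker (0 = apo).
#' @return a list spec for [make_toy_host()].
#' @export
toy_host_spec <- function(n_hotspots = 4, hotspot_depth = 18,
                          hotspot_radius = 2.2, shell_radius = 5.5,
                          n_shell = 32, blocked = 0) {
  stopifnot(n_hotspots >= 0, blocked >= 0, blocked <= n_hotspots,
            hotspot_depth >= 0)
  list(n_hotspots = n_hotspots, hotspot_depth = hotspot_depth,
       hotspot_radius = hotspot_radius, shell_radius = shell_radius,
       n_shell = n_shell, blocked = blocked)
}

# roughly even points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a toy host-cavity configuration
#'
#' @param spec a [toy_host_spec()].
#' @param model a [water_model()] (default TIP3P-like).
#' @param box a [simulation_box()] (default 30 A periodic cube, 10 A
#'   cutoff); the cavity is centred in the box.
#' @param roi region of GC sampling (default: sphere of radius 3 A at the
#'   cavity centre).
#' @return a [water_configuration()] with no waters; hotspot positions are
#'   attached as attribute `hotspots`.
#' @export
make_toy_host <- function(spec = toy_host_spec(),
                          model = load_water_model("tip3p"),
                          box = simulation_box(c(30, 30, 30), cutoff = 10),
                          roi = NULL) {
  center <- box$lengths / 2
  if (is.null(roi)) roi <- roi_sphere(center, 3)
  sites <- list()
  if (spec$n_shell > 0) {
    shell <- sweep(fibonacci_sphere(spec$n_shell, spec$shell_radius), 2,
                   center, "+")
    sites[[1]] <- interaction_sites(shell, charge = 0, sigma = 2.6,
                                    epsilon = 0.3, kind = "host")
  }
  hotspots <- NULL
  if (spec$n_hotspots > 0) {
    base <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3)
    if (spec$n_hotspots <= 4) {
      dirs <- base[seq_len(spec$n_hotspots), , drop = FALSE]
    } else {
      dirs <- fibonacci_sphere(spec$n_hotspots)
    }
    hotspots <- sweep(dirs * spec$hotspot_radius, 2, center, "+")
    # water oxygen feels well depth = sqrt(eps_site * eps_O)
    eps_o <- max(model$sites$epsilon)
    eps_site <- if (eps_o > 0) spec$hotspot_depth^2 / eps_o else 0
    sites[[length(sites) + 1]] <-
      interaction_sites(hotspots, charge = 0, sigma = 2.0,
                        epsilon = eps_site, kind = "host")
  }
  if (spec$blocked > 0) {
    # the blocker's large core cancels the wells of the hotspots it covers
    blk <- hotspots[seq_len(spec$blocked), , drop = FALSE]
    sites[[length(sites) + 1]] <-
      interaction_sites(blk, charge = 0, sigma = 4.2, epsilon = 0.2,
                        kind = "host")
  }
  host <- if (length(sites)) do.call(rbind, sites) else
    interaction_sites(matrix(numeric(0), 0, 3))
  if (nrow(host) > 1) {
    D <- stats::dist(as.matrix(host[, c("x", "y", "z")]))
    if (min(D) < 1e-3 && spec$blocked == 0) {
      stop("overlapping host sites in toy host construction")
    }
  }
  cfg <- water_configuration(box, host, model, roi = roi)
  attr(cfg, "hotspots") <- hotspots
  attr(cfg, "spec") <- spec
  cfg
}

#' Specify a synthetic GIST density field
#'
#' A bulk water level (`rho0 * bulk_scale`) plus isotropic Gaussian density
#' peaks.  Bulk waters are orientationally disordered (uniform quaternions);
#' peak waters are drawn around a fixed mode orientation with rotation-angle
#' spread `sd_angle` (smaller = more ordered).
#'
#' @param bulk_scale bulk density as a multiple of the model's `rho0`
#'   (0 for no bulk component).
#' @param peaks data frame with columns `x, y, z` (centre, Angstrom), `sd`
#'   (isotropic spread, Angstrom), `waters_per_frame` (expected count) and
#'   `sd_angle` (orientation spread, radians; `Inf` = disordered).
#' @param well_depth depth (kJ/mol) of the analytic Gaussian solute-water
#'   potential assigned to peak waters: `U_sw(r) = -well_depth *
#'   exp(-|r - c|^2 / (2 sd^2))` summed over peaks.  Bulk waters get
#'   `U_sw = 0`; all waters get `U_ww = 0`, so energy-sum identities are
#'   exactly checkable.
#' @return a list spec for [make_gist_frames()].
#' @export
synthetic_gist_spec <- function(bulk_scale = 1, peaks = NULL,
                                well_depth = 20) {
  if (is.null(peaks)) {
    peaks <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        sd = numeric(0), waters_per_frame = numeric(0),
                        sd_angle = numeric(0))
  }
  stopifnot(bulk_scale >= 0, all(peaks$sd > 0),
            all(peaks$waters_per_frame >= 0))
  list(bulk_scale = bulk_scale, peaks = peaks, well_depth = well_depth)
}

#' Generate synthetic GIST frames with planted ground truth
#'
#' Per frame, bulk water counts are Poisson with mean
#' `rho0 * bulk_scale * V_grid` placed uniformly over the grid volume, and
#' each peak contributes a Poisson number of waters at Gaussian positions
#' around its centre.  Orientations are uniform for bulk waters and
#' concentrated (rotation-angle spread `sd_angle`) for peak waters.
#'
#' @param spec a [synthetic_gist_spec()].
#' @param grid a [gist_grid()].
#' @param n_frames number of frames (>= 1).
#' @param model a [water_model()] (for `rho0`).
#' @param T temperature, Kelvin.
#' @param seed RNG seed.
#' @return a [gist_frames()] object.
#' @export
make_gist_frames <- function(spec, grid, n_frames, model = load_water_model("tip3p"),
                             T = 300, seed = 1) {
  if (n_frames < 1) stop("n_frames must be at least 1")
  set.seed(seed)
  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$spacing
  V <- prod(hi - lo)
  lam_bulk <- model$rho0 * spec$bulk_scale * V
  pk <- spec$peaks
  u_sw_of <- function(X) {
    if (nrow(pk) == 0 || nrow(X) == 0) return(numeric(nrow(X)))
    u <- numeric(nrow(X))
    for (p in seq_len(nrow(pk))) {
      d2 <- rowSums(sweep(X, 2, c(pk$x[p], pk$y[p], pk$z[p]))^2)
      u <- u - spec$well_depth * exp(-d2 / (2 * pk$sd[p]^2))
    }
    u
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    nb <- stats::rpois(1, lam_bulk)
    Xb <- cbind(stats::runif(nb, lo[1], hi[1]), stats::runif(nb, lo[2], hi[2]),
                stats::runif(nb, lo[3], hi[3]))
    Qb <- random_quaternions(nb)
    Xp <- matrix(numeric(0), 0, 3); Qp <- matrix(numeric(0), 0, 4)
    for (p in seq_len(nrow(pk))) {
      np <- stats::rpois(1, pk$waters_per_frame[p])
      if (np == 0) next
      Xi <- cbind(stats::rnorm(np, pk$x[p], pk$sd[p]),
                  stats::rnorm(np, pk$y[p], pk$sd[p]),
                  stats::rnorm(np, pk$z[p], pk$sd[p]))
      Qi <- if (is.finite(pk$sd_angle[p])) {
        concentrated_quaternions(np, sd_angle = pk$sd_angle[p])
      } else {
        random_quaternions(np)
      }
      Xp <- rbind(Xp, Xi); Qp <- rbind(Qp, Qi)
    }
    X <- rbind(Xb, Xp); Q <- rbind(Qb, Qp)
    frames[[f]] <- list(positions = X, orientations = Q,
                        U_sw = u_sw_of(X), U_ww = numeric(nrow(X)))
  }
  out <- gist_frames(frames, model, T)
  attr(out, "spec") <- spec
  out
}

#' Generate a noisy exponential occupancy trace
#'
#' `N(t) = a + b (1 - exp(-k t)) + eps`, with Gaussian noise floored at 0,
#' over `n_repeats` independent repeats averaged into the trace mean.
#'
#' @param a,b,k_rate planted parameters (waters, waters, ns^-1); all >= 0.
#' @param noise_sd Gaussian noise standard deviation, waters.
#' @param n_points time points (default 200 over `t_max`).
#' @param n_repeats independent repeats (default 10).
#' @param t_max trace length, ns (default 20).
#' @param seed RNG seed.
#' @return an [occupancy_trace()]; planted parameters in attribute
#'   `planted`.
#' @export
make_occupancy_trace <- function(a, b, k_rate, noise_sd = 0.5,
                                 n_points = 200, n_repeats = 10, t_max = 20,
                                 seed = 1) {
  stopifnot(a >= 0, b >= 0, k_rate >= 0)
  set.seed(seed)
  t <- seq(0, t_max, length.out = n_points)
  truth <- a + b * (1 - exp(-k_rate * t))
  reps <- matrix(0, n_points, n_repeats)
  for (r in seq_len(n_repeats)) {
    reps[, r] <- pmax(truth + stats::rnorm(n_points, 0, noise_sd), 0)
  }
  tr <- occupancy_trace(t, rowMeans(reps), repeats = reps)
  attr(tr, "planted") <- c(a = a, b = b, k_rate = k_rate)
  tr
}

#' Titrate a configuration over a grid of Adams values
#'
#' Convenience driver: runs one GCMC simulation per Adams value (seeds
#' derived from `seed`) and assembles the titration curve.
#'
#' @param config a [water_configuration()].
#' @param B_values Adams values (>= 4 distinct values).
#' @param params_template an [adams_parameters()] supplying T, mu_ex, V_std.
#' @param n_moves moves per Adams value.
#' @param mix a [move_mix()].
#' @param seed base seed; run `i` uses `seed + i`.
#' @param record_every record cadence.
#' @param discard_fraction burn-in fraction.
#' @return a `titration_curve` with `B_equil` computed from the template
#'   parameters and the configuration's ROI.
#' @export
titrate_gcmc <- function(config, B_values, params_template = adams_parameters(),
                         n_moves = 20000, mix = move_mix(), seed = 1,
                         record_every = 20, discard_fraction = 0.2) {
  traces <- lapply(seq_along(B_values), function(i) {
    p <- params_template
    p$B <- B_values[i]
    run_gcmc(config, p, mix, n_moves = n_moves, record_every = record_every,
             seed = seed + i)
  })
  B_eq <- equilibrium_adams(params_template, config$roi)
  build_titration_curve(traces, discard_fraction = discard_fraction,
                        B_equil = B_eq)
}
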