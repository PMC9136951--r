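# Pairwise Lennard-Jones + Coulomb energetics with plain cutoff truncation.
#
# Conventions (package-wide):
#   * Lorentz-Berthelot combining: sigma_ij = (sigma_i + sigma_j)/2,
#     epsilon_ij = sqrt(epsilon_i * epsilon_j); a site with epsilon = 0 (or
#     sigma = 0) has no LJ term.
#   * Electrostatics: k_e q_i q_j / r with k_e = 138.935458 kJ mol^-1 A e^-2.
#   * Plain truncation: any pair beyond the box cutoff contributes exactly 0.
#     No shifting, switching or long-range correction.
#   * Minimum-image convention in periodic boxes.
#   * Separations below 1e-6 A are a hard-core overlap: the energy is the
#     +Inf sentinel, which samplers treat as an automatic rejection.

# Sum of pair energies between two groups of sites.
# A, B: lists with xyz (m x 3), charge, sigma, epsilon.
group_energy <- function(A, B, box) {
  m <- nrow(A$xyz); n <- nrow(B$xyz)
  if (m == 0 || n == 0) return(0)
  dx <- outer(A$xyz[, 1], B$xyz[, 1], "-")
  dy <- outer(A$xyz[, 2], B$xyz[, 2], "-")
  dz <- outer(A$xyz[, 3], B$xyz[, 3], "-")
  if (box$periodic) {
    L <- box$lengths
    dx <- dx - L[1] * round(dx / L[1])
    dy <- dy - L[2] * round(dy / L[2])
    dz <- dz - L[3] * round(dz / L[3])
  }
  r2 <- dx * dx + dy * dy + dz * dz
  if (any(r2 < wn_constants$hardcore_dist^2)) return(Inf)
  within <- r2 <= box$cutoff^2
  if (!any(within)) return(0)
  r2w <- r2[within]
  u <- 0
  # Coulomb
  qq <- outer(A$charge, B$charge)[within]
  nz <- qq != 0
  if (any(nz)) u <- u + wn_constants$coulomb * sum(qq[nz] / sqrt(r2w[nz]))
  # Lennard-Jones (Lorentz-Berthelot)
  eps <- sqrt(outer(A$epsilon, B$epsilon))[within]
  lj <- eps > 0
  if (any(lj)) {
    sig <- (outer(A$sigma, B$sigma, "+") / 2)[within][lj]
    s6 <- (sig * sig / r2w[lj])^3
    u <- u + sum(4 * eps[lj] * (s6 * s6 - s6))
  }
  u
}

sites_as_group <- function(sites) {
  list(xyz = as.matrix(sites[, c("x", "y", "z")]),
       charge = sites$charge, sigma = sites$sigma, epsilon = sites$epsilon)
}

one_site_group <- function(site) {
  list(xyz = matrix(c(site$x, site$y, site$z), 1, 3),
       charge = site$charge, sigma = site$sigma, epsilon = site$epsilon)
}

#' Pairwise interaction energy between two sites
#'
#' Lennard-Jones (Lorentz-Berthelot combining) plus Coulomb energy at the
#' minimum-image separation, plainly truncated at the box cutoff.
#'
#' @param site_a,site_b one-row data frames (or lists) with fields
#'   `x, y, z, charge, sigma, epsilon`.
#' @param box a [simulation_box()].
#' @return energy in kJ/mol; exactly 0 beyond the cutoff; `+Inf` if the
#'   separation is below the hard-core threshold (1e-6 A).
#' @examples
#' box <- simulation_box(c(50, 50, 50), cutoff = 12)
#' a <- list(x = 0, y = 0, z = 0, charge = 0, sigma = 3.2, epsilon = 0.5)
#' b <- list(x = 3.2, y = 0, z = 0, charge = 0, sigma = 3.2, epsilon = 0.5)
#' pair_energy(a, b, box)  # LJ zero crossing at r = sigma
#' @export
pair_energy <- function(site_a, site_b, box) {
  group_energy(one_site_group(site_a), one_site_group(site_b), box)
}

# All sites of all waters except `exclude`, as one group.
other_water_group <- function(config, exclude = 0) {
  n <- n_waters(config)
  idx <- setdiff(seq_len(n), exclude)
  if (!length(idx)) {
    return(list(xyz = matrix(numeric(0), 0, 3), charge = numeric(0),
                sigma = numeric(0), epsilon = numeric(0)))
  }
  s <- length(config$model$sites$charge)
  xyz <- matrix(0, length(idx) * s, 3)
  for (k in seq_along(idx)) {
    w <- water_sites(config, idx[k])
    xyz[((k - 1) * s + 1):(k * s), ] <- w$xyz
  }
  list(xyz = xyz,
       charge = rep(config$model$sites$charge, length(idx)),
       sigma = rep(config$model$sites$sigma, length(idx)),
       epsilon = rep(config$model$sites$epsilon, length(idx)))
}

# Energy of an arbitrary trial water (sites group) against the rest of the
# system, excluding water index `exclude` from the water-water part.
trial_water_energy <- function(config, wgroup, exclude = 0) {
  u_sw <- group_energy(wgroup, sites_as_group(config$host), config$box)
  u_ww <- group_energy(wgroup, other_water_group(config, exclude), config$box)
  c(U_sw = u_sw, U_ww = u_ww)
}

#' Solute-water and water-water energy of one water
#'
#' @param config a [water_configuration()].
#' @param water_index index of the water (1-based).
#' @return named vector `c(U_sw, U_ww)` in kJ/mol: the summed site-site
#'   energies of that water against all host sites and against all other
#'   waters.  Summing `U_ww` over all waters counts every water-water pair
#'   twice, so the total water-water energy is half that sum.
#' @export
water_interaction_energy <- function(config, water_index) {
  stopifnot(water_index >= 1, water_index <= n_waters(config))
  trial_water_energy(config, water_sites(config, water_index),
                     exclude = water_index)
}

#' Total potential energy of a configuration
#'
#' @param config a [water_configuration()].
#' @return total energy in kJ/mol (host-host interactions are constant for a
#'   fixed host and are excluded).
#' @export
total_energy <- function(config) {
  n <- n_waters(config)
  if (n == 0) return(0)
  u <- 0
  for (i in seq_len(n)) {
    e <- water_interaction_energy(config, i)
    u <- u + e[["U_sw"]] + 0.5 * e[["U_ww"]]
  }
  u
}

#' Propose a GCMC move
#'
#' @param type one of `"insert"`, `"delete"`, `"translate"`, `"rotate"`.
#' @param index water index (delete/translate/rotate).
#' @param position oxygen position of the inserted/moved water.
#' @param orientation unit quaternion of the inserted/rotated water.
#' @return a list of class `gc_move`.
#' @export
gc_move <- function(type, index = NA_integer_, position = NULL,
                    orientation = NULL) {
  stopifnot(type %in% c("insert", "delete", "translate", "rotate"))
  structure(list(type = type, index = index, position = position,
                 orientation = orientation), class = "gc_move")
}

#' Energy change of a proposed move
#'
#' Computed over only the affected water's interactions, so it equals the
#' full-system energy difference without recomputing unaffected pairs.
#'
#' @param config a [water_configuration()].
#' @param move a [gc_move()].
#' @return `Delta U` in kJ/mol; `+Inf` for insertions onto an occupied hard
#'   core (automatic rejection).
#' @export
move_delta_energy <- function(config, move) {
  model <- config$model
  trial_group <- function(pos, q) {
    xyz <- sweep(quat_rotate(q, model$geometry), 2, pos, "+")
    list(xyz = xyz, charge = model$sites$charge,
         sigma = model$sites$sigma, epsilon = model$sites$epsilon)
  }
  switch(move$type,
    insert = {
      e <- trial_water_energy(config, trial_group(move$position, move$orientation))
      e[["U_sw"]] + e[["U_ww"]]
    },
    delete = {
      e <- water_interaction_energy(config, move$index)
      -(e[["U_sw"]] + e[["U_ww"]])
    },
    translate = ,
    rotate = {
      old <- water_interaction_energy(config, move$index)
      pos <- if (is.null(move$position)) config$positions[move$index, ] else move$position
      q <- if (is.null(move$orientation)) config$orientations[move$index, ] else move$orientation
      e <- trial_water_energy(config, trial_group(pos, q), exclude = move$index)
      new <- e[["U_sw"]] + e[["U_ww"]]
      if (is.infinite(new)) Inf else new - (old[["U_sw"]] + old[["U_ww"]])
    }
  )
}
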