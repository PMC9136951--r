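# Grand-canonical Monte Carlo over a region of interest.
#
# The Adams parameter B is the working proxy for chemical potential: the
# insertion and deletion acceptance probabilities are
#   P_ins = min[1, exp(B - beta dU) / (N + 1)]
#   P_del = min[1, N exp(-B - beta dU)]
# where N is the number of waters before the move and dU the energy change.
# At equilibrium with bulk water, B_equil = beta mu_ex + ln(V_ROI / V_std).

#' Thermodynamic parameters for grand-canonical sampling
#'
#' @param B Adams parameter (dimensionless).  May be `NA` when the object is
#'   only used to compute [equilibrium_adams()].
#' @param T temperature, Kelvin.
#' @param mu_ex excess chemical potential of water, kJ/mol.  The default is
#'   a calibrated value for rigid three-site water under plain-cutoff
#'   Monte Carlo conditions.
#' @param V_std standard-state volume of one water, A^3.
#' @param Lambda thermal de Broglie wavelength, A.  Carried for completeness;
#'   it cancels whenever B is specified directly.
#' @return object of class `adams_parameters` with derived field
#'   `beta = 1/(kB T)` in mol/kJ.
#' @export
adams_parameters <- function(B = NA_real_, T = 300, mu_ex = -25.9,
                             V_std = 30, Lambda = NA_real_) {
  stopifnot(T > 0, V_std > 0)
  structure(list(B = B, T = T, beta = wn_beta(T), mu_ex = mu_ex,
                 V_std = V_std, Lambda = Lambda),
            class = "adams_parameters")
}

#' Equilibrium Adams value for an ROI
#'
#' `B_equil = beta * mu_ex + ln(V_ROI / V_std)`: the Adams value at which
#' the ROI is in equilibrium with bulk water.
#'
#' @param params an [adams_parameters()].
#' @param roi an `roi_region` (only its volume is used).
#' @return the equilibrium Adams value (dimensionless).
#' @export
equilibrium_adams <- function(params, roi) {
  v <- if (inherits(roi, "roi_region")) roi$volume else as.numeric(roi)
  if (!isTRUE(v > 0)) stop("ROI volume must be positive")
  params$beta * params$mu_ex + log(v / params$V_std)
}

#' Insertion acceptance probability
#'
#' @param N number of waters in the initial state.
#' @param dU energy change of the insertion, kJ/mol (`+Inf` for a hard-core
#'   overlap).
#' @param params an [adams_parameters()] with `B` set.
#' @return probability in `[0, 1]`.
#' @export
insertion_acceptance <- function(N, dU, params) {
  stopifnot(N >= 0)
  if (!is.finite(dU) && dU > 0) return(0)
  min(1, exp(params$B - params$beta * dU) / (N + 1))
}

#' Deletion acceptance probability
#'
#' @param N number of waters in the initial state (must be >= 1).
#' @param dU energy change of removing the chosen water, kJ/mol.
#' @param params an [adams_parameters()] with `B` set.
#' @return probability in `[0, 1]`.
#' @export
deletion_acceptance <- function(N, dU, params) {
  if (N < 1) stop("deletion requires at least one water")
  min(1, N * exp(-params$B - params$beta * dU))
}

#' Move mixture for the sampler
#'
#' Insertion and deletion weights must be equal (symmetric proposal, so the
#' Adams acceptance ratios need no proposal correction).
#'
#' @param insert,delete,translate,rotate proposal weights (normalised
#'   internally).
#' @param max_translation half-width of the uniform cubic displacement
#'   proposal, Angstrom.
#' @return object of class `move_mix`.
#' @export
move_mix <- function(insert = 0.25, delete = 0.25, translate = 0.25,
                     rotate = 0.25, max_translation = 0.3) {
  w <- c(insert = insert, delete = delete, translate = translate,
         rotate = rotate)
  stopifnot(all(w >= 0), sum(w) > 0, max_translation > 0)
  if (abs(insert - delete) > 1e-12) {
    stop("insert and delete weights must be equal")
  }
  structure(list(weights = w / sum(w), max_translation = max_translation),
            class = "move_mix")
}

#' Run grand-canonical Monte Carlo on a rigid-water configuration
#'
#' Insertions propose a uniform point in the ROI with a uniform random
#' orientation; deletions pick uniformly among the waters present;
#' translations and rotations act on single waters.  The toy systems are
#' closed over the ROI (no explicit bulk phase): a translation that would
#' carry an oxygen outside the ROI is rejected, so N-in-ROI equals
#' N-in-system throughout.
#'
#' @param config starting [water_configuration()].
#' @param params an [adams_parameters()] with `B` set.
#' @param mix a [move_mix()].
#' @param n_moves number of MC moves.
#' @param record_every record `N` and the running energy every this many
#'   moves.
#' @param seed RNG seed; the run is bit-for-bit reproducible given the seed.
#' @param frame_every optionally snapshot the full configuration every this
#'   many moves (`NULL` for no frames).
#' @return object of class `gc_trace`: list with `records` (data frame:
#'   `step, N, U_total, acc_insert, acc_delete, acc_translate, acc_rotate`),
#'   `frames` (list of `positions`/`orientations` snapshots), `counters`,
#'   `final` configuration, `params`, `mix`, `seed`.
#' @export
run_gcmc <- function(config, params, mix = move_mix(), n_moves,
                     record_every = 100, seed = 1, frame_every = NULL) {
  stopifnot(n_moves > 0, is.finite(params$B))
  set.seed(seed)
  model <- config$model
  box <- config$box
  roi <- config$roi
  host_group <- sites_as_group(config$host)
  s <- nrow(model$geometry)
  q_site <- model$sites$charge
  sig_site <- model$sites$sigma
  eps_site <- model$sites$epsilon

  n <- n_waters(config)
  cap <- max(16L, 2L * n)
  pos <- matrix(NA_real_, cap, 3)
  ori <- matrix(NA_real_, cap, 4)
  sxyz <- matrix(NA_real_, cap * s, 3)
  if (n > 0) {
    pos[1:n, ] <- config$positions
    ori[1:n, ] <- config$orientations
    for (i in 1:n) {
      sxyz[((i - 1) * s + 1):(i * s), ] <-
        sweep(quat_rotate(config$orientations[i, ], model$geometry), 2,
              config$positions[i, ], "+")
    }
  }

  water_group_excl <- function(n, excl) {
    idx <- seq_len(n)
    if (excl > 0) idx <- idx[idx != excl]
    if (!length(idx)) {
      return(list(xyz = matrix(numeric(0), 0, 3), charge = numeric(0),
                  sigma = numeric(0), epsilon = numeric(0)))
    }
    rows <- as.vector(outer(1:s, (idx - 1) * s, "+"))
    list(xyz = sxyz[rows, , drop = FALSE],
         charge = rep(q_site, length(idx)),
         sigma = rep(sig_site, length(idx)),
         epsilon = rep(eps_site, length(idx)))
  }
  trial_energy <- function(W, n, excl) {
    u <- group_energy(W, host_group, box)
    if (is.infinite(u)) return(Inf)
    u2 <- group_energy(W, water_group_excl(n, excl), box)
    u + u2
  }

  u_total <- 0
  if (n > 0) {
    for (i in 1:n) {
      W <- list(xyz = sxyz[((i - 1) * s + 1):(i * s), , drop = FALSE],
                charge = q_site, sigma = sig_site, epsilon = eps_site)
      u_sw <- group_energy(W, host_group, box)
      u_ww <- group_energy(W, water_group_excl(n, i), box)
      u_total <- u_total + u_sw + 0.5 * u_ww
    }
  }

  acc <- c(insert = 0L, delete = 0L, translate = 0L, rotate = 0L)
  att <- c(insert = 0L, delete = 0L, translate = 0L, rotate = 0L)
  noop <- 0L
  interacting <- any(q_site != 0) || any(eps_site > 0) ||
    nrow(config$host) > 0

  n_rec <- n_moves %/% record_every
  rec <- data.frame(step = integer(n_rec), N = integer(n_rec),
                    U_total = numeric(n_rec),
                    acc_insert = integer(n_rec), acc_delete = integer(n_rec),
                    acc_translate = integer(n_rec), acc_rotate = integer(n_rec))
  frames <- list()
  ri <- 0L
  cum_w <- cumsum(mix$weights)
  u_move <- stats::runif(n_moves)
  beta <- params$beta
  B <- params$B

  for (step in seq_len(n_moves)) {
    um <- u_move[step]
    type <- if (um < cum_w[1]) 1L else if (um < cum_w[2]) 2L else
      if (um < cum_w[3]) 3L else 4L
    if (type == 1L) {                                   # insert
      att[1] <- att[1] + 1L
      p_new <- as.vector(roi_sample(roi, 1))
      q_new <- as.vector(random_quaternions(1))
      if (interacting) {
        W <- list(xyz = sweep(quat_rotate(q_new, model$geometry), 2, p_new, "+"),
                  charge = q_site, sigma = sig_site, epsilon = eps_site)
        dU <- trial_energy(W, n, 0L)
      } else {
        dU <- 0
      }
      if (stats::runif(1) < insertion_acceptance(n, dU, params)) {
        n <- n + 1L
        if (n > cap) {        # grow storage
          cap2 <- cap * 2L
          pos2 <- matrix(NA_real_, cap2, 3); pos2[1:(n - 1), ] <- pos[1:(n - 1), ]
          ori2 <- matrix(NA_real_, cap2, 4); ori2[1:(n - 1), ] <- ori[1:(n - 1), ]
          sx2 <- matrix(NA_real_, cap2 * s, 3)
          sx2[1:((n - 1) * s), ] <- sxyz[1:((n - 1) * s), ]
          pos <- pos2; ori <- ori2; sxyz <- sx2; cap <- cap2
        }
        pos[n, ] <- p_new
        ori[n, ] <- q_new
        sxyz[((n - 1) * s + 1):(n * s), ] <-
          sweep(quat_rotate(q_new, model$geometry), 2, p_new, "+")
        u_total <- u_total + (if (interacting) dU else 0)
        acc[1] <- acc[1] + 1L
      }
    } else if (type == 2L) {                            # delete
      if (n == 0L) { noop <- noop + 1L } else {
        att[2] <- att[2] + 1L
        i <- sample.int(n, 1)
        if (interacting) {
          W <- list(xyz = sxyz[((i - 1) * s + 1):(i * s), , drop = FALSE],
                    charge = q_site, sigma = sig_site, epsilon = eps_site)
          dU <- -trial_energy(W, n, i)
        } else dU <- 0
        if (stats::runif(1) < deletion_acceptance(n, dU, params)) {
          if (i < n) {    # move last water into slot i
            pos[i, ] <- pos[n, ]; ori[i, ] <- ori[n, ]
            sxyz[((i - 1) * s + 1):(i * s), ] <- sxyz[((n - 1) * s + 1):(n * s), ]
          }
          n <- n - 1L
          u_total <- u_total + dU
          acc[2] <- acc[2] + 1L
        }
      }
    } else if (type == 3L) {                            # translate
      if (n == 0L) { noop <- noop + 1L } else {
        att[3] <- att[3] + 1L
        i <- sample.int(n, 1)
        disp <- stats::runif(3, -mix$max_translation, mix$max_translation)
        p_new <- pos[i, ] + disp
        if (roi_contains(roi, matrix(p_new, 1))) {
          if (interacting) {
            Wold <- list(xyz = sxyz[((i - 1) * s + 1):(i * s), , drop = FALSE],
                         charge = q_site, sigma = sig_site, epsilon = eps_site)
            u_old <- trial_energy(Wold, n, i)
            new_xyz <- sweep(quat_rotate(ori[i, ], model$geometry), 2, p_new, "+")
            Wnew <- list(xyz = new_xyz, charge = q_site, sigma = sig_site,
                         epsilon = eps_site)
            u_new <- trial_energy(Wnew, n, i)
            dU <- if (is.infinite(u_new)) Inf else u_new - u_old
          } else dU <- 0
          p_acc <- if (is.infinite(dU)) 0 else min(1, exp(-beta * dU))
          if (stats::runif(1) < p_acc) {
            pos[i, ] <- p_new
            sxyz[((i - 1) * s + 1):(i * s), ] <-
              sweep(quat_rotate(ori[i, ], model$geometry), 2, p_new, "+")
            u_total <- u_total + (if (interacting) dU else 0)
            acc[3] <- acc[3] + 1L
          }
        }
      }
    } else {                                            # rotate
      if (n == 0L) { noop <- noop + 1L } else {
        att[4] <- att[4] + 1L
        i <- sample.int(n, 1)
        q_new <- as.vector(random_quaternions(1))
        if (interacting) {
          Wold <- list(xyz = sxyz[((i - 1) * s + 1):(i * s), , drop = FALSE],
                       charge = q_site, sigma = sig_site, epsilon = eps_site)
          u_old <- trial_energy(Wold, n, i)
          new_xyz <- sweep(quat_rotate(q_new, model$geometry), 2, pos[i, ], "+")
          Wnew <- list(xyz = new_xyz, charge = q_site, sigma = sig_site,
                       epsilon = eps_site)
          u_new <- trial_energy(Wnew, n, i)
          dU <- if (is.infinite(u_new)) Inf else u_new - u_old
        } else dU <- 0
        p_acc <- if (is.infinite(dU)) 0 else min(1, exp(-beta * dU))
        if (stats::runif(1) < p_acc) {
          ori[i, ] <- q_new
          sxyz[((i - 1) * s + 1):(i * s), ] <-
            sweep(quat_rotate(q_new, model$geometry), 2, pos[i, ], "+")
          u_total <- u_total + (if (interacting) dU else 0)
          acc[4] <- acc[4] + 1L
        }
      }
    }
    if (step %% record_every == 0L) {
      ri <- ri + 1L
      rec$step[ri] <- step; rec$N[ri] <- n; rec$U_total[ri] <- u_total
      rec$acc_insert[ri] <- acc[1]; rec$acc_delete[ri] <- acc[2]
      rec$acc_translate[ri] <- acc[3]; rec$acc_rotate[ri] <- acc[4]
    }
    if (!is.null(frame_every) && step %% frame_every == 0L) {
      frames[[length(frames) + 1L]] <- list(
        step = step,
        positions = pos[seq_len(n), , drop = FALSE],
        orientations = ori[seq_len(n), , drop = FALSE]
      )
    }
  }

  final <- water_configuration(box, config$host, model,
                               pos[seq_len(n), , drop = FALSE],
                               ori[seq_len(n), , drop = FALSE], roi)
  structure(list(records = rec, frames = frames,
                 counters = list(accepted = acc, attempted = att,
                                 empty_noop = noop),
                 final = final, params = params, mix = mix, seed = seed),
            class = "gc_trace")
}

#' @export
print.gc_trace <- function(x, ...) {
  cat("GCMC trace: B =", signif(x$params$B, 5), ", T =", x$params$T, "K,",
      nrow(x$records), "records, seed", x$seed, "\n")
  cat("  final N =", utils::tail(x$records$N, 1),
      " mean N =", signif(mean(x$records$N), 4), "\n")
  cat("  accepted:", paste(names(x$counters$accepted),
                           x$counters$accepted, collapse = ", "), "\n")
  invisible(x)
}
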