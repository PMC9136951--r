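# Discrete-site grand-canonical model with an exactly enumerable partition
# function.  This is the correctness oracle for the GCMC sampler and for the
# grand-canonical integration of titration curves: every sum over occupancy
# states can be carried out exactly for up to 20 sites.

#' Define a lattice grand-canonical system
#'
#' `M` binding sites with site energies `epsilon_m` (kJ/mol) and optional
#' pair couplings `J_mn` (kJ/mol) between simultaneously occupied sites.
#' A state is an occupancy vector in `{0,1}^M` with energy
#' `U(s) = sum_m s_m epsilon_m + sum_{m<n} s_m s_n J_mn` and
#' grand-canonical weight `exp(B N(s) - beta U(s))`.
#'
#' @param energies vector of site energies, kJ/mol (length M <= 20).
#' @param coupling optional symmetric `M x M` coupling matrix, kJ/mol
#'   (diagonal ignored).
#' @param T temperature, Kelvin.
#' @return object of class `lattice_gc_system`.
#' @export
lattice_gc_system <- function(energies, coupling = NULL, T = 300) {
  energies <- as.numeric(energies)
  M <- length(energies)
  stopifnot(M >= 1, M <= 20, all(is.finite(energies)))
  if (is.null(coupling)) coupling <- matrix(0, M, M)
  coupling <- as.matrix(coupling)
  stopifnot(nrow(coupling) == M, ncol(coupling) == M,
            isTRUE(all.equal(coupling, t(coupling))))
  diag(coupling) <- 0
  structure(list(M = M, energies = energies, coupling = coupling, T = T,
                 beta = wn_beta(T)),
            class = "lattice_gc_system")
}

# occupancy bits for all 2^M states: (2^M) x M matrix of 0/1
lattice_states <- function(M) {
  s <- 0:(2^M - 1)
  bits <- matrix(0L, length(s), M)
  for (m in seq_len(M)) bits[, m] <- bitwAnd(bitwShiftR(s, m - 1L), 1L)
  bits
}

# energy of every occupancy state
lattice_state_energies <- function(system) {
  bits <- lattice_states(system$M)
  U <- as.vector(bits %*% system$energies)
  J <- system$coupling
  if (any(J != 0)) {
    nz <- which(upper.tri(J) & J != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      U <- U + J[nz[r, 1], nz[r, 2]] * bits[, nz[r, 1]] * bits[, nz[r, 2]]
    }
  }
  list(bits = bits, N = rowSums(bits), U = U)
}

#' Exact enumeration of the lattice grand partition function
#'
#' Sums `exp(B N(s) - beta U(s))` over all `2^M` occupancy states with
#' log-sum-exp guarding.
#'
#' @param system a [lattice_gc_system()].
#' @param B Adams value (scalar or vector).
#' @return for scalar `B`, a list with `lnXi`, `mean_N`, `var_N` and `p_N`
#'   (named vector over N = 0..M); for vector `B`, a data frame with one row
#'   per Adams value.
#' @export
enumerate_lattice <- function(system, B) {
  st <- lattice_state_energies(system)
  one <- function(b) {
    lw <- b * st$N - system$beta * st$U
    m <- max(lw)
    w <- exp(lw - m)
    Z <- sum(w)
    mean_N <- sum(st$N * w) / Z
    var_N <- sum(st$N^2 * w) / Z - mean_N^2
    p <- vapply(0:system$M, function(nn) sum(w[st$N == nn]) / Z, numeric(1))
    names(p) <- 0:system$M
    list(lnXi = m + log(Z), mean_N = mean_N, var_N = var_N, p_N = p)
  }
  if (length(B) == 1) return(one(B))
  res <- lapply(B, one)
  data.frame(B = B,
             lnXi = vapply(res, `[[`, numeric(1), "lnXi"),
             mean_N = vapply(res, `[[`, numeric(1), "mean_N"),
             var_N = vapply(res, `[[`, numeric(1), "var_N"))
}

#' GCMC sampling of a lattice grand-canonical system
#'
#' Insertions pick one of the `M` cells uniformly (an occupied cell is an
#' automatic rejection); deletions pick uniformly among occupied cells.  The
#' insertion proposal is uniform over the `M` cells rather than over a
#' continuous volume, so the Adams acceptance rules are applied with
#' `B_cell = B + ln M` -- exactly as the continuum Adams parameter absorbs
#' `ln V_ROI`.  The stationary distribution is then proportional to
#' `exp(B N - beta U)`, the weight [enumerate_lattice()] sums.
#'
#' @param system a [lattice_gc_system()].
#' @param B Adams value.
#' @param n_moves number of insertion/deletion attempts.
#' @param seed RNG seed.
#' @param record_every record cadence (default every move).
#' @return a `gc_trace` (same shape as [run_gcmc()] traces) whose `params$B`
#'   is the physical Adams value `B`.
#' @export
run_gcmc_lattice <- function(system, B, n_moves, seed = 1, record_every = 1) {
  stopifnot(n_moves > 0)
  set.seed(seed)
  M <- system$M
  eps <- system$energies
  J <- system$coupling
  has_J <- any(J != 0)
  params_cell <- adams_parameters(B = B + log(M), T = system$T)
  occ <- rep(FALSE, M)
  n <- 0L
  u_total <- 0

  u_move <- stats::runif(n_moves)
  u_site <- stats::runif(n_moves)
  u_acc <- stats::runif(n_moves)

  n_rec <- n_moves %/% record_every
  rec_N <- integer(n_rec); rec_U <- numeric(n_rec); rec_step <- integer(n_rec)
  acc <- c(insert = 0L, delete = 0L, translate = 0L, rotate = 0L)
  ri <- 0L

  for (step in seq_len(n_moves)) {
    if (u_move[step] < 0.5) {                       # insertion
      m <- floor(u_site[step] * M) + 1L
      if (!occ[m]) {
        dU <- eps[m] + if (has_J) sum(J[m, occ]) else 0
        if (u_acc[step] < insertion_acceptance(n, dU, params_cell)) {
          occ[m] <- TRUE; n <- n + 1L; u_total <- u_total + dU
          acc[1] <- acc[1] + 1L
        }
      }
    } else {                                        # deletion
      if (n > 0L) {
        m <- which(occ)[floor(u_site[step] * n) + 1L]
        dU <- -(eps[m] + if (has_J) sum(J[m, occ]) else 0)
        if (u_acc[step] < deletion_acceptance(n, dU, params_cell)) {
          occ[m] <- FALSE; n <- n - 1L; u_total <- u_total + dU
          acc[2] <- acc[2] + 1L
        }
      }
    }
    if (step %% record_every == 0L) {
      ri <- ri + 1L
      rec_step[ri] <- step; rec_N[ri] <- n; rec_U[ri] <- u_total
    }
  }
  rec <- data.frame(step = rec_step, N = rec_N, U_total = rec_U,
                    acc_insert = NA_integer_, acc_delete = NA_integer_,
                    acc_translate = NA_integer_, acc_rotate = NA_integer_)
  params <- adams_parameters(B = B, T = system$T)
  structure(list(records = rec, frames = list(),
                 counters = list(accepted = acc),
                 final = occ, params = params, mix = NULL, seed = seed),
            class = "gc_trace")
}

#' Exact transfer free energy of a lattice system
#'
#' The exact counterpart of [gci_binding_free_energy()]: with
#' `A(B) = kT [B <N>(B) - ln Xi(B)]` from exact enumeration and `B(N)` the
#' Adams value at which the exact mean occupancy equals `N`,
#' `dG(N_i -> N_f) = kT [B_f N_f - B_i N_i - (ln Xi(B_f) - ln Xi(B_i))
#' - (N_f - N_i) B_equil]`.  A requested `N` outside the mean-occupancy range
#' attainable on `B_range` is clamped to the nearer end of the range (the
#' same convention the titration integrator uses).
#'
#' @param system a [lattice_gc_system()].
#' @param N_i,N_f initial and final network sizes.
#' @param B_equil reference (equilibrium) Adams value.
#' @param B_range length-2 vector bracketing the inversion.
#' @return free energy in kJ/mol.
#' @export
lattice_transfer_free_energy <- function(system, N_i, N_f, B_equil,
                                         B_range = c(-30, 30)) {
  kT <- wn_constants$kB * system$T
  meanN <- function(b) enumerate_lattice(system, b)$mean_N
  lnXi <- function(b) enumerate_lattice(system, b)$lnXi
  b_of_N <- function(N) {
    lo <- meanN(B_range[1]); hi <- meanN(B_range[2])
    if (N <= lo) return(B_range[1])
    if (N >= hi) return(B_range[2])
    stats::uniroot(function(b) meanN(b) - N, interval = B_range,
                   tol = 1e-10)$root
  }
  B_i <- b_of_N(N_i); B_f <- b_of_N(N_f)
  kT * (B_f * N_f - B_i * N_i - (lnXi(B_f) - lnXi(B_i)) -
          (N_f - N_i) * B_equil)
}
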