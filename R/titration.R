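# Titration curves <N>(B) and grand-canonical integration of network
# binding free energies.
#
# The mean occupancy is the B-derivative of the log grand partition
# function, so integrating the titration curve between the Adams values
# B_i, B_f at which the (smoothed) curve passes through the network sizes
# N_i, N_f gives the transfer free energy
#   dG(N_i -> N_f) = kT [ B_f N_f - B_i N_i - int_{B_i}^{B_f} <N> dB
#                         - (N_f - N_i) B_equil ],
# where the last term references the transfer to bulk water at B_equil.

#' Build a titration curve from GCMC traces
#'
#' Traces run at the same Adams value are treated as independent repeats and
#' pooled: the point mean is the mean of repeat means and its standard error
#' is the between-repeat spread (`sd/sqrt(R)`).  A single trace per B gets a
#' block standard error (20 blocks) to absorb autocorrelation.
#'
#' @param traces list of `gc_trace` objects (from [run_gcmc()] or
#'   [run_gcmc_lattice()]), each carrying its Adams value in `params$B`.
#' @param discard_fraction burn-in fraction of records dropped from the start
#'   of every trace (default 0.2).
#' @param B_equil optional equilibrium Adams value stored on the curve.
#' @return object of class `titration_curve`: data frame `points` with
#'   columns `B, mean_N, se_N, n_samples`, plus `T`, `B_equil` and
#'   provenance.
#' @export
build_titration_curve <- function(traces, discard_fraction = 0.2,
                                  B_equil = NA_real_) {
  stopifnot(length(traces) >= 1, discard_fraction >= 0, discard_fraction < 1)
  Bs <- vapply(traces, function(tr) tr$params$B, numeric(1))
  Ts <- vapply(traces, function(tr) tr$params$T, numeric(1))
  if (length(unique(Ts)) != 1) stop("traces were run at different temperatures")
  if (length(unique(Bs)) < 4) {
    stop("need at least 4 distinct Adams values to build a titration curve")
  }
  post <- lapply(traces, function(tr) {
    N <- tr$records$N
    keep <- N[max(1, floor(discard_fraction * length(N)) + 1):length(N)]
    if (length(keep) < 50) {
      stop("a trace has fewer than 50 post-burn-in records")
    }
    keep
  })
  pts <- lapply(split(seq_along(traces), Bs), function(idx) {
    reps <- post[idx]
    means <- vapply(reps, mean, numeric(1))
    n_tot <- sum(lengths(reps))
    if (length(idx) > 1) {
      se <- stats::sd(means) / sqrt(length(means))
    } else {
      x <- reps[[1]]
      nb <- 20L
      bl <- split(x, cut(seq_along(x), nb, labels = FALSE))
      bm <- vapply(bl, mean, numeric(1))
      se <- stats::sd(bm) / sqrt(nb)
    }
    data.frame(B = Bs[idx[1]], mean_N = mean(means), se_N = se,
               n_samples = n_tot)
  })
  points <- do.call(rbind, pts)
  points <- points[order(points$B), ]
  rownames(points) <- NULL
  structure(list(points = points, T = Ts[1], B_equil = B_equil,
                 discard_fraction = discard_fraction,
                 seeds = vapply(traces, function(tr) tr$seed, numeric(1))),
            class = "titration_curve")
}

#' Construct a titration curve from a table of points
#'
#' Convenience constructor for curves whose points come from an external
#' source (or from exact enumeration).
#'
#' @param B,mean_N,se_N,n_samples point vectors (B strictly increasing).
#' @param T temperature, Kelvin.
#' @param B_equil optional equilibrium Adams value.
#' @return a `titration_curve`.
#' @export
titration_curve <- function(B, mean_N, se_N = 0, n_samples = NA_integer_,
                            T = 300, B_equil = NA_real_) {
  stopifnot(length(B) >= 4, all(diff(B) > 0), all(mean_N >= 0))
  structure(list(points = data.frame(B = B, mean_N = mean_N,
                                     se_N = rep_len(se_N, length(B)),
                                     n_samples = rep_len(n_samples, length(B))),
                 T = T, B_equil = B_equil, discard_fraction = NA_real_,
                 seeds = NULL),
            class = "titration_curve")
}

# Monotone smoothing: isotonic regression then monotone piecewise cubic
# (Fritsch-Carlson) interpolation on a refined grid.
smooth_titration <- function(curve, n_grid = 1000) {
  p <- curve$points
  iso <- stats::isoreg(p$B, p$mean_N)
  f <- stats::splinefun(p$B, iso$yf, method = "monoH.FC")
  Bg <- seq(min(p$B), max(p$B), length.out = n_grid)
  list(B = Bg, N = pmax(0, f(Bg)), fun = f, iso = iso$yf)
}

# invert the smoothed curve: B at which it passes through N.
# Flat stretches resolve to the midpoint of the flat interval; a requested N
# within clamp_tol of the attained range clamps to the range end.
invert_titration <- function(sm, N, clamp_tol = 0.05) {
  lo <- min(sm$N); hi <- max(sm$N)
  if (N < lo - clamp_tol || N > hi + clamp_tol) {
    stop(sprintf(paste0("requested N = %g outside the sampled occupancy ",
                        "range [%.4g, %.4g]; refusing to extrapolate"),
                 N, lo, hi))
  }
  Nc <- min(max(N, lo), hi)
  d <- abs(sm$N - Nc)
  hit <- which(d <= d[which.min(d)] + 1e-12)
  mean(range(sm$B[hit]))
}

#' Network binding free energy by grand-canonical integration
#'
#' @param curve a `titration_curve`.
#' @param N_i,N_f initial and final network sizes (within the span of the
#'   smoothed curve; a value within `clamp_tol` of the span is clamped to
#'   its end, beyond that the function refuses to extrapolate).
#' @param B_equil equilibrium Adams value (defaults to the curve's).
#' @param clamp_tol tolerance for end clamping (waters).
#' @return list with `dG` (kJ/mol), `se` (propagated through the quadrature),
#'   `B_i`, `B_f`.
#' @export
gci_binding_free_energy <- function(curve, N_i, N_f,
                                    B_equil = curve$B_equil,
                                    clamp_tol = 0.05) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!is.finite(B_equil)) stop("B_equil is required (none stored on curve)")
  kT <- wn_constants$kB * curve$T
  if (N_i == N_f) return(list(dG = 0, se = 0, B_i = NA_real_, B_f = NA_real_))
  sm <- smooth_titration(curve)
  B_i <- invert_titration(sm, N_i, clamp_tol)
  B_f <- invert_titration(sm, N_f, clamp_tol)
  lo <- min(B_i, B_f); hi <- max(B_i, B_f)
  keep <- sm$B >= lo & sm$B <= hi
  Bq <- c(lo, sm$B[keep], hi)
  Nq <- c(sm$fun(lo), sm$N[keep], sm$fun(hi))
  I <- pracma::trapz(Bq, Nq)
  if (B_f < B_i) I <- -I
  dG <- kT * (B_f * N_f - B_i * N_i - I - (N_f - N_i) * B_equil)
  # SE: the integral is linear in the per-point means; propagate point SEs
  # through trapezoid weights on the original grid restricted to [lo, hi].
  p <- curve$points
  w <- rep(0, nrow(p))
  inb <- which(p$B >= lo - 1e-9 & p$B <= hi + 1e-9)
  if (length(inb) >= 2) {
    Bp <- p$B[inb]
    w[inb] <- c(diff(Bp) / 2, 0) + c(0, diff(Bp) / 2)
  }
  se <- kT * sqrt(sum((w * p$se_N)^2))
  list(dG = dG, se = se, B_i = B_i, B_f = B_f)
}

#' Free-energy profile over network sizes
#'
#' Tabulates the binding free energy `dG(0 -> N)` for every integer `N`
#' attainable on the smoothed titration curve, locates the global minimum,
#' flags a shallow minimum (neighbours within kT), and interpolates the mean
#' occupancy at `B_equil` with its standard error.
#'
#' @param curve a `titration_curve`.
#' @param B_equil equilibrium Adams value (defaults to the curve's).
#' @param clamp_tol end-clamping tolerance passed to
#'   [gci_binding_free_energy()].
#' @return object of class `free_energy_profile`: data frame `profile`
#'   (`N, dG, se`), `optimal_N`, `dG_min`, `shallow` flag, `N_at_Bequil`,
#'   `se_N_at_Bequil`.
#' @export
free_energy_profile <- function(curve, B_equil = curve$B_equil,
                                clamp_tol = 0.05) {
  stopifnot(inherits(curve, "titration_curve"))
  if (!is.finite(B_equil)) stop("B_equil is required (none stored on curve)")
  p <- curve$points
  if (B_equil < min(p$B) || B_equil > max(p$B)) {
    stop(sprintf("B_equil = %g outside the sampled Adams range [%g, %g]",
                 B_equil, min(p$B), max(p$B)))
  }
  sm <- smooth_titration(curve)
  N_max <- floor(max(sm$N) + clamp_tol)
  Ns <- 0:N_max
  res <- lapply(Ns, function(N) {
    if (N == 0) return(list(dG = 0, se = 0))
    gci_binding_free_energy(curve, 0, N, B_equil, clamp_tol)
  })
  prof <- data.frame(N = Ns,
                     dG = vapply(res, `[[`, numeric(1), "dG"),
                     se = vapply(res, `[[`, numeric(1), "se"))
  i_min <- which.min(prof$dG)
  kT <- wn_constants$kB * curve$T
  nb <- prof$dG[c(i_min - 1, i_min + 1)]
  nb <- nb[!is.na(nb)]
  shallow <- length(nb) > 0 && any(abs(nb - prof$dG[i_min]) < kT)
  N_eq <- sm$fun(B_equil)
  se_eq <- stats::approx(p$B, p$se_N, xout = B_equil, rule = 2)$y
  structure(list(profile = prof, optimal_N = prof$N[i_min],
                 dG_min = prof$dG[i_min], shallow = shallow,
                 N_at_Bequil = N_eq, se_N_at_Bequil = se_eq,
                 B_equil = B_equil, T = curve$T),
            class = "free_energy_profile")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("Titration curve:", nrow(x$points), "Adams values, T =", x$T, "K\n")
  if (is.finite(x$B_equil)) cat("  B_equil =", signif(x$B_equil, 5), "\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("Water-network free-energy profile (T =", x$T, "K)\n")
  cat(sprintf("  optimal N = %d, dG_min = %.2f kJ/mol%s\n", x$optimal_N,
              x$dG_min, if (x$shallow) "  [shallow minimum]" else ""))
  cat(sprintf("  <N> at B_equil (%.3f) = %.2f +/- %.2f\n", x$B_equil,
              x$N_at_Bequil, x$se_N_at_Bequil))
  print(x$profile, row.names = FALSE)
  invisible(x)
}
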