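# Comparison statistics for hydration structure across simulations:
# exponential equilibration fits, water-site clustering, Tanimoto similarity,
# crystal-water recovery curves, rank tests on occupancy distributions and
# paired-site deviation metrics.

#' Synthesise or wrap an occupancy trace
#'
#' @param times time points, ns, strictly increasing.
#' @param mean_N mean number of waters in the ROI at each time (averaged
#'   over repeats).
#' @param repeats optional matrix (`length(times) x R`) of per-repeat series.
#' @param label free-text label (e.g. "ACD-NPT").
#' @return object of class `occupancy_trace`.
#' @export
occupancy_trace <- function(times, mean_N, repeats = NULL, label = "") {
  stopifnot(all(diff(times) > 0), all(mean_N >= 0),
            length(times) == length(mean_N))
  if (!is.null(repeats)) stopifnot(nrow(repeats) == length(times))
  structure(list(times = times, mean_N = mean_N, repeats = repeats,
                 label = label),
            class = "occupancy_trace")
}

#' Fit the exponential hydration-equilibration model
#'
#' Fits `N(t) = a + b (1 - exp(-k t))` by bounded nonlinear least squares
#' (all three parameters constrained non-negative): `a` waters at `t = 0`,
#' converging to `a + b` as `t -> Inf`.  The equilibration time is the time
#' at which the fitted curve reaches 95% of the plateau,
#' `t_eq = (1/k) ln(b / (0.05 (a + b)))`, defined as 0 when
#' `b <= 0.05 (a + b)` (the trace is already equilibrated at the start).
#' `N_eq` is the mean of the observed `N(t)` over `t >= t_eq`.
#'
#' @param trace an [occupancy_trace()] (>= 10 time points).
#' @return object of class `equilibration_fit`: `a`, `b`, `k_rate` (ns^-1),
#'   `t_eq` (ns), `N_eq` (waters), `cov` (parameter covariance), `fit`
#'   (the underlying `nls` object).
#' @export
fit_equilibration <- function(trace) {
  stopifnot(inherits(trace, "occupancy_trace"))
  t <- trace$times; N <- trace$mean_N
  if (length(t) < 10) stop("need at least 10 time points")
  a0 <- max(N[1], 1e-3)
  b0 <- max(mean(utils::tail(N, max(3, length(N) %/% 5))) - a0, 1e-3)
  k0 <- 3 / max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(N ~ a + b * (1 - exp(-k * t)),
                      start = list(a = a0, b = b0, k = k0),
                      lower = c(0, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # A trace with no time trend leaves b and k jointly unidentifiable
    # (singular gradient); it is already equilibrated, so fall back to the
    # constant model b = 0.
    trend <- suppressWarnings(stats::cor(t, N))
    if (is.na(trend) || abs(trend) < 0.3) {
      out <- structure(list(a = mean(N), b = 0, k_rate = 0, t_eq = 0,
                            N_eq = mean(N), cov = NULL, fit = NULL,
                            label = trace$label),
                       class = "equilibration_fit")
      return(out)
    }
    stop("equilibration fit did not converge (starting values a=",
         signif(a0, 3), ", b=", signif(b0, 3), ", k=", signif(k0, 3),
         "): ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  a <- cf[["a"]]; b <- cf[["b"]]; k <- cf[["k"]]
  t_eq <- if (b > 0.05 * (a + b) && k > 0) log(b / (0.05 * (a + b))) / k else 0
  N_eq <- mean(N[t >= t_eq])
  structure(list(a = a, b = b, k_rate = k, t_eq = t_eq, N_eq = N_eq,
                 cov = tryCatch(stats::vcov(fit), error = function(e) NULL),
                 fit = fit, label = trace$label),
            class = "equilibration_fit")
}

#' @export
print.equilibration_fit <- function(x, ...) {
  cat(sprintf(
    "Equilibration fit%s: a = %.3f, b = %.3f, k = %.3f /ns; t_eq = %.3f ns, N_eq = %.3f\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$a, x$b, x$k_rate, x$t_eq, x$N_eq))
  invisible(x)
}

#' Cluster water observations into hydration sites
#'
#' Average-linkage hierarchical clustering of water oxygen positions pooled
#' over frames, cut at `cutoff`; the distance between waters present in the
#' same frame is set to an arbitrarily high value (1e6 A) so that two waters
#' observed simultaneously are never merged.  Clusters occupied in fewer
#' than `occupancy_min` of the frames are dropped (unless
#' `occupancy_min = 0`).
#'
#' @param frames list of `n_i x 3` matrices of water oxygen positions, one
#'   per frame (frames may be empty).
#' @param cutoff linkage distance cutoff, Angstrom (default 2.4).
#' @param occupancy_min minimum occupancy fraction (default 0.3).
#' @return object of class `water_cluster_set`: data frame `clusters`
#'   (`x, y, z, occupancy, n_members`, ordered by decreasing occupancy),
#'   `n_frames` and the clustering parameters.
#' @export
cluster_waters <- function(frames, cutoff = 2.4, occupancy_min = 0.3) {
  stopifnot(length(frames) >= 1)
  frames <- lapply(frames, function(f) matrix(f, ncol = 3))
  n_frames <- length(frames)
  counts <- vapply(frames, nrow, integer(1))
  X <- do.call(rbind, frames)
  frame_id <- rep(seq_along(frames), counts)
  empty <- structure(list(clusters = data.frame(x = numeric(0), y = numeric(0),
                                                z = numeric(0),
                                                occupancy = numeric(0),
                                                n_members = integer(0)),
                          n_frames = n_frames, cutoff = cutoff,
                          occupancy_min = occupancy_min),
                     class = "water_cluster_set")
  if (is.null(X) || nrow(X) == 0) return(empty)
  if (nrow(X) == 1) {
    memb <- 1L
  } else {
    D <- as.matrix(stats::dist(X))
    same <- outer(frame_id, frame_id, "==")
    diag(same) <- FALSE
    D[same] <- 1e6
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    memb <- stats::cutree(hc, h = cutoff)
  }
  cl <- lapply(split(seq_len(nrow(X)), memb), function(idx) {
    data.frame(x = mean(X[idx, 1]), y = mean(X[idx, 2]), z = mean(X[idx, 3]),
               occupancy = length(unique(frame_id[idx])) / n_frames,
               n_members = length(idx))
  })
  clusters <- do.call(rbind, cl)
  if (occupancy_min > 0) {
    clusters <- clusters[clusters$occupancy >= occupancy_min, , drop = FALSE]
  }
  clusters <- clusters[order(-clusters$occupancy), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, n_frames = n_frames, cutoff = cutoff,
                 occupancy_min = occupancy_min),
            class = "water_cluster_set")
}

#' @export
print.water_cluster_set <- function(x, ...) {
  cat("Water cluster set:", nrow(x$clusters), "cluster(s) from", x$n_frames,
      "frame(s); cutoff", x$cutoff, "A, occupancy >=", x$occupancy_min, "\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

# Greedy ascending-distance one-to-one matching between two point sets.
# Returns a data frame (i, j, dist) of matched pairs with dist <= max_dist.
greedy_match <- function(A, B, max_dist = Inf) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  D <- sqrt(pmax(outer(rowSums(A^2), rep(1, nrow(B))) +
                   outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B), 0))
  ord <- order(D)
  used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
  out <- list()
  for (o in ord) {
    if (D[o] > max_dist) break
    i <- (o - 1) %% nrow(A) + 1
    j <- (o - 1) %/% nrow(A) + 1
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out[[length(out) + 1]] <- data.frame(i = i, j = j, dist = D[o])
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  do.call(rbind, out)
}

cluster_xyz <- function(x) {
  if (inherits(x, "water_cluster_set")) {
    as.matrix(x$clusters[, c("x", "y", "z")])
  } else {
    matrix(x, ncol = 3)
  }
}

#' Tanimoto similarity of two hydration-site sets
#'
#' `T = c / (a + b - c)` where `a` and `b` are the numbers of clusters in
#' the two sets and `c` the number that agree within `match_dist` under
#' greedy ascending-distance one-to-one matching (symmetric by
#' construction).
#'
#' @param set_a,set_b [cluster_waters()] results (or plain `n x 3` centroid
#'   matrices).  Both should be filtered at the same occupancy threshold.
#' @param match_dist agreement distance, Angstrom (default 1.4).
#' @return similarity in `[0, 1]`.  Two empty sets are defined as similarity
#'   1 (attribute `both_empty` set); one empty set gives 0.
#' @export
tanimoto_similarity <- function(set_a, set_b, match_dist = 1.4) {
  A <- cluster_xyz(set_a); B <- cluster_xyz(set_b)
  a <- nrow(A); b <- nrow(B)
  if (a == 0 && b == 0) return(structure(1, both_empty = TRUE))
  if (a == 0 || b == 0) return(0)
  c_match <- nrow(greedy_match(A, B, match_dist))
  c_match / (a + b - c_match)
}

#' Crystal-water recovery curve
#'
#' For each distance threshold, the fraction of crystallographic water sites
#' recovered by at least one cluster centroid within that distance, under
#' one-to-one greedy ascending-distance matching (so a single centroid
#' cannot recover two crystal waters).  Because greedy matching processes
#' pairs in ascending distance, the matching at a smaller threshold is a
#' prefix of the matching at a larger one, and the curve is nondecreasing.
#'
#' @param clusters a [cluster_waters()] result (or `n x 3` centroid matrix).
#' @param crystal_waters `m x 3` matrix of crystal-water oxygen coordinates
#'   (must be non-empty).
#' @param thresholds nondecreasing distance thresholds, Angstrom.
#' @return data frame `threshold, recovered, fraction`.
#' @export
crystal_recovery <- function(clusters, crystal_waters,
                             thresholds = seq(0, 2, by = 0.1)) {
  crystal_waters <- matrix(crystal_waters, ncol = 3)
  if (nrow(crystal_waters) == 0) stop("no crystal waters to recover")
  if (any(diff(thresholds) < 0)) stop("thresholds must be nondecreasing")
  C <- cluster_xyz(clusters)
  m <- greedy_match(crystal_waters, C, max_dist = max(thresholds))
  rec <- vapply(thresholds, function(d) sum(m$dist <= d), numeric(1))
  data.frame(threshold = thresholds, recovered = rec,
             fraction = rec / nrow(crystal_waters))
}

# Two-sample Kruskal-Wallis (tie-corrected chi-square via stats::kruskal.test
# with a permutation fallback for small samples).
kw_two_sample <- function(x, y, n_perm = 2000) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(list(H = 0, p = 1, degenerate = TRUE))
  }
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  kt <- stats::kruskal.test(pooled, g)
  H <- unname(kt$statistic); p <- kt$p.value
  if (min(length(x), length(y)) < 10) {
    # permutation reference distribution of H
    stat <- function(perm) {
      unname(stats::kruskal.test(pooled, g[perm])$statistic)
    }
    n <- length(pooled)
    ge <- 0L
    for (r in seq_len(n_perm)) {
      if (stat(sample.int(n)) >= H - 1e-12) ge <- ge + 1L
    }
    p <- (ge + 1) / (n_perm + 1)
  }
  list(H = H, p = p, degenerate = FALSE)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.1, ".", ""))))
}

#' Pairwise rank-test comparison of occupancy distributions
#'
#' Every pair of post-equilibration N-series is compared with a two-sample
#' Kruskal-Wallis rank test (tie-corrected chi-square approximation; an
#' exact permutation reference is used when either subsampled series has
#' fewer than 10 values).  Significance stars follow the convention
#' `p < 0.001 "***"`, `< 0.01 "**"`, `< 0.05 "*"`, `< 0.1 "."`.
#'
#' @param samples named list of numeric N-series (post-equilibration).
#' @param subsample_every keep every `subsample_every`-th value of each
#'   series to thin autocorrelated samples (default 1 = keep all).
#' @return list with symmetric matrices `p` (unit diagonal), `H`, and
#'   character matrix `stars`.
#' @export
compare_N_distributions <- function(samples, subsample_every = 1) {
  stopifnot(length(samples) >= 2)
  sub <- lapply(samples, function(x) x[seq(1, length(x), by = subsample_every)])
  if (any(lengths(sub) < 5)) {
    stop("every series must retain at least 5 values after subsampling")
  }
  k <- length(sub)
  nms <- names(sub)
  if (is.null(nms)) nms <- paste0("S", seq_len(k))
  P <- matrix(1, k, k, dimnames = list(nms, nms))
  H <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- kw_two_sample(sub[[i]], sub[[j]])
      P[i, j] <- P[j, i] <- r$p
      H[i, j] <- H[j, i] <- r$H
    }
  }
  stars <- matrix(p_stars(P), k, k, dimnames = dimnames(P))
  diag(stars) <- ""
  list(p = P, H = H, stars = stars)
}

#' Pair hydration sites between two runs and score their agreement
#'
#' Sites are paired one-to-one by greedy ascending centroid distance with
#' pairs beyond `pairing_dist` discarded; the paired scalar values (for
#' example per-site free energies) are scored with the Pearson correlation,
#' the mean absolute deviation, the maximum absolute deviation and the mean
#' relative deviation (absolute difference divided by the larger of the two
#' absolute values, averaged over pairs).
#'
#' @param sites_a,sites_b data frames with columns `x, y, z, value`.
#' @param pairing_dist maximum pairing distance, Angstrom (default 1.0).
#' @return list `R`, `MAD`, `Max`, `MRD`, `n_paired`, `pairs`.
#' @export
pair_and_score_sites <- function(sites_a, sites_b, pairing_dist = 1.0) {
  A <- as.matrix(sites_a[, c("x", "y", "z")])
  B <- as.matrix(sites_b[, c("x", "y", "z")])
  m <- greedy_match(A, B, pairing_dist)
  if (nrow(m) == 0) {
    D <- sqrt(pmax(outer(rowSums(A^2), rep(1, nrow(B))) +
                     outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B), 0))
    stop("no site pairs within ", pairing_dist, " A; nearest distances: ",
         paste(signif(sort(D)[seq_len(min(3, length(D)))], 3), collapse = ", "))
  }
  va <- sites_a$value[m$i]; vb <- sites_b$value[m$j]
  dv <- abs(va - vb)
  denom <- pmax(abs(va), abs(vb))
  mrd <- mean(ifelse(denom > 0, dv / denom, 0))
  R <- if (nrow(m) >= 2 && stats::sd(va) > 0 && stats::sd(vb) > 0) {
    stats::cor(va, vb)
  } else NA_real_
  list(R = R, MAD = mean(dv), Max = max(dv), MRD = mrd, n_paired = nrow(m),
       pairs = cbind(m, value_a = va, value_b = vb))
}
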