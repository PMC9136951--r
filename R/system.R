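# Simulation boxes, regions of interest and rigid-water configurations.

#' Define a (possibly periodic) orthorhombic simulation box
#'
#' @param lengths 3-vector of box edge lengths, Angstrom.
#' @param periodic logical; apply the minimum-image convention?
#' @param cutoff non-bonded cutoff, Angstrom.  Interactions are plainly
#'   truncated (zero beyond the cutoff, no shift or switch, no long-range
#'   electrostatic correction).
#' @return object of class `simulation_box`.
#' @export
simulation_box <- function(lengths, periodic = TRUE, cutoff = 10) {
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) == 3, all(lengths > 0), cutoff > 0)
  if (periodic && any(lengths <= 2 * cutoff)) {
    stop("periodic box lengths must all exceed twice the cutoff")
  }
  structure(list(lengths = lengths, periodic = periodic, cutoff = cutoff),
            class = "simulation_box")
}

#' Cuboidal region of interest
#' @param center 3-vector, Angstrom.
#' @param lengths 3-vector of edge lengths, Angstrom.
#' @return object of class `roi_region`.
#' @export
roi_cuboid <- function(center, lengths) {
  center <- as.numeric(center); lengths <- as.numeric(lengths)
  stopifnot(length(center) == 3, length(lengths) == 3, all(lengths > 0))
  structure(list(shape = "cuboid", center = center, lengths = lengths,
                 volume = prod(lengths)),
            class = "roi_region")
}

#' Spherical region of interest
#' @param center 3-vector, Angstrom.
#' @param radius radius, Angstrom.
#' @return object of class `roi_region`.
#' @export
roi_sphere <- function(center, radius) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, radius > 0)
  structure(list(shape = "sphere", center = center, radius = radius,
                 volume = 4 / 3 * pi * radius^3),
            class = "roi_region")
}

#' Test points for ROI membership
#' @param roi an `roi_region`.
#' @param X `n x 3` matrix of points.
#' @return logical vector.
#' @export
roi_contains <- function(roi, X) {
  X <- matrix(X, ncol = 3)
  if (roi$shape == "cuboid") {
    h <- roi$lengths / 2
    abs(X[, 1] - roi$center[1]) <= h[1] &
      abs(X[, 2] - roi$center[2]) <= h[2] &
      abs(X[, 3] - roi$center[3]) <= h[3]
  } else {
    rowSums(sweep(X, 2, roi$center)^2) <= roi$radius^2
  }
}

#' Sample points uniformly inside an ROI
#' @param roi an `roi_region`.
#' @param n number of points.
#' @return `n x 3` matrix.
#' @export
roi_sample <- function(roi, n) {
  if (roi$shape == "cuboid") {
    sweep(
      cbind(stats::runif(n, -0.5, 0.5) * roi$lengths[1],
            stats::runif(n, -0.5, 0.5) * roi$lengths[2],
            stats::runif(n, -0.5, 0.5) * roi$lengths[3]),
      2, roi$center, "+"
    )
  } else {
    # direct radial sampling: r ~ R * U^(1/3), direction uniform
    r <- roi$radius * stats::runif(n)^(1 / 3)
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    sz <- sqrt(1 - z^2)
    sweep(cbind(r * sz * cos(phi), r * sz * sin(phi), r * z),
          2, roi$center, "+")
  }
}

roi_inside_box <- function(roi, box) {
  if (!box$periodic) return(TRUE)
  lo <- rep(0, 3); hi <- box$lengths
  if (roi$shape == "cuboid") {
    all(roi$center - roi$lengths / 2 >= lo) &&
      all(roi$center + roi$lengths / 2 <= hi)
  } else {
    all(roi$center - roi$radius >= lo) && all(roi$center + roi$radius <= hi)
  }
}

#' Assemble a rigid-water configuration
#'
#' Host sites are fixed in space for the lifetime of the object; waters are
#' described by their oxygen position and a unit quaternion orientation.
#'
#' @param box a [simulation_box()].
#' @param host_sites data frame from [interaction_sites()] (may have 0 rows).
#' @param model a [water_model()].
#' @param positions `n x 3` matrix of water oxygen positions (may be empty).
#' @param orientations `n x 4` matrix of unit quaternions.
#' @param roi an `roi_region`; for a periodic box it must lie wholly inside
#'   the primary cell `[0, L)^3`.
#' @return object of class `water_configuration`.
#' @export
water_configuration <- function(box, host_sites, model, positions = NULL,
                                orientations = NULL, roi) {
  stopifnot(inherits(box, "simulation_box"), inherits(model, "water_model"),
            inherits(roi, "roi_region"))
  if (is.null(positions)) positions <- matrix(numeric(0), 0, 3)
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (is.null(orientations)) orientations <- matrix(rep(c(1, 0, 0, 0), n),
                                                    ncol = 4, byrow = TRUE)
  orientations <- matrix(orientations, ncol = 4)
  stopifnot(nrow(orientations) == n)
  if (n > 0) {
    norms <- sqrt(rowSums(orientations^2))
    if (any(abs(norms - 1) > 1e-9)) {
      stop("orientation quaternions must be unit norm within 1e-9")
    }
  }
  if (!roi_inside_box(roi, box)) {
    stop("ROI must lie wholly inside the primary periodic cell")
  }
  structure(
    list(box = box, host = host_sites, model = model,
         positions = positions, orientations = orientations, roi = roi),
    class = "water_configuration"
  )
}

#' Number of waters in a configuration
#' @param config a `water_configuration`.
#' @export
n_waters <- function(config) nrow(config$positions)

#' Expand a water into its interaction sites
#'
#' Applies the orientation quaternion to the model's rigid internal geometry
#' and translates to the oxygen position.
#'
#' @param config a `water_configuration`.
#' @param index water index (1-based).
#' @return list with `xyz` (s x 3), `charge`, `sigma`, `epsilon`.
#' @export
water_sites <- function(config, index) {
  q <- config$orientations[index, ]
  xyz <- quat_rotate(q, config$model$geometry)
  xyz <- sweep(xyz, 2, config$positions[index, ], "+")
  list(xyz = xyz,
       charge = config$model$sites$charge,
       sigma = config$model$sites$sigma,
       epsilon = config$model$sites$epsilon)
}

#' @export
print.water_configuration <- function(x, ...) {
  cat("Rigid-water configuration:", n_waters(x), "water(s),",
      nrow(x$host), "host site(s)\n")
  cat("  box:", paste(signif(x$box$lengths, 4), collapse = " x "),
      "A,", if (x$box$periodic) "periodic," else "non-periodic,",
      "cutoff", x$box$cutoff, "A\n")
  cat("  ROI:", x$roi$shape, "volume", signif(x$roi$volume, 5), "A^3\n")
  cat("  water model:", x$model$name, "\n")
  invisible(x)
}
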