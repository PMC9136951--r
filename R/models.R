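# Rigid water models and interaction-site tables.

site_kinds <- c("host", "water_oxygen", "water_hydrogen", "water_virtual")

#' Build a table of interaction sites
#'
#' @param position `n x 3` matrix of coordinates (Angstrom).
#' @param charge partial charges (e), recycled.
#' @param sigma Lennard-Jones diameters (Angstrom), recycled; 0 disables LJ.
#' @param epsilon LJ well depths (kJ/mol), recycled; 0 disables LJ.
#' @param kind site tag, one of `"host"`, `"water_oxygen"`,
#'   `"water_hydrogen"`, `"water_virtual"`.
#' @return a data frame with columns `x, y, z, charge, sigma, epsilon, kind`.
#' @export
interaction_sites <- function(position, charge = 0, sigma = 0, epsilon = 0,
                              kind = "host") {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- nrow(position)
  kind <- rep_len(kind, n)
  stopifnot(all(kind %in% site_kinds))
  out <- data.frame(
    x = position[, 1], y = position[, 2], z = position[, 3],
    charge = rep_len(as.numeric(charge), n),
    sigma = rep_len(as.numeric(sigma), n),
    epsilon = rep_len(as.numeric(epsilon), n),
    kind = kind,
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(as.matrix(out[, 1:6])))) {
    stop("interaction sites must have finite coordinates and parameters")
  }
  if (any(out$sigma < 0) || any(out$epsilon < 0)) {
    stop("sigma and epsilon must be non-negative")
  }
  out
}

#' Read a rigid water model from a key-value parameter file
#'
#' The plain-text format has `name` and `rho0` records plus one `site` record
#' per interaction site:
#' `site <name> <kind> <x> <y> <z> <charge> <sigma> <epsilon>`.
#' Site coordinates are internal (molecule-frame) coordinates with the oxygen
#' at the origin; the molecule is rigid, so these internal distances never
#' change during sampling.
#'
#' @param path path to the parameter file.
#' @return an object of class `water_model`: list with `name`, `rho0`
#'   (bulk number density, A^-3) and `sites` (see [interaction_sites()]).
#' @export
read_water_model <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  name <- NULL; rho0 <- NULL; sites <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "name") {
      name <- tok[2]
    } else if (tok[1] == "rho0") {
      rho0 <- as.numeric(tok[2])
    } else if (tok[1] == "site") {
      if (length(tok) != 9) stop("malformed site record: ", ln)
      sites[[length(sites) + 1]] <- data.frame(
        name = tok[2], kind = tok[3],
        x = as.numeric(tok[4]), y = as.numeric(tok[5]), z = as.numeric(tok[6]),
        charge = as.numeric(tok[7]), sigma = as.numeric(tok[8]),
        epsilon = as.numeric(tok[9]), stringsAsFactors = FALSE
      )
    } else {
      stop("unknown record '", tok[1], "' in water model file")
    }
  }
  if (is.null(name) || is.null(rho0) || !length(sites)) {
    stop("water model file must define name, rho0 and at least one site")
  }
  sites <- do.call(rbind, sites)
  water_model(name, rho0, sites)
}

#' Construct a rigid water model
#'
#' @param name model name.
#' @param rho0 bulk number density, A^-3; must be positive.
#' @param sites data frame with columns
#'   `name, kind, x, y, z, charge, sigma, epsilon` in molecule-frame
#'   coordinates.
#' @return object of class `water_model`.
#' @export
water_model <- function(name, rho0, sites) {
  stopifnot(is.numeric(rho0), rho0 > 0)
  needed <- c("name", "kind", "x", "y", "z", "charge", "sigma", "epsilon")
  stopifnot(all(needed %in% names(sites)))
  stopifnot(all(sites$kind %in% site_kinds))
  if (abs(sum(sites$charge)) > 1e-10) {
    stop("water model must be net neutral (|sum q| <= 1e-10 e)")
  }
  structure(
    list(name = name, rho0 = rho0,
         sites = sites[, needed],
         geometry = as.matrix(sites[, c("x", "y", "z")])),
    class = "water_model"
  )
}

#' Load one of the shipped water models
#' @param name `"tip3p"`, `"tip4p"` or `"ideal"`.  The ideal model is a
#'   single uncharged site with no LJ parameters; a gas of such waters is
#'   non-interacting, which gives closed-form grand-canonical behaviour
#'   (Poisson occupancy with mean `e^B`).
#' @return a `water_model`.
#' @export
load_water_model <- function(name = c("tip3p", "tip4p", "ideal")) {
  name <- match.arg(name)
  if (name == "ideal") {
    return(water_model("ideal", rho0 = 0.0329, sites = data.frame(
      name = "O", kind = "water_oxygen", x = 0, y = 0, z = 0,
      charge = 0, sigma = 0, epsilon = 0, stringsAsFactors = FALSE
    )))
  }
  path <- system.file("extdata", "water_models", paste0(name, ".txt"),
                      package = "waternet")
  if (!nzchar(path)) stop("bundled water model not found: ", name)
  read_water_model(path)
}

#' @export
print.water_model <- function(x, ...) {
  cat("Rigid water model", x$name, "\n")
  cat("  bulk density rho0 =", x$rho0, "A^-3\n")
  cat("  sites:\n")
  print(x$sites, row.names = FALSE)
  invisible(x)
}
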