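# Readers and writers: PDB structures (via bio3d), multi-model PDB and
# compact CSV trajectories, OpenDX density maps, YAML run configuration and
# CSV result tables.  All coordinates are in Angstrom and all energies in
# kJ/mol; CSV files carry a '#' comment header with the package version and
# seed so reruns are traceable (and byte-identical for equal seeds).

water_resids <- c("HOH", "WAT", "SOL")

#' Read host sites and waters from a PDB file
#'
#' Waters are identified by residue name (HOH/WAT/SOL); everything else is a
#' host atom.  1-based PDB serials map to the row order of the returned
#' tables; B-factors are retained for reporting.
#'
#' @param path PDB file.
#' @return list with `host` (data frame `x, y, z, elety, resid, b`),
#'   `water_xyz` (matrix of water oxygen coordinates), `water_b`
#'   (B-factors of those oxygens).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path)
  is_w <- at$resid %in% water_resids
  is_o <- is_w & startsWith(trimws(at$elety), "O")
  host <- at[!is_w, , drop = FALSE]
  list(
    host = data.frame(x = host$x, y = host$y, z = host$z,
                      elety = host$elety, resid = host$resid, b = host$b,
                      stringsAsFactors = FALSE),
    water_xyz = as.matrix(at[is_o, c("x", "y", "z")]),
    water_b = at$b[is_o]
  )
}

#' Read crystal-water oxygen coordinates from a PDB file
#' @param path PDB file with water HETATM records (HOH/WAT/SOL).
#' @return `m x 3` matrix of oxygen coordinates.
#' @export
read_crystal_waters <- function(path) {
  s <- read_structure(path)
  if (nrow(s$water_xyz) == 0) stop("no water records in ", path)
  s$water_xyz
}

#' Write cluster centroids as a PDB file
#'
#' One pseudo-atom (HETATM, resid HOH) per cluster centroid; the occupancy
#' column carries the cluster occupancy.
#'
#' @param set a [cluster_waters()] result.
#' @param path output path.
#' @export
write_cluster_pdb <- function(set, path) {
  cl <- set$clusters
  n <- nrow(cl)
  if (n == 0) {
    writeLines(c("REMARK   empty water cluster set", "END"), path)
    return(invisible(path))
  }
  xyz <- as.vector(t(as.matrix(cl[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("HETATM", n),
                   resno = seq_len(n), resid = rep("HOH", n),
                   eleno = seq_len(n), elety = rep("O", n),
                   o = round(cl$occupancy, 2), b = rep(0, n))
  invisible(path)
}

#' Write water frames as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, one HOH oxygen ATOM record per water.
#' Frames may have different water counts (grand-canonical trajectories).
#' Orientations cannot be carried by the PDB format; use
#' [write_frames_csv()] for a lossless encoding.
#'
#' @param frames list of frames (lists with `positions`), e.g.
#'   `gc_trace$frames` or `gist_frames$frames`.
#' @param path output path.
#' @export
write_frames_pdb <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", fi), con)
    X <- frames[[fi]]$positions
    if (!is.null(X) && nrow(X)) {
      for (i in seq_len(nrow(X))) {
        writeLines(sprintf(
          "ATOM  %5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
          i, i, X[i, 1], X[i, 2], X[i, 3], 1, 0), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB of water frames
#'
#' Fixed-column parser for MODEL/ENDMDL blocks with possibly varying atom
#' counts per frame (which rules out fixed-topology trajectory readers).
#'
#' @param path multi-model PDB file.
#' @return list of frames, each a list with `positions` (n x 3 matrix).
#' @export
read_frames_pdb <- function(path) {
  lines <- readLines(path)
  frames <- list()
  cur <- NULL
  for (li in seq_along(lines)) {
    ln <- lines[li]
    tag <- substr(ln, 1, 6)
    if (startsWith(ln, "MODEL")) {
      cur <- list()
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (any(is.na(c(x, y, z)))) {
        stop("malformed ATOM record at line ", li, " of ", path)
      }
      cur[[length(cur) + 1]] <- c(x, y, z)
    } else if (startsWith(ln, "ENDMDL")) {
      X <- if (length(cur)) do.call(rbind, cur) else matrix(numeric(0), 0, 3)
      frames[[length(frames) + 1]] <- list(positions = X)
      cur <- NULL
    }
  }
  if (!length(frames)) stop("no MODEL blocks in ", path)
  frames
}

csv_header <- function(seed = NA) {
  c(sprintf("# waternet %s",
            as.character(utils::packageVersion("waternet"))),
    if (!is.na(seed)) sprintf("# seed %s", format(seed)) else "# seed NA",
    "# units: lengths A, energies kJ/mol, temperatures K")
}

#' Write water frames to the compact CSV trajectory format
#'
#' Columns: `frame, water, x, y, z, qw, qx, qy, qz`.  This is the package's
#' lossless trajectory encoding (PDB cannot carry quaternions).
#'
#' @param frames list of frames with `positions` and `orientations`.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @export
write_frames_csv <- function(frames, path, seed = NA) {
  rows <- lapply(seq_along(frames), function(fi) {
    f <- frames[[fi]]
    n <- nrow(f$positions)
    if (n == 0) return(NULL)
    data.frame(frame = fi, water = seq_len(n),
               x = f$positions[, 1], y = f$positions[, 2],
               z = f$positions[, 3],
               qw = f$orientations[, 1], qx = f$orientations[, 2],
               qy = f$orientations[, 3], qz = f$orientations[, 4])
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header(seed), con)
  if (is.null(df)) {
    writeLines("frame,water,x,y,z,qw,qx,qy,qz", con)
  } else {
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read the compact CSV trajectory format
#'
#' @param path CSV written by [write_frames_csv()].
#' @param n_frames optional total frame count (trailing empty frames cannot
#'   be inferred from the data rows).
#' @return list of frames with `positions` and `orientations`.
#' @export
read_frames_csv <- function(path, n_frames = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(n_frames)) n_frames <- if (nrow(df)) max(df$frame) else 0
  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    d <- df[df$frame == fi, , drop = FALSE]
    frames[[fi]] <- list(
      positions = matrix(as.numeric(as.matrix(d[, c("x", "y", "z")])),
                         ncol = 3),
      orientations = matrix(as.numeric(as.matrix(d[, c("qw", "qx", "qy", "qz")])),
                            ncol = 4)
    )
  }
  frames
}

#' Write a scalar field in OpenDX format
#'
#' @param values numeric vector in the package's x-fastest linear voxel
#'   order, or a `gist_map` (in which case `grid` is taken from it).
#' @param grid a [gist_grid()] (ignored when `values` is a `gist_map`).
#' @param path output path.
#' @export
write_dx <- function(values, grid = NULL, path) {
  if (inherits(values, "gist_map")) {
    grid <- values$grid
    values <- values$values
  }
  stopifnot(inherits(grid, "gist_grid"),
            length(values) == prod(grid$dims))
  d <- grid$dims; h <- grid$spacing; o <- grid$origin
  arr <- array(values, dim = d)
  vc <- as.vector(aperm(arr, c(3, 2, 1)))   # C order: z fastest
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0.000000 0.000000", h),
    sprintf("delta 0.000000 %.6f 0.000000", h),
    sprintf("delta 0.000000 0.000000 %.6f", h),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vc))
  ), con)
  n3 <- (length(vc) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vc[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.8g %.8g %.8g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vc)) {
    writeLines(paste(sprintf("%.8g", vc[(n3 + 1):length(vc)]),
                     collapse = " "), con)
  }
  writeLines(c('attribute "dep" string "positions"',
               'object "field" class field'), con)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' @param path DX file written by [write_dx()] (or another C-ordered
#'   regular-grid DX writer with diagonal deltas).
#' @return list with `grid` (a [gist_grid()]) and `values` (x-fastest
#'   linear order).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(utils::tail(strsplit(gp, "[[:space:]]+")[[1]], 3))
  ol <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(ol, "[[:space:]]+")[[1]][2:4])
  dl <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(dl, function(s) {
    as.numeric(strsplit(s, "[[:space:]]+")[[1]][2:4])
  }, numeric(3)))
  dimnames(deltas) <- NULL
  spacing <- deltas[1, 1]
  if (any(abs(deltas - diag(rep(spacing, 3))) > 1e-9)) {
    stop("only cubic diagonal DX grids are supported")
  }
  i0 <- grep("data follows", lines)[1]
  iend <- grep("^attribute|^object \"", lines)
  iend <- iend[iend > i0]
  iend <- if (length(iend)) min(iend) - 1 else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):iend]),
                                     "[[:space:]]+")))
  vals <- vals[!is.na(vals)]
  stopifnot(length(vals) == prod(dims))
  arr <- array(vals, dim = rev(dims))          # read back C order
  values <- as.vector(aperm(arr, c(3, 2, 1)))  # to x-fastest
  list(grid = gist_grid(origin, spacing, dims), values = values)
}

run_config_defaults <- function() {
  list(
    seed = 1,
    sampler = list(B_values = numeric(0), n_moves = 20000,
                   record_every = 20, max_translation = 0.3,
                   discard_fraction = 0.2),
    thermo = list(T = 300, mu_ex = -25.9, V_std = 30),
    grid = list(origin = c(0, 0, 0), spacing = 0.5, dims = c(10, 10, 10)),
    analysis = list(cluster_cutoff = 2.4, match_dist = 1.4,
                    occupancy_min = 0.3,
                    recovery_thresholds = seq(0, 2, by = 0.1),
                    subsample_every = 1, pairing_dist = 1.0),
    out_prefix = "waternet"
  )
}

check_config_keys <- function(cfg, ref, path = "") {
  for (k in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(ref)) stop("unknown configuration key: ", here)
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) stop("expected a mapping at ", here)
      check_config_keys(cfg[[k]], ref[[k]], here)
    }
  }
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected with their location; absent keys take the
#' documented defaults (cluster cutoff 2.4 A, agreement distance 1.4 A,
#' occupancy threshold 0.3, recovery thresholds 0-2 A, grid spacing 0.5 A).
#'
#' @param path YAML file.
#' @return a fully populated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- run_config_defaults()
  check_config_keys(cfg, ref)
  merged <- utils::modifyList(ref, cfg)
  # YAML sequences arrive as lists; the numeric-vector fields are flattened
  merged$sampler$B_values <- as.numeric(unlist(merged$sampler$B_values))
  merged$grid$origin <- as.numeric(unlist(merged$grid$origin))
  merged$grid$dims <- as.numeric(unlist(merged$grid$dims))
  merged$analysis$recovery_thresholds <-
    as.numeric(unlist(merged$analysis$recovery_thresholds))
  with(merged, {
    stopifnot(thermo$T > 0, grid$spacing > 0, all(grid$dims >= 1),
              analysis$cluster_cutoff > 0, analysis$match_dist >= 0,
              analysis$occupancy_min >= 0, analysis$occupancy_min <= 1,
              all(diff(analysis$recovery_thresholds) >= 0),
              sampler$discard_fraction >= 0, sampler$discard_fraction < 1)
  })
  merged
}

#' Serialise a run configuration to YAML
#' @param config configuration list.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write the N-trace and acceptance counters of a GCMC run as CSV
#' @param trace a `gc_trace`.
#' @param path output path.
#' @export
write_gcmc_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header(trace$seed), con)
  writeLines(sprintf("# B %.8g T %.8g", trace$params$B, trace$params$T), con)
  utils::write.csv(trace$records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a titration curve as CSV
#' @param curve a `titration_curve`.
#' @param path output path.
#' @export
write_titration_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header(if (length(curve$seeds)) curve$seeds[1] else NA), con)
  writeLines(sprintf("# T %.8g B_equil %.8g", curve$T, curve$B_equil), con)
  utils::write.csv(curve$points, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a free-energy profile as CSV
#' @param profile a `free_energy_profile`.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header(NA), con)
  writeLines(sprintf("# optimal_N %d dG_min %.8g N_at_Bequil %.8g",
                     profile$optimal_N, profile$dG_min, profile$N_at_Bequil),
             con)
  utils::write.csv(profile$profile, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
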