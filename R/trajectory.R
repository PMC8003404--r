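# Trajectory container and periodic-boundary coordinate handling. A
# trajectory is a frames x particles x 3 array of positions (nm) on a
# uniform time grid (ps) in a cubic periodic box.

#' Particle trajectory in a periodic cubic box
#'
#' @param positions numeric array `[frames, particles, 3]`, nm.
#' @param box_side cubic box edge length L, nm.
#' @param dt frame spacing, ps (alternative to `times`).
#' @param times explicit uniformly spaced frame times, ps.
#' @param wrapped logical: are coordinates folded into `[0, L)`?
#' @param species species label carried through the analysis.
#' @param d_true optional known ground-truth diffusion coefficient,
#'   m^2 s^-1 (synthetic data only).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(positions, box_side, dt = NULL, times = NULL,
                       wrapped = FALSE, species = "", d_true = NULL) {
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3)
    stop("positions must be a frames x particles x 3 array")
  n_frames <- dim(positions)[1]
  if (n_frames < 2) stop("at least two frames required")
  if (dim(positions)[2] < 1) stop("at least one particle required")
  if (is.null(times)) {
    if (is.null(dt) || dt <= 0) stop("supply times or a positive dt")
    times <- (seq_len(n_frames) - 1) * dt
  }
  if (length(times) != n_frames) stop("times must match the frame count")
  steps <- diff(times)
  if (any(steps <= 0) || diff(range(steps)) > 1e-9 * max(steps))
    stop("times must be strictly increasing with constant spacing")
  if (box_side <= 0) stop("box_side must be positive")
  if (wrapped && (min(positions) < 0 || max(positions) >= box_side))
    stop("wrapped trajectory has coordinates outside [0, box_side)")
  structure(list(times = as.numeric(times), positions = positions,
                 box_side = box_side, wrapped = isTRUE(wrapped),
                 species = species, d_true = d_true),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory%s: %d frames x %d particles, dt = %g ps, L = %.3f nm (%s)\n",
    if (nzchar(x$species)) paste0(" [", x$species, "]") else "",
    dim(x$positions)[1], dim(x$positions)[2], x$times[2] - x$times[1],
    x$box_side, if (x$wrapped) "wrapped" else "unwrapped"))
  if (!is.null(x$d_true))
    cat(sprintf("  known d_true = %.3g m^2/s\n", x$d_true))
  invisible(x)
}

#' Number of frames / particles of a trajectory
#' @param traj a [trajectory()].
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$positions)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$positions)[2]

#' Fold trajectory coordinates into the primary box
#'
#' @param traj a [trajectory()].
#' @return wrapped trajectory; the input coordinates are retained in the
#'   `"unwrapped"` attribute when the input was unwrapped.
#' @export
wrap_trajectory <- function(traj) {
  if (traj$wrapped) return(traj)
  out <- traj
  out$positions <- traj$positions %% traj$box_side
  out$wrapped <- TRUE
  attr(out, "unwrapped") <- traj$positions
  out
}

#' Reconstruct continuous coordinates from a wrapped trajectory
#'
#' Accumulates minimum-image frame-to-frame displacements, so the result is
#' continuous up to a global integer number of box lengths per particle.
#' Valid only while true per-frame displacements stay below half the box
#' side; displacements at that limit are ambiguous and are reported.
#'
#' @param traj a wrapped [trajectory()]; unwrapped input is returned as is.
#' @param on_ambiguity `"warn"`, `"error"` or `"ignore"` when a
#'   minimum-image displacement component reaches box_side/2.
#' @return unwrapped trajectory.
#' @export
unwrap_trajectory <- function(traj,
                              on_ambiguity = c("warn", "error", "ignore")) {
  on_ambiguity <- match.arg(on_ambiguity)
  if (!traj$wrapped) return(traj)
  L <- traj$box_side
  pos <- traj$positions
  nf <- dim(pos)[1]
  d <- pos[-1, , , drop = FALSE] - pos[-nf, , , drop = FALSE]
  d <- d - L * round(d / L)
  if (any(abs(d) >= L / 2 * 0.999999)) {
    msg <- "frame-to-frame displacement at half the box side: unwrapping is ambiguous (frames too far apart?)"
    if (on_ambiguity == "error") stop(msg)
    if (on_ambiguity == "warn") warning(msg)
  }
  out <- traj
  for (k in 1:3) {
    first <- pos[1, , k]
    out$positions[, , k] <- rbind(first,
                                  sweep(apply(d[, , k, drop = FALSE], 2,
                                              cumsum), 2, first, "+"))
  }
  # drop dimnames introduced by rbind/apply
  dimnames(out$positions) <- NULL
  out$wrapped <- FALSE
  out
}

#' Write a trajectory as a TSV frame table with a JSON metadata sidecar
#'
#' Columns: frame, time_ps, particle_id, x_nm, y_nm, z_nm. The sidecar
#' records box_side, dt, wrapped flag, species, d_true and seed (when
#' known), so a synthetic run is fully reproducible from its files.
#'
#' @param traj a [trajectory()].
#' @param path TSV output path.
#' @param metadata_path sidecar path (default `path` + `.json`).
#' @export
write_trajectory_tsv <- function(traj, path,
                                 metadata_path = paste0(path, ".json")) {
  nf <- n_frames(traj); np <- n_particles(traj)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = np),
    time_ps = rep(traj$times, each = np),
    particle_id = rep(seq_len(np), nf),
    x_nm = as.vector(t(traj$positions[, , 1])),
    y_nm = as.vector(t(traj$positions[, , 2])),
    z_nm = as.vector(t(traj$positions[, , 3])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(box_side_nm = traj$box_side,
               dt_ps = traj$times[2] - traj$times[1],
               n_frames = nf, n_particles = np, wrapped = traj$wrapped,
               species = traj$species)
  if (!is.null(traj$d_true)) meta$d_true_m2s <- traj$d_true
  if (!is.null(attr(traj, "seed"))) meta$seed <- attr(traj, "seed")
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory from a TSV frame table
#'
#' @param path TSV written by [write_trajectory_tsv()].
#' @param metadata_path JSON sidecar path.
#' @return a [trajectory()].
#' @export
read_trajectory_tsv <- function(path, metadata_path = paste0(path, ".json")) {
  df <- utils::read.delim(path)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  nf <- meta$n_frames; np <- meta$n_particles
  ord <- order(df$frame, df$particle_id)
  df <- df[ord, ]
  pos <- array(NA_real_, c(nf, np, 3))
  pos[, , 1] <- t(matrix(df$x_nm, np, nf))
  pos[, , 2] <- t(matrix(df$y_nm, np, nf))
  pos[, , 3] <- t(matrix(df$z_nm, np, nf))
  trajectory(pos, box_side = meta$box_side_nm,
             times = unique(df$time_ps), wrapped = isTRUE(meta$wrapped),
             species = meta$species %||% "",
             d_true = meta$d_true_m2s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a structure or trajectory in GRO format
#'
#' Fixed-column GROMACS text format (nm units, cubic box vector on the last
#' line). For a trajectory one concatenated frame block per stored time is
#' written, with the time in the title line.
#'
#' @param x a `box_structure` or [trajectory()].
#' @param path output file.
#' @param title title line text.
#' @export
write_gro <- function(x, path, title = "fizzdiff") {
  if (inherits(x, "box_structure")) {
    writeLines(gro_frame_lines(x$atoms, x$box_side, title), path)
  } else if (inherits(x, "trajectory")) {
    np <- n_particles(x)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(n_frames(x))) {
      atoms <- data.frame(mol_id = seq_len(np), resname = "PRT",
                          atom = "COM", element = "X",
                          x = x$positions[f, , 1], y = x$positions[f, , 2],
                          z = x$positions[f, , 3])
      writeLines(gro_frame_lines(atoms, x$box_side,
                                 sprintf("%s t= %.3f", title, x$times[f])),
                 con)
    }
  } else stop("write_gro handles box_structure or trajectory objects")
  invisible(path)
}

gro_frame_lines <- function(atoms, box_side, title) {
  n <- nrow(atoms)
  c(title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            atoms$mol_id %% 100000L, substr(atoms$resname, 1, 5),
            substr(atoms$atom, 1, 5), seq_len(n) %% 100000L,
            atoms$x, atoms$y, atoms$z),
    sprintf("%10.5f%10.5f%10.5f", box_side, box_side, box_side))
}

#' Read a (multi-frame) GRO file
#'
#' @param path GRO file.
#' @return for a single frame, a list with `atoms` and `box_side`; for a
#'   multi-frame file, a [trajectory()] built from the per-frame atom
#'   positions (times parsed from `t=` in the title lines, else frame
#'   index).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); i <- 1
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    title <- lines[i]
    n <- as.integer(trimws(lines[i + 1]))
    rec <- lines[(i + 2):(i + 1 + n)]
    atoms <- data.frame(
      mol_id = as.integer(substr(rec, 1, 5)),
      resname = trimws(substr(rec, 6, 10)),
      atom = trimws(substr(rec, 11, 15)),
      x = as.numeric(substr(rec, 21, 28)),
      y = as.numeric(substr(rec, 29, 36)),
      z = as.numeric(substr(rec, 37, 44)))
    box <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]])[1]
    tm <- regmatches(title, regexpr("t= *([-0-9.eE+]+)", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm))
               else length(frames))
    frames[[length(frames) + 1]] <- list(atoms = atoms, box = box)
    i <- i + 3 + n
  }
  if (length(frames) == 1)
    return(list(atoms = frames[[1]]$atoms, box_side = frames[[1]]$box))
  np <- nrow(frames[[1]]$atoms)
  pos <- array(NA_real_, c(length(frames), np, 3))
  for (f in seq_along(frames)) {
    pos[f, , 1] <- frames[[f]]$atoms$x
    pos[f, , 2] <- frames[[f]]$atoms$y
    pos[f, , 3] <- frames[[f]]$atoms$z
  }
  trajectory(pos, box_side = frames[[1]]$box, times = times,
             wrapped = min(pos) >= 0 && max(pos) < frames[[1]]$box)
}
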