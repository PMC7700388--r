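#' In-memory multi-frame coordinate trajectory
#'
#' A `memtraj` object holds an ordered sequence of frames sharing one atom
#' table. Coordinates are stored in nanometres in an `n_atoms x 3 x n_frames`
#' array; each frame carries an orthorhombic box (edge lengths, nm) and a
#' time stamp in picoseconds.
#'
#' @param atoms data.frame with columns `index` (unique integer), `name`
#'   (atom name, e.g. `"P"`, `"CA"`), `resno` (residue number), `resname`
#'   (residue name) and `segid` (segment identifier, may be `""`).
#' @param xyz numeric array `n_atoms x 3 x n_frames` (nm). A plain
#'   `n_atoms x 3` matrix is promoted to a single frame.
#' @param box numeric `n_frames x 3` matrix of box edge lengths (nm); a
#'   length-3 vector is recycled over frames.
#' @param time numeric vector of frame times (ps); defaults to `0, 1, 2, ...`.
#' @return An object of class `memtraj`.
#' @export
memtraj <- function(atoms, xyz, box, time = NULL) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), ncol(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  n_at <- dim(xyz)[1]
  n_fr <- dim(xyz)[3]
  req <- c("index", "name", "resno", "resname", "segid")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) != n_at)
    stop("atom table has ", nrow(atoms), " rows but coordinates have ",
         n_at, " atoms")
  if (anyDuplicated(atoms$index))
    stop("atom indices must be unique within a frame")
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  if (is.vector(box) && length(box) == 3L)
    box <- matrix(box, nrow = n_fr, ncol = 3L, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != n_fr || ncol(box) != 3L)
    stop("box must be an n_frames x 3 matrix of edge lengths")
  if (any(box <= 0))
    stop("box edge lengths must be positive")
  if (is.null(time)) time <- seq_len(n_fr) - 1
  if (length(time) != n_fr)
    stop("time vector length must equal the number of frames")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$index <- as.integer(atoms$index)
  atoms$resno <- as.integer(atoms$resno)
  structure(
    list(atoms = atoms, xyz = xyz, box = box, time = as.numeric(time)),
    class = "memtraj")
}

#' @export
print.memtraj <- function(x, ...) {
  cat("memtraj: ", n_frames(x), " frame(s), ", n_atoms(x), " atoms\n", sep = "")
  cat("  box (frame 1): ",
      paste(sprintf("%.3f", x$box[1, ]), collapse = " x "), " nm\n", sep = "")
  cat("  time: ", x$time[1], " .. ", x$time[n_frames(x)], " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `memtraj`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Number of atoms in a trajectory
#' @param traj a `memtraj`
#' @return integer atom count
#' @export
n_atoms <- function(traj) dim(traj$xyz)[1]

#' Extract the coordinate matrix of one frame
#' @param traj a `memtraj`
#' @param i frame index (1-based)
#' @return `n_atoms x 3` matrix, nm
#' @export
frame_xyz <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$xyz[, , i, drop = TRUE]
}

#' Subset a trajectory to a window of frames
#' @param traj a `memtraj`
#' @param frames integer vector of frame indices to keep
#' @return a `memtraj` with the selected frames, in the given order
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(all(frames >= 1), all(frames <= n_frames(traj)))
  memtraj(traj$atoms, traj$xyz[, , frames, drop = FALSE],
          traj$box[frames, , drop = FALSE], traj$time[frames])
}

#' Frame indices of the analysis window
#'
#' Production trajectories are analysed over their final portion once the
#' system has relaxed; the conventional default is the last half of the run.
#'
#' @param traj a `memtraj`
#' @param window_fraction fraction of frames, taken from the end, in (0, 1]
#' @return integer vector of frame indices
#' @export
analysis_window <- function(traj, window_fraction = 0.5) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  nf <- n_frames(traj)
  n_keep <- max(1L, ceiling(nf * window_fraction))
  seq.int(nf - n_keep + 1L, nf)
}
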