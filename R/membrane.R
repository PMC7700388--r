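#' Assign lipid head groups to leaflets
#'
#' Splits the phosphorus atoms at the median of their z coordinates, which
#' stays correct if the bilayer drifts away from the box centre. The bilayer
#' centre `center_z` is the mean z of all phosphorus atoms and the normal is
#' fixed to +z.
#'
#' @param xyz `n_atoms x 3` coordinate matrix of one frame (nm)
#' @param lipid_idx atom row indices of the phospholipid phosphorus atoms
#' @param amphiphile_idx atom rows counting one particle per amphiphile
#'   (phospholipid or sterol); defaults to `lipid_idx`. Its per-leaflet count
#'   is the area-per-lipid denominator.
#' @return list of class `membrane_frame`: `upper_P`, `lower_P` (atom index
#'   sets), `center_z` (nm), `normal`, `n_lipids_per_leaflet`
#' @export
assign_leaflets <- function(xyz, lipid_idx, amphiphile_idx = lipid_idx) {
  if (length(lipid_idx) < 2)
    stop("leaflet assignment needs at least 2 phosphorus atoms")
  z <- xyz[lipid_idx, 3]
  med <- stats::median(z)
  upper <- lipid_idx[z > med]
  lower <- lipid_idx[z <= med]
  if (!length(upper) || !length(lower) ||
      mean(xyz[upper, 3]) - mean(xyz[lower, 3]) < 1e-9)
    stop("degenerate bilayer: phosphorus atoms do not form two leaflets")
  za <- xyz[amphiphile_idx, 3]
  n_per_leaflet <- max(sum(za > stats::median(za)),
                       sum(za <= stats::median(za)))
  # a symmetric bilayer has equal halves; keep the larger count if odd
  structure(list(upper_P = upper, lower_P = lower,
                 center_z = mean(z), normal = c(0, 0, 1),
                 n_lipids_per_leaflet = as.integer(n_per_leaflet)),
            class = "membrane_frame")
}

#' Area per lipid of one frame
#'
#' Lateral box area divided by the number of amphiphiles in one leaflet
#' (phospholipids and sterols both count: a membrane with sterol present
#' reports a single condensed area, not a per-species decomposition).
#'
#' @param box length-3 box edge vector (nm)
#' @param mf a `membrane_frame` from [assign_leaflets()]
#' @return area per lipid, nm^2
#' @export
area_per_lipid <- function(box, mf) {
  n <- mf$n_lipids_per_leaflet
  if (is.null(n) || n < 1) stop("no amphiphiles in leaflet")
  box[1] * box[2] / n
}

#' Bilayer thickness of one frame
#'
#' Mean separation along the normal between the phosphorus atoms of the two
#' leaflets: `mean z(upper) - mean z(lower)`.
#'
#' @param xyz `n_atoms x 3` coordinate matrix (nm)
#' @param mf a `membrane_frame`
#' @return thickness, nm
#' @export
bilayer_thickness <- function(xyz, mf) {
  if (!length(mf$upper_P) || !length(mf$lower_P))
    stop("empty leaflet: cannot compute thickness")
  mean(xyz[mf$upper_P, 3]) - mean(xyz[mf$lower_P, 3])
}

#' Percent change of a value relative to a reference
#'
#' `100 * (reference - value) / reference`, the convention used to report
#' e.g. sterol condensation of the area per lipid ("decreased by X%").
#' Returns the unrounded percentage, the integer percent used for reporting,
#' and the plain difference `reference - value`.
#'
#' @param reference reference value (> 0)
#' @param value compared value
#' @return list: `percent`, `percent_rounded`, `difference`
#' @export
percent_change <- function(reference, value) {
  if (!is.finite(reference) || reference <= 0)
    stop("reference must be a positive finite number")
  pct <- 100 * (reference - value) / reference
  list(percent = pct, percent_rounded = round(pct),
       difference = reference - value)
}

#' Per-frame bilayer metrics over an analysis window
#'
#' @param traj a [memtraj]
#' @param config selection config; needs roles `lipid_P` and (optionally)
#'   `amphiphile`
#' @param window_fraction final fraction of frames analysed (default 0.5)
#' @return data.frame of class `bilayer_metrics`: `frame`, `time`,
#'   `area_per_lipid` (nm^2), `thickness` (nm), `center_z` (nm)
#' @export
bilayer_metrics <- function(traj, config = selection_defaults(),
                            window_fraction = 0.5) {
  win <- analysis_window(traj, window_fraction)
  lipid_idx <- resolve_selection(traj, "lipid_P", config)
  amph_idx <- if (!is.null(config$roles$amphiphile))
    resolve_selection(traj, "amphiphile", config) else lipid_idx
  out <- lapply(win, function(f) {
    m <- frame_xyz(traj, f)
    mf <- assign_leaflets(m, lipid_idx, amph_idx)
    data.frame(frame = f, time = traj$time[f],
               area_per_lipid = area_per_lipid(traj$box[f, ], mf),
               thickness = bilayer_thickness(m, mf),
               center_z = mf$center_z)
  })
  res <- do.call(rbind, out)
  class(res) <- c("bilayer_metrics", class(res))
  res
}

#' Time average with block-averaged standard error
#'
#' Molecular-dynamics series are serially correlated, so the naive standard
#' error of the mean underestimates the true uncertainty. The series is cut
#' into contiguous blocks; the reported error is the standard error of the
#' block means, which converges to the correct value once blocks exceed the
#' correlation time.
#'
#' @param x numeric series (per-frame values)
#' @param n_blocks number of contiguous blocks (default 10)
#' @return list: `mean`, `se` (block standard error), `n_blocks`,
#'   `block_length`
#' @export
block_average <- function(x, n_blocks = 10) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 * n_blocks)
    stop("series too short: need at least 2 frames per block (",
         n, " frames, ", n_blocks, " blocks)")
  bl <- n %/% n_blocks
  use <- x[seq_len(bl * n_blocks)]       # drop the ragged tail
  bm <- colMeans(matrix(use, nrow = bl))
  list(mean = mean(x), se = stats::sd(bm) / sqrt(n_blocks),
       n_blocks = n_blocks, block_length = bl)
}

#' Summary table of bilayer metrics
#'
#' @param metrics output of [bilayer_metrics()]
#' @param n_blocks blocks for the error estimate (default 10)
#' @return data.frame with one row per quantity: `quantity`, `mean`, `se`
#' @export
summarize_metrics <- function(metrics, n_blocks = 10) {
  a <- block_average(metrics$area_per_lipid, n_blocks)
  t <- block_average(metrics$thickness, n_blocks)
  data.frame(quantity = c("area_per_lipid_nm2", "thickness_nm"),
             mean = c(a$mean, t$mean), se = c(a$se, t$se))
}
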