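#' Insertion-depth series of a moiety
#'
#' Per frame, the signed distance along the membrane normal between the
#' unweighted geometric centre of the selected moiety atoms (e.g. the
#' farnesyl anchor or the bound GTP) and the bilayer centre. The sign
#' convention is positive toward the protein-bearing leaflet: if the mean
#' raw depth over the window is negative the whole series is flipped.
#' "Preferred localisations" are the modes (local maxima) of the 1D depth
#' histogram at 0.1 nm resolution.
#'
#' @param traj a [memtraj]
#' @param moiety_idx atom rows of the moiety
#' @param lipid_idx atom rows of the phosphorus atoms (bilayer centre)
#' @param window_fraction final fraction of frames analysed
#' @param bin_width histogram bin width, nm (default 0.1)
#' @return list of class `depth_series`: `frame`, `time`, `depth` (nm),
#'   `mean`, `modes` (bin centres of local maxima, by decreasing occupancy),
#'   `bin_width`
#' @export
depth_series <- function(traj, moiety_idx, lipid_idx,
                         window_fraction = 0.5, bin_width = 0.1) {
  if (!length(moiety_idx)) stop("empty moiety selection")
  if (length(lipid_idx) < 2) stop("need phosphorus atoms for bilayer centre")
  win <- analysis_window(traj, window_fraction)
  depth <- vapply(win, function(f) {
    m <- frame_xyz(traj, f)
    mean(m[moiety_idx, 3]) - mean(m[lipid_idx, 3])
  }, numeric(1))
  if (mean(depth) < 0) depth <- -depth
  structure(list(frame = win, time = traj$time[win], depth = depth,
                 mean = mean(depth),
                 modes = histogram_modes(depth, bin_width),
                 bin_width = bin_width),
            class = "depth_series")
}

# Local maxima of a fixed-width histogram, ordered by decreasing count.
histogram_modes <- function(x, bin_width) {
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi - lo < bin_width) hi <- lo + bin_width
  br <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  cts <- h$counts
  n <- length(cts)
  left <- c(-Inf, cts[-n]); right <- c(cts[-1], -Inf)
  is_max <- cts > 0 & cts >= left & cts >= right & (cts > left | cts > right)
  if (!any(is_max)) is_max[which.max(cts)] <- TRUE
  ord <- order(cts[is_max], decreasing = TRUE)
  h$mids[is_max][ord]
}

#' @export
print.depth_series <- function(x, ...) {
  cat("depth_series: ", length(x$depth), " frames, mean ",
      sprintf("%.3f", x$mean), " nm\n", sep = "")
  cat("  preferred localisations (nm): ",
      paste(sprintf("%.2f", utils::head(x$modes, 3)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' RMSD time series of the 5-aa HVR motif
#'
#' Per frame, the motif atoms are optimally superposed onto the same atoms
#' of the reference frame (Kabsch) and the RMSD of the fitted coordinates is
#' reported, so only internal conformational change - not rigid-body motion -
#' contributes. The default reference is the first frame of the analysis
#' window.
#'
#' @param traj a [memtraj]
#' @param motif_idx atom rows of the motif (same atoms in every frame)
#' @param window_fraction final fraction of frames analysed
#' @param reference_frame frame index of the reference structure; default
#'   first frame of the window
#' @return list of class `rmsd_series`: `frame`, `time`, `rmsd` (nm),
#'   `reference_frame`
#' @export
hvr_rmsd_series <- function(traj, motif_idx, window_fraction = 0.5,
                            reference_frame = NULL) {
  if (length(motif_idx) < 3)
    stop("motif selection must contain at least 3 atoms")
  win <- analysis_window(traj, window_fraction)
  if (is.null(reference_frame)) reference_frame <- win[1]
  ref <- frame_xyz(traj, reference_frame)[motif_idx, , drop = FALSE]
  vals <- vapply(win, function(f) {
    kabsch_superpose(frame_xyz(traj, f)[motif_idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  structure(list(frame = win, time = traj$time[win], rmsd = vals,
                 reference_frame = reference_frame),
            class = "rmsd_series")
}

#' Radial distribution function under periodic boundaries
#'
#' g(r) between two selections, averaged over frames. Distances use the
#' minimum-image convention in the orthorhombic box; counts in each shell
#' are normalised by the ideal-gas expectation `N_A * rho_B * 4 pi r^2 dr`
#' per frame, with `rho_B = N_B / V` for distinct selections and
#' `(N_B - 1) / V` when the selections are identical (self-pairs excluded).
#'
#' @param traj a [memtraj]
#' @param sel_a,sel_b atom row indices of the two selections
#' @param r_max maximum distance, nm; must not exceed half the smallest box
#'   edge
#' @param dr bin width, nm (default 0.05)
#' @param window_fraction final fraction of frames analysed (default 1: RDFs
#'   are often wanted over the whole trajectory)
#' @return list of class `rdf_result`: `r` (bin centres), `g`, `counts`
#'   (mean pair count per bin per frame), `r_max`, `dr`
#' @export
compute_rdf <- function(traj, sel_a, sel_b, r_max, dr = 0.05,
                        window_fraction = 1) {
  if (!length(sel_a) || !length(sel_b)) stop("empty RDF selection")
  win <- analysis_window(traj, window_fraction)
  if (r_max > min(traj$box[win, ]) / 2 + 1e-12)
    stop("r_max (", r_max, " nm) exceeds half the smallest box edge")
  same <- identical(sort(sel_a), sort(sel_b))
  n_bins <- ceiling(r_max / dr)
  edges <- seq(0, n_bins * dr, by = dr)
  acc_counts <- numeric(n_bins)
  acc_ideal <- numeric(n_bins)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  for (f in win) {
    m <- frame_xyz(traj, f)
    box <- traj$box[f, ]
    A <- m[sel_a, , drop = FALSE]
    B <- m[sel_b, , drop = FALSE]
    d <- pair_distances_pbc(A, B, box, exclude_self = same)
    d <- d[d < r_max]
    acc_counts <- acc_counts + tabulate(pmin(floor(d / dr) + 1L, n_bins),
                                        nbins = n_bins)
    V <- prod(box)
    rho_b <- (length(sel_b) - if (same) 1 else 0) / V
    acc_ideal <- acc_ideal + length(sel_a) * rho_b * shell_vol
  }
  g <- ifelse(acc_ideal > 0, acc_counts / acc_ideal, 0)
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                 counts = acc_counts / length(win), r_max = r_max, dr = dr,
                 n_frames = length(win)),
            class = "rdf_result")
}

# All A-B minimum-image distances; chunked over A to bound memory.
pair_distances_pbc <- function(A, B, box, exclude_self = FALSE) {
  nA <- nrow(A); nB <- nrow(B)
  chunk <- max(1L, floor(2e6 / nB))
  out <- vector("list", ceiling(nA / chunk))
  k <- 0L
  for (s in seq(1L, nA, by = chunk)) {
    e <- min(s + chunk - 1L, nA)
    idx <- s:e
    dx <- outer(A[idx, 1], B[, 1], "-")
    dy <- outer(A[idx, 2], B[, 2], "-")
    dz <- outer(A[idx, 3], B[, 3], "-")
    dx <- dx - box[1] * floor(dx / box[1] + 0.5)
    dy <- dy - box[2] * floor(dy / box[2] + 0.5)
    dz <- dz - box[3] * floor(dz / box[3] + 0.5)
    d2 <- dx * dx + dy * dy + dz * dz
    if (exclude_self) d2[cbind(seq_along(idx), idx)] <- Inf
    k <- k + 1L
    out[[k]] <- sqrt(d2[is.finite(d2)])
  }
  unlist(out, use.names = FALSE)
}
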