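#' Orientation-state region model
#'
#' Orientation states of membrane-bound KRas-4B are described in the
#' (z, cos Theta) plane, where z is the C-alpha 132 to C-alpha 183 distance
#' and Theta the tilt of the beta1-strand vector against the membrane
#' normal. Literature centres: OS1 (active, effector-binding loop exposed)
#' at (1.86 nm, -0.5); OS2 (occluded) at (4.97 nm, 1); OS0 (intermediate)
#' at (3.33 nm, 0.9). Only centres are published, so classification is
#' nearest-centre under per-axis normalisation; the scales default to a
#' plausible z span (5 nm) and the full cosine range (2).
#'
#' @param centers 3x2 matrix (rows OS1, OS0, OS2; columns z, cos_theta)
#' @param z_scale,cos_scale axis normalisation for the distance metric
#' @return list of class `os_region_model`
#' @export
os_region_model <- function(centers = rbind(OS1 = c(1.86, -0.5),
                                            OS0 = c(3.33, 0.9),
                                            OS2 = c(4.97, 1.0)),
                            z_scale = 5.0, cos_scale = 2.0) {
  stopifnot(nrow(centers) == 3, ncol(centers) == 2,
            z_scale > 0, cos_scale > 0,
            !anyDuplicated(centers))
  structure(list(centers = centers, z_scale = z_scale, cos_scale = cos_scale),
            class = "os_region_model")
}

#' Classify frames into orientation states
#'
#' Nearest-centre classification under the normalised Euclidean metric
#' `((dz / z_scale)^2 + (dcos / cos_scale)^2)`. Ties break deterministically
#' in the fixed order OS1, OS0, OS2.
#'
#' @param z order parameter z, nm (vectorised)
#' @param cos_theta cosine of the tilt angle (vectorised)
#' @param model an [os_region_model()]
#' @return character vector of labels `"OS1"`, `"OS0"`, `"OS2"`
#' @export
classify_os <- function(z, cos_theta, model = os_region_model()) {
  stopifnot(length(z) == length(cos_theta),
            all(is.finite(z)), all(is.finite(cos_theta)))
  cen <- model$centers[c("OS1", "OS0", "OS2"), , drop = FALSE]
  d2 <- sapply(seq_len(3), function(k)
    ((z - cen[k, 1]) / model$z_scale)^2 +
      ((cos_theta - cen[k, 2]) / model$cos_scale)^2)
  d2 <- matrix(d2, ncol = 3)
  rownames(cen)[max.col(-d2, ties.method = "first")]
}

#' Order parameter z: marker C-alpha separation
#'
#' Euclidean 3D distance between the two marker C-alpha atoms (residues 132
#' on lobe 2 and 183 on the HVR for KRas-4B). The protein must be whole
#' (unwrapped): no minimum-image convention is applied to this internal
#' vector. `mode = "projection"` instead returns the absolute projection of
#' the marker separation onto the membrane normal.
#'
#' @param xyz frame coordinate matrix (nm)
#' @param i_a,i_b atom row indices of the two markers
#' @param mode `"euclidean"` (default) or `"projection"`
#' @param normal membrane normal (projection mode only)
#' @return distance, nm
#' @export
order_parameter_z <- function(xyz, i_a, i_b,
                              mode = c("euclidean", "projection"),
                              normal = c(0, 0, 1)) {
  mode <- match.arg(mode)
  v <- xyz[i_b, ] - xyz[i_a, ]
  if (mode == "euclidean") sqrt(sum(v^2)) else abs(sum(v * normal))
}

#' Tilt angles of body-fixed vectors against the membrane normal
#'
#' `order_parameter_theta` measures the beta1-strand vector (C-alpha of
#' residue 5 to C-alpha of residue 9); `order_parameter_phi` the alpha5-helix
#' vector (C-alpha 156 to C-alpha 163). Both use the N-to-C direction along
#' the backbone; flipping a vector maps the angle to its supplement.
#'
#' @param xyz frame coordinate matrix (nm)
#' @param i_from,i_to atom rows of the vector tail and head
#' @param normal membrane normal, default +z
#' @return list `degrees`, `cosine`
#' @export
order_parameter_theta <- function(xyz, i_from, i_to, normal = c(0, 0, 1)) {
  v <- xyz[i_to, ] - xyz[i_from, ]
  if (sum(v^2) == 0) stop("coincident marker atoms")
  angle_to_normal(v, normal)
}

#' @rdname order_parameter_theta
#' @export
order_parameter_phi <- order_parameter_theta

#' Per-frame orientation records over an analysis window
#'
#' Computes (z, Theta, cos Theta, Phi) per frame from the marker C-alpha
#' atoms and classifies each frame into an orientation state.
#'
#' @param traj a [memtraj] (protein whole/unwrapped)
#' @param config selection config with a `ca_marker` role
#' @param markers named list of marker residue numbers; defaults
#'   `list(beta1 = c(5, 9), alpha5 = c(156, 163), z_pair = c(132, 183))`
#' @param window_fraction final fraction of frames analysed
#' @param z_mode `"euclidean"` or `"projection"` (see [order_parameter_z()])
#' @param model an [os_region_model()]
#' @return data.frame of class `orientation_records`: `frame`, `time`, `z`,
#'   `theta`, `cos_theta`, `phi`, `os`
#' @export
orientation_records <- function(traj, config = selection_defaults(),
                                markers = list(beta1 = c(5, 9),
                                               alpha5 = c(156, 163),
                                               z_pair = c(132, 183)),
                                window_fraction = 0.5,
                                z_mode = c("euclidean", "projection"),
                                model = os_region_model()) {
  z_mode <- match.arg(z_mode)
  win <- analysis_window(traj, window_fraction)
  get1 <- function(res) resolve_selection(traj, "ca_marker", config, res)
  i5 <- get1(markers$beta1[1]);  i9 <- get1(markers$beta1[2])
  i156 <- get1(markers$alpha5[1]); i163 <- get1(markers$alpha5[2])
  i132 <- get1(markers$z_pair[1]); i183 <- get1(markers$z_pair[2])
  n <- length(win)
  z <- theta <- ct <- phi <- numeric(n)
  for (k in seq_len(n)) {
    m <- frame_xyz(traj, win[k])
    z[k] <- order_parameter_z(m, i132, i183, mode = z_mode)
    th <- order_parameter_theta(m, i5, i9)
    theta[k] <- th$degrees; ct[k] <- th$cosine
    phi[k] <- order_parameter_phi(m, i156, i163)$degrees
  }
  res <- data.frame(frame = win, time = traj$time[win], z = z,
                    theta = theta, cos_theta = ct, phi = phi,
                    os = classify_os(z, ct, model),
                    stringsAsFactors = FALSE)
  class(res) <- c("orientation_records", class(res))
  res
}

#' Two-dimensional conformational density map
#'
#' Normalised 2D histogram over two reaction coordinates, with marginal
#' (relative-frequency) distributions and the modal bin. The axis range is
#' the data range padded by 5% on each side; degenerate (constant) axes are
#' widened symmetrically so a single value still occupies one bin.
#'
#' @param x,y coordinate vectors of equal length (e.g. `theta`, `phi`)
#' @param n_bins bins per axis (default 50)
#' @param x_range,y_range optional explicit axis limits `c(lo, hi)`
#' @return list of class `density_map2d`: `x_breaks`, `y_breaks`, `x_mid`,
#'   `y_mid`, `prob` (n_bins x n_bins, sums to 1), `marginal_x`,
#'   `marginal_y`, `mode` (c(x, y) bin centres; first maximal bin in
#'   column-major order on ties)
#' @export
density_map <- function(x, y, n_bins = 50, x_range = NULL, y_range = NULL) {
  stopifnot(length(x) == length(y))
  if (!length(x)) stop("density map needs at least one record")
  pad_range <- function(v, r) {
    if (!is.null(r)) return(r)
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-12) c(lo - 0.5, hi + 0.5)
    else c(lo - 0.05 * (hi - lo), hi + 0.05 * (hi - lo))
  }
  xr <- pad_range(x, x_range); yr <- pad_range(y, y_range)
  xb <- seq(xr[1], xr[2], length.out = n_bins + 1)
  yb <- seq(yr[1], yr[2], length.out = n_bins + 1)
  ix <- findInterval(x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(tabulate(ix + (iy - 1L) * n_bins, nbins = n_bins * n_bins),
                   n_bins, n_bins)
  prob <- counts / length(x)
  xm <- (xb[-1] + xb[-length(xb)]) / 2
  ym <- (yb[-1] + yb[-length(yb)]) / 2
  imax <- arrayInd(which.max(prob), dim(prob))
  structure(list(x_breaks = xb, y_breaks = yb, x_mid = xm, y_mid = ym,
                 prob = prob,
                 marginal_x = rowSums(prob), marginal_y = colSums(prob),
                 mode = c(xm[imax[1]], ym[imax[2]]), n = length(x)),
            class = "density_map2d")
}

#' @export
print.density_map2d <- function(x, ...) {
  cat("density_map2d: ", length(x$x_mid), "x", length(x$y_mid),
      " bins over ", x$n, " records\n", sep = "")
  cat(sprintf("  mode at (%.4g, %.4g)\n", x$mode[1], x$mode[2]))
  invisible(x)
}

#' Quick-look image of a 2D density map
#' @param x a `density_map2d`
#' @param ... passed to [graphics::image()]
#' @return invisibly, `x`
#' @export
plot.density_map2d <- function(x, ...) {
  graphics::image(x$x_mid, x$y_mid, x$prob,
                  xlab = "x", ylab = "y", useRaster = TRUE, ...)
  graphics::points(x$mode[1], x$mode[2], pch = 4, cex = 1.5)
  invisible(x)
}

#' Occupancy fractions of the orientation states
#'
#' @param os character vector of OS labels (or an `orientation_records`
#'   data.frame)
#' @return named numeric vector over `OS1`, `OS0`, `OS2`, summing to 1
#' @export
os_occupancy <- function(os) {
  if (is.data.frame(os)) os <- os$os
  if (!length(os)) stop("no records to compute occupancy over")
  labs <- c("OS1", "OS0", "OS2")
  out <- vapply(labs, function(l) mean(os == l), numeric(1))
  out
}
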