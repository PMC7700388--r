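#' Minimum-image convention for periodic displacements
#'
#' Maps each displacement component into `[-box/2, +box/2)` for an
#' orthorhombic periodic box, i.e. returns the shortest periodic copy of the
#' displacement.
#'
#' @param d displacement(s), nm: length-3 vector or `n x 3` matrix
#' @param box length-3 vector of box edge lengths, nm (all > 0)
#' @return object of the same shape as `d`
#' @export
minimum_image <- function(d, box) {
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box edge lengths must be positive and finite")
  if (is.matrix(d)) {
    b <- matrix(box, nrow = nrow(d), ncol = 3, byrow = TRUE)
    d - b * floor(d / b + 0.5)
  } else {
    d - box * floor(d / box + 0.5)
  }
}

#' Angle between a vector and the membrane normal
#'
#' @param v length-3 vector (any length > 0)
#' @param normal unit normal, default `c(0, 0, 1)`
#' @return list with `degrees` in `[0, 180]` and `cosine` in `[-1, 1]`
#' @export
angle_to_normal <- function(v, normal = c(0, 0, 1)) {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv == 0)
    stop("cannot take the angle of a zero vector")
  nn <- sqrt(sum(normal^2))
  ct <- sum(v * normal) / (nv * nn)
  ct <- min(1, max(-1, ct))
  list(degrees = acos(ct) * 180 / pi, cosine = ct)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets, by SVD of the cross-covariance matrix with the
#' usual determinant correction so reflections are never returned.
#'
#' @param mobile,reference `N x 3` matrices (nm), `N >= 3`, not collinear
#' @return list: `rotation` (3x3, det +1), `translation` (length 3), `rmsd`
#'   (nm), and `fitted` (`N x 3`, the transformed mobile coordinates). The
#'   transform maps a mobile row-vector `x` to `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("mobile and reference must be N x 3 matrices of equal N")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  if (qr(P)$rank < 2 || qr(Q)$rank < 2)
    stop("degenerate point set: all points collinear")
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # maps P rows: x -> x %*% t(R)
  fitted <- P %*% t(R)
  rmsd_val <- sqrt(mean(rowSums((fitted - Q)^2)))
  fitted <- sweep(fitted, 2, cr, FUN = "+")
  translation <- as.numeric(cr - as.numeric(R %*% cm))
  list(rotation = R, translation = translation, rmsd = rmsd_val,
       fitted = fitted)
}

#' Root-mean-square deviation between paired coordinates
#'
#' `sqrt(mean_i |a_i - b_i|^2)` over the `n` atom pairs, with uniform
#' weights; optionally after optimal rigid superposition of `a` onto `b`.
#'
#' @param a,b `N x 3` matrices (nm) with equal `N >= 1`
#' @param superpose superimpose `a` onto `b` first (requires `N >= 3`)
#' @return RMSD in nm
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.vector(a)) a <- matrix(a, ncol = 3)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3)
    stop("coordinate sets must be N x 3 with equal N")
  if (superpose) return(kabsch_superpose(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}
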