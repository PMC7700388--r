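#' Specification of a synthetic bilayer + protein trajectory
#'
#' The generator emulates the statistical structure a membrane-anchored
#' GTPase trajectory presents to the analysis pipeline: a two-leaflet slab
#' of single-particle pseudo-lipids (304 by default, matching a typical
#' simulated patch) with tunable area per lipid and thickness, and a rigid
#' pseudo-protein placed at prescribed orientation angles (Theta, Phi) and
#' anchor depth. Ground truth for every frame is returned alongside the
#' coordinates, so pipeline estimates can be checked against known values.
#'
#' Processes:
#' * `angle_process = "fixed"`: constant requested (Theta, Phi).
#' * `"gaussian_drift"`: stationary AR(1) fluctuation around the requested
#'   centre with long-run standard deviation `angle_sigma` degrees and
#'   autocorrelation `angle_rho`, reflected into the feasible angle range.
#' * `depth_process = "fixed"`: constant anchor depth.
#' * `"two_state"`: discrete-time Markov switch of the anchor depth between
#'   `depth_levels` (anchored / solvated) with per-frame switch probability
#'   `switch_prob` — the bimodal anchor dynamics seen for the farnesyl group.
#'
#' @param n_lipids_per_leaflet particles per leaflet (default 152)
#' @param target_apl target area per lipid, nm^2
#' @param target_thickness target bilayer thickness, nm
#' @param chol_fraction fraction of leaflet particles relabelled as sterol
#'   analogs, in `[0, 1)`
#' @param condensation_factor multiplies `target_apl` when
#'   `chol_fraction > 0` (sterol condensation); default 1
#' @param jitter_sigma Gaussian positional noise on lipid particles, nm
#' @param protein_jitter_sigma Gaussian positional noise on protein atoms, nm
#' @param theta,phi requested orientation angles, degrees
#' @param depth_far anchor (FAR) depth from the bilayer centre, nm
#' @param depth_gtp optional GTP-centre depth, nm (`NULL`: rigid-body value)
#' @param angle_process,angle_sigma,angle_rho see Details
#' @param depth_process,depth_levels,switch_prob see Details
#' @param schedule optional per-frame data.frame with columns `theta`,
#'   `phi`, `depth_far` (and optionally `depth_gtp`), overriding processes
#' @param n_frames,frame_dt frames and frame spacing (ps)
#' @param seed RNG seed; identical spec + seed gives identical trajectories
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_lipids_per_leaflet = 152,
                           target_apl = 0.679,
                           target_thickness = 3.84,
                           chol_fraction = 0,
                           condensation_factor = 1,
                           jitter_sigma = 0.05,
                           protein_jitter_sigma = 0,
                           theta = 80, phi = 105,
                           depth_far = 1.73, depth_gtp = NULL,
                           angle_process = c("fixed", "gaussian_drift"),
                           angle_sigma = 8, angle_rho = 0.95,
                           depth_process = c("fixed", "two_state"),
                           depth_levels = c(1.73, 3.90), switch_prob = 0.02,
                           schedule = NULL,
                           n_frames = 500, frame_dt = 2000, seed = 1) {
  spec <- list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
               target_apl = target_apl,
               target_thickness = target_thickness,
               chol_fraction = chol_fraction,
               condensation_factor = condensation_factor,
               jitter_sigma = jitter_sigma,
               protein_jitter_sigma = protein_jitter_sigma,
               theta = theta, phi = phi,
               depth_far = depth_far, depth_gtp = depth_gtp,
               angle_process = match.arg(angle_process),
               angle_sigma = angle_sigma, angle_rho = angle_rho,
               depth_process = match.arg(depth_process),
               depth_levels = depth_levels, switch_prob = switch_prob,
               schedule = schedule,
               n_frames = as.integer(n_frames), frame_dt = frame_dt,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_lipids_per_leaflet < 2) stop("need at least 2 lipids per leaflet")
    if (target_apl <= 0 || target_thickness <= 0)
      stop("target_apl and target_thickness must be positive")
    if (chol_fraction < 0 || chol_fraction >= 1)
      stop("chol_fraction must be in [0, 1)")
    if (condensation_factor <= 0) stop("condensation_factor must be positive")
    if (jitter_sigma < 0 || protein_jitter_sigma < 0)
      stop("jitter sigmas must be non-negative")
    if (jitter_sigma >= target_thickness / 2)
      stop("jitter_sigma >= half the leaflet spacing: leaflets would not ",
           "be identifiable")
    if (switch_prob < 0 || switch_prob > 1)
      stop("switch_prob must be a probability")
    if (n_frames < 1) stop("n_frames must be >= 1")
    if (!is.null(schedule)) {
      need <- c("theta", "phi", "depth_far")
      if (!all(need %in% names(schedule)))
        stop("schedule must have columns theta, phi, depth_far")
      if (nrow(schedule) != n_frames)
        stop("schedule must have n_frames rows")
    }
  })
  invisible(spec)
}

#' Rigid pseudo-protein template
#'
#' A fixed, minimal coordinate scaffold carrying exactly the atoms the
#' analyses read: one C-alpha per marker residue (5, 9, 132, 156, 163), the
#' backbone atoms (N, CA, C, O) of the 5-aa HVR motif residues 180-184
#' (whose residue-183 CA doubles as the z-order-parameter marker), and
#' 5-atom FAR and GTP clusters whose geometric centres sit exactly on their
#' nominal cluster positions. The beta1 (CA5 to CA9) and alpha5 (CA156 to
#' CA163) vectors enclose exactly 45 degrees, and the CA132-CA183 distance
#' is exactly 1.86 nm, so the rigid template reports the literature OS1
#' z value. Centroid at the origin.
#'
#' @return list: `atoms` (data.frame), `xyz` (matrix, nm),
#'   `inter_vector_angle` (degrees)
#' @export
build_protein_template <- function() {
  deg <- pi / 180
  gam <- 45
  ca5 <- c(0, 0, 0)
  ca9 <- c(0, 0, 1.2)                                   # beta1 along +z
  ca156 <- c(0.9, 0.4, -0.6)
  ca163 <- ca156 + 1.05 * c(sin(gam * deg), 0, cos(gam * deg))
  hvr_ca <- t(sapply(0:4, function(k)
    c(0.4, -0.8 - 0.35 * k, -0.9 + 0.05 * k)))          # residues 180..184
  ca183 <- hvr_ca[4, ]
  ca132 <- ca183 + c(0, 1.2, sqrt(1.86^2 - 1.2^2))      # |CA132-CA183| = 1.86
  off <- rbind(c(0.10, 0.05, -0.05), c(-0.10, 0.08, 0.02),
               c(0.05, -0.10, 0.06), c(-0.05, -0.03, -0.03),
               c(0, 0, 0))                              # offsets sum to zero
  far_c <- c(0.4, -2.6, -1.1)
  gtp_c <- c(1.3, 0.9, 0.9)

  rows <- list()
  add <- function(name, resno, resname, xyz)
    rows[[length(rows) + 1]] <<- data.frame(name = name, resno = resno,
                                            resname = resname,
                                            x = xyz[1], y = xyz[2], z = xyz[3],
                                            stringsAsFactors = FALSE)
  add("CA", 5, "KRS", ca5);     add("CA", 9, "KRS", ca9)
  add("CA", 132, "KRS", ca132)
  add("CA", 156, "KRS", ca156); add("CA", 163, "KRS", ca163)
  bb_off <- rbind(N = c(-0.12, 0.08, 0.03), CA = c(0, 0, 0),
                  C = c(0.12, -0.10, -0.02), O = c(0.18, -0.05, 0.10))
  for (k in 0:4)
    for (nm in rownames(bb_off))
      add(nm, 180 + k, "KRS", hvr_ca[k + 1, ] + bb_off[nm, ])
  for (j in 1:5) add(paste0("C", j), 201, "FAR", far_c + off[j, ])
  for (j in 1:5) add(paste0("G", j), 202, "GTP", gtp_c + off[j, ])
  df <- do.call(rbind, rows)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))                   # centroid at origin
  atoms <- data.frame(index = seq_len(nrow(df)), name = df$name,
                      resno = df$resno, resname = df$resname, segid = "PROT",
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = xyz, inter_vector_angle = gam)
}

# Feasible Phi interval for a given Theta, both degrees, with the template's
# fixed inter-vector angle gamma: rotating the alpha5 vector about beta1
# sweeps a cone, so Phi ranges over [|Theta-gamma|, min(Theta+gamma,
# 360-Theta-gamma)].
phi_feasible <- function(theta, gamma) {
  c(abs(theta - gamma), min(theta + gamma, 360 - theta - gamma))
}

#' Place the rigid template at prescribed orientation and depth
#'
#' Finds the proper rotation taking the template's beta1 vector to tilt
#' `theta` and its alpha5 vector to tilt `phi` (both against +z), by a
#' deterministic two-stage construction: the beta1 vector is put on the
#' requested Theta-cone in the xz-plane, then the alpha5 direction is solved
#' in the orthonormal frame of the beta1 axis; of the two mirror solutions
#' the one with positive out-of-plane component is taken. The placed FAR
#' cluster centre sits at `depth_far` above `center_z`; the xy position is
#' the lateral box centre. An optional `depth_gtp` rigidly shifts only the
#' GTP cluster along z (the nucleotide's association with the membrane
#' interface varies independently of the scaffold orientation).
#'
#' Requests outside the feasible Phi interval for the given Theta raise an
#' error naming the attainable interval; accepted requests are realised to
#' machine precision, never clamped.
#'
#' @param template from [build_protein_template()]
#' @param theta,phi requested tilt angles, degrees in `[0, 180]`
#' @param depth_far FAR-centre depth above the bilayer centre, nm
#' @param center_z bilayer centre, nm
#' @param box length-3 box vector, nm
#' @param depth_gtp optional GTP-centre depth, nm
#' @return list: `xyz` (placed coordinates), `atoms`, `realized_theta`,
#'   `realized_phi` (degrees)
#' @export
place_protein <- function(template, theta, phi, depth_far, center_z, box,
                          depth_gtp = NULL) {
  deg <- pi / 180
  stopifnot(theta >= 0, theta <= 180, phi >= 0, phi <= 180)
  a <- template$atoms
  i5 <- which(a$name == "CA" & a$resno == 5)
  i9 <- which(a$name == "CA" & a$resno == 9)
  i156 <- which(a$name == "CA" & a$resno == 156)
  i163 <- which(a$name == "CA" & a$resno == 163)
  u0 <- template$xyz[i9, ] - template$xyz[i5, ];   u0 <- u0 / sqrt(sum(u0^2))
  v0 <- template$xyz[i163, ] - template$xyz[i156, ]; v0 <- v0 / sqrt(sum(v0^2))
  gamma <- acos(min(1, max(-1, sum(u0 * v0)))) / deg
  fr <- phi_feasible(theta, gamma)
  tol <- 1e-9
  if (phi < fr[1] - tol || phi > fr[2] + tol)
    stop(sprintf(paste0("infeasible orientation request: with Theta = %.6g",
                        " deg the attainable Phi interval is [%.6g, %.6g] deg",
                        " (requested %.6g)"), theta, fr[1], fr[2], phi))
  phi <- min(max(phi, fr[1]), fr[2])   # only absorbs the <=1e-9 tolerance
  th <- theta * deg; ph <- phi * deg; gm <- gamma * deg
  u <- c(sin(th), 0, cos(th))
  if (sin(th) < 1e-12) {
    # beta1 along the normal: Phi is forced to gamma (or its supplement)
    v <- c(sin(gm), 0, sign(cos(th)) * cos(gm))
  } else {
    p <- c(cos(th), 0, -sin(th))                  # unit, in-plane, normal to u
    q <- c(0, 1, 0)                               # u x p
    av <- cos(gm)
    bv <- (av * cos(th) - cos(ph)) / sin(th)      # from v.z = cos(phi)
    cv2 <- 1 - av^2 - bv^2
    cv <- sqrt(max(0, cv2))
    v <- av * u + bv * p + cv * q
  }
  basis <- function(e1, vv) {
    e2 <- vv - sum(vv * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
    cbind(e1, e2, c(e1[2] * e2[3] - e1[3] * e2[2],
                    e1[3] * e2[1] - e1[1] * e2[3],
                    e1[1] * e2[2] - e1[2] * e2[1]))
  }
  E <- basis(u0, v0); FF <- basis(u, v)
  R <- FF %*% t(E)                                 # proper rotation by design
  xyz <- template$xyz %*% t(R)
  far_idx <- which(a$resname == "FAR")
  far_center <- colMeans(xyz[far_idx, , drop = FALSE])
  shift <- c(box[1] / 2, box[2] / 2, center_z + depth_far) - far_center
  xyz <- sweep(xyz, 2, shift, FUN = "+")
  if (!is.null(depth_gtp)) {
    gtp_idx <- which(a$resname == "GTP")
    dz <- (center_z + depth_gtp) - mean(xyz[gtp_idx, 3])
    xyz[gtp_idx, 3] <- xyz[gtp_idx, 3] + dz
  }
  list(xyz = xyz, atoms = a,
       realized_theta = angle_to_normal(xyz[i9, ] - xyz[i5, ])$degrees,
       realized_phi = angle_to_normal(xyz[i163, ] - xyz[i156, ])$degrees)
}

#' Build one synthetic bilayer slab frame
#'
#' Two square lattices of single-particle pseudo-phosphates at plus/minus
#' half the target thickness around the box mid-plane; the lateral box edge
#' is chosen so that box area / particles-per-leaflet equals the effective
#' target area per lipid (`target_apl` times the condensation factor when
#' sterol is present). A `chol_fraction` of evenly spaced particles per
#' leaflet is relabelled as sterol analogs (`CHL`). Gaussian jitter of width
#' `jitter_sigma` is then applied to every coordinate.
#'
#' @param spec a [synthetic_spec()]
#' @return list: `atoms`, `xyz` (nm), `box` (length 3), `apl_effective`
#' @export
build_slab <- function(spec) {
  n <- spec$n_lipids_per_leaflet
  apl_eff <- spec$target_apl *
    if (spec$chol_fraction > 0) spec$condensation_factor else 1
  L <- sqrt(n * apl_eff)
  box_z <- spec$target_thickness + 10
  box <- c(L, L, box_z)
  ncell <- ceiling(sqrt(n))
  sp <- L / ncell
  g <- expand.grid(i = seq_len(ncell) - 1L, j = seq_len(ncell) - 1L)
  site <- cbind((g$i + 0.5) * sp, (g$j + 0.5) * sp)[seq_len(n), , drop = FALSE]
  zc <- box_z / 2
  xyz <- rbind(cbind(site, zc + spec$target_thickness / 2),
               cbind(site, zc - spec$target_thickness / 2))
  n_chol <- round(spec$chol_fraction * n)
  chol <- if (n_chol > 0)
    round(seq(1, n, length.out = n_chol)) else integer(0)
  is_chol <- rep(seq_len(n) %in% chol, 2L)
  atoms <- data.frame(index = seq_len(2L * n),
                      name = ifelse(is_chol, "C1", "P"),
                      resno = seq_len(2L * n),
                      resname = ifelse(is_chol, "CHL", "DOP"),
                      segid = "MEMB", stringsAsFactors = FALSE)
  if (spec$jitter_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter_sigma),
                        ncol = 3)
  list(atoms = atoms, xyz = xyz, box = box, apl_effective = apl_eff)
}

# Reflect x into [lo, hi] by folding.
reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(rep(lo, length(x)))
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# Per-frame placement schedule from the spec's processes (RNG already seeded).
build_schedule <- function(spec, gamma) {
  nf <- spec$n_frames
  if (!is.null(spec$schedule)) {
    s <- spec$schedule
    if (is.null(s$depth_gtp)) s$depth_gtp <- NA_real_
    return(s[, c("theta", "phi", "depth_far", "depth_gtp")])
  }
  theta <- rep(spec$theta, nf); phi <- rep(spec$phi, nf)
  if (spec$angle_process == "gaussian_drift") {
    rho <- spec$angle_rho
    sd_step <- spec$angle_sigma * sqrt(1 - rho^2)
    for (t in seq_len(nf)) {
      prev_t <- if (t == 1) spec$theta else theta[t - 1]
      prev_p <- if (t == 1) spec$phi else phi[t - 1]
      theta[t] <- reflect_into(spec$theta + rho * (prev_t - spec$theta) +
                                 stats::rnorm(1, 0, sd_step), 0, 180)
      fr <- phi_feasible(theta[t], gamma)
      phi[t] <- reflect_into(spec$phi + rho * (prev_p - spec$phi) +
                               stats::rnorm(1, 0, sd_step), fr[1], fr[2])
    }
  }
  depth <- rep(spec$depth_far, nf)
  if (spec$depth_process == "two_state") {
    state <- integer(nf); state[1] <- 1L
    flips <- stats::runif(nf) < spec$switch_prob
    if (nf > 1)
      for (t in 2:nf)
        state[t] <- if (flips[t]) 3L - state[t - 1] else state[t - 1]
    depth <- spec$depth_levels[state]
  }
  data.frame(theta = theta, phi = phi, depth_far = depth,
             depth_gtp = if (is.null(spec$depth_gtp)) NA_real_
                         else spec$depth_gtp)
}

#' Generate a ground-truthed synthetic trajectory
#'
#' Composes per-frame slab + placed protein following the spec's placement
#' schedule. Deterministic: the same spec and seed reproduce the trajectory
#' exactly (and byte-for-byte on disk via [write_trajectory()]).
#'
#' @param spec a [synthetic_spec()]
#' @return list: `trajectory` (a [memtraj]), `truth` (per-frame data.frame
#'   of requested and realised Theta/Phi/depths plus box and target
#'   metrics), `spec`
#' @export
generate_trajectory <- function(spec) {
  validate_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  template <- build_protein_template()
  gamma <- template$inter_vector_angle
  sched <- build_schedule(spec, gamma)
  nf <- spec$n_frames

  slab0 <- build_slab(spec)          # geometry probe; re-jittered per frame
  n_memb <- nrow(slab0$atoms)
  prot_atoms <- template$atoms
  prot_atoms$index <- prot_atoms$index + n_memb
  # protein residue numbers are kept as in the template (marker residues
  # 5..183): selections always combine them with atom/residue names, so the
  # overlap with lipid residue numbering is harmless
  atoms <- rbind(slab0$atoms, prot_atoms)
  n_tot <- nrow(atoms)

  xyz <- array(NA_real_, dim = c(n_tot, 3L, nf))
  truth <- vector("list", nf)
  lipid_rows <- which(slab0$atoms$resname == "DOP")
  far_rows <- n_memb + which(template$atoms$resname == "FAR")
  gtp_rows <- n_memb + which(template$atoms$resname == "GTP")
  for (f in seq_len(nf)) {
    slab <- build_slab(spec)
    center_z <- mean(slab$xyz[lipid_rows, 3])
    dg <- if (is.na(sched$depth_gtp[f])) NULL else sched$depth_gtp[f]
    pl <- place_protein(template, sched$theta[f], sched$phi[f],
                        sched$depth_far[f], center_z, slab$box,
                        depth_gtp = dg)
    pxyz <- pl$xyz
    if (spec$protein_jitter_sigma > 0)
      pxyz <- pxyz + matrix(stats::rnorm(length(pxyz), 0,
                                         spec$protein_jitter_sigma), ncol = 3)
    xyz[seq_len(n_memb), , f] <- slab$xyz
    xyz[n_memb + seq_len(nrow(pxyz)), , f] <- pxyz
    truth[[f]] <- data.frame(
      frame = f, time = (f - 1) * spec$frame_dt,
      theta_req = sched$theta[f], phi_req = sched$phi[f],
      theta_realized = pl$realized_theta, phi_realized = pl$realized_phi,
      depth_far_req = sched$depth_far[f],
      depth_far_realized = mean(pxyz[far_rows - n_memb, 3]) - center_z,
      depth_gtp_realized = mean(pxyz[gtp_rows - n_memb, 3]) - center_z,
      center_z = center_z, apl_effective = slab$apl_effective,
      box_x = slab$box[1], box_y = slab$box[2], box_z = slab$box[3])
  }
  traj <- memtraj(atoms, xyz, slab0$box, time = (seq_len(nf) - 1) * spec$frame_dt)
  list(trajectory = traj, truth = do.call(rbind, truth), spec = spec)
}

#' Preset synthetic systems
#'
#' Four presets mirror the study conditions of wild-type and oncogenic
#' lipid-anchored KRas-4B on anionic bilayers without and with 30%
#' cholesterol: bilayer targets are the reported per-system area per lipid
#' and thickness; orientation centres and anchor/nucleotide depths are the
#' reported preferred values for each system.
#'
#' * `wt_chol0`: A 0.679 nm^2, thickness 3.84 nm; (Theta, Phi) about
#'   (59, 52.5) deg; FAR anchored at 1.30 nm; GTP at 4.38 nm.
#' * `wt_chol30`: A 0.523 nm^2, thickness 4.35 nm, 30% sterol; (53, 37) deg;
#'   FAR switching between 1.73 and 3.90 nm; GTP at 2.39 nm.
#' * `onc_chol0`: A 0.679 nm^2, thickness 3.89 nm; (99, 83) deg; FAR at
#'   1.47 nm; GTP at 2.78 nm.
#' * `onc_chol30`: A 0.525 nm^2, thickness 4.23 nm, 30% sterol; (80, 105)
#'   deg (the active OS1 orientation); FAR anchored 0.17 nm deeper than the
#'   sterol-free oncogenic case (1.30 nm); GTP bound to the catalytic
#'   domain (rigid-body depth).
#'
#' @param name one of `"wt_chol0"`, `"wt_chol30"`, `"onc_chol0"`,
#'   `"onc_chol30"`
#' @param seed RNG seed
#' @param n_frames frames to generate (default 1000: a 2-microsecond-spaced
#'   emulation of a 1000-frame production run)
#' @param ... further overrides passed to [synthetic_spec()]
#' @return a [synthetic_spec()]
#' @export
synthetic_preset <- function(name = c("wt_chol0", "wt_chol30",
                                      "onc_chol0", "onc_chol30"),
                             seed = 1, n_frames = 1000, ...) {
  name <- match.arg(name)
  base <- switch(name,
    wt_chol0 = list(target_apl = 0.679, target_thickness = 3.84,
                    chol_fraction = 0, theta = 59, phi = 52.5,
                    depth_far = 1.30, depth_gtp = 4.38),
    wt_chol30 = list(target_apl = 0.523, target_thickness = 4.35,
                     chol_fraction = 0.3, theta = 53, phi = 37,
                     depth_far = 1.73, depth_gtp = 2.39,
                     depth_process = "two_state",
                     depth_levels = c(1.73, 3.90), switch_prob = 0.02),
    onc_chol0 = list(target_apl = 0.679, target_thickness = 3.89,
                     chol_fraction = 0, theta = 99, phi = 83,
                     depth_far = 1.47, depth_gtp = 2.78),
    onc_chol30 = list(target_apl = 0.525, target_thickness = 4.23,
                      chol_fraction = 0.3, theta = 80, phi = 105,
                      depth_far = 1.30, depth_gtp = NULL))
  args <- utils::modifyList(
    c(base, list(angle_process = "gaussian_drift", angle_sigma = 8,
                 seed = seed, n_frames = n_frames)),
    list(...))
  do.call(synthetic_spec, args)
}
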