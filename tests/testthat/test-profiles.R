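test_that("depth series reports the signed distance from the bilayer centre", {
  gen <- quick_traj(n_frames = 6, depth_far = 1.73, seed = 22)
  tr <- gen$trajectory
  lip <- resolve_selection(tr, "lipid_P")
  far <- resolve_selection(tr, "far_group")
  d <- depth_series(tr, far, lip, window_fraction = 1)
  expect_equal(d$depth, rep(1.73, 6), tolerance = 1e-9)
  expect_equal(d$mean, 1.73, tolerance = 1e-9)
  expect_equal(d$modes[1], 1.75, tolerance = 0.051)  # 0.1 nm bin centre
  expect_error(depth_series(tr, integer(0), lip), "empty moiety")
})

test_that("a moiety at the bilayer centre has zero depth", {
  gen <- quick_traj(n_frames = 3, seed = 23)
  tr <- gen$trajectory
  lip <- resolve_selection(tr, "lipid_P")
  # use the phosphorus set itself: its centre IS the bilayer centre
  d <- depth_series(tr, lip, lip, window_fraction = 1)
  expect_equal(d$depth, rep(0, 3), tolerance = 1e-12)
})

test_that("depth series is invariant under rigid z-translation", {
  gen <- quick_traj(n_frames = 5, seed = 24)
  tr <- gen$trajectory
  lip <- resolve_selection(tr, "lipid_P")
  far <- resolve_selection(tr, "far_group")
  shifted <- tr
  shifted$xyz <- tr$xyz + 2.0
  expect_equal(depth_series(shifted, far, lip, 1)$depth,
               depth_series(tr, far, lip, 1)$depth)
})

test_that("two-state anchor dynamics yield the two histogram modes", {
  spec <- synthetic_spec(depth_process = "two_state",
                         depth_levels = c(1.73, 3.90), switch_prob = 0.02,
                         jitter_sigma = 0.05, n_frames = 2000,
                         angle_process = "fixed", seed = 25)
  gen <- generate_trajectory(spec)
  tr <- gen$trajectory
  d <- depth_series(tr, resolve_selection(tr, "far_group"),
                    resolve_selection(tr, "lipid_P"), window_fraction = 1)
  top2 <- sort(d$modes[1:2])
  expect_lt(abs(top2[1] - 1.73), 0.1)
  expect_lt(abs(top2[2] - 3.90), 0.1)
})

test_that("HVR motif RMSD is zero for identical and rigidly moved frames", {
  gen <- quick_traj(n_frames = 5, seed = 26)
  tr <- gen$trajectory
  hvr <- resolve_selection(tr, "hvr_motif")
  r <- hvr_rmsd_series(tr, hvr, window_fraction = 1)
  expect_equal(r$rmsd, rep(0, 5), tolerance = 1e-9)
  expect_equal(r$reference_frame, 1)

  # rigidly move every frame: superposition removes the motion entirely
  set.seed(26)
  moved <- tr
  for (f in 2:5) moved$xyz[, , f] <- rigid_move(tr$xyz[, , 1])
  r2 <- hvr_rmsd_series(moved, hvr, window_fraction = 1)
  expect_equal(r2$rmsd, rep(0, 5), tolerance = 1e-9)
})

test_that("HVR RMSD matches a direct formula evaluation under distortion", {
  gen <- quick_traj(n_frames = 3, seed = 27)
  tr <- gen$trajectory
  hvr <- resolve_selection(tr, "hvr_motif")
  set.seed(27)
  tr$xyz[hvr, , 2] <- tr$xyz[hvr, , 2] +
    matrix(stats::rnorm(length(hvr) * 3, 0, 0.05), ncol = 3)
  r <- hvr_rmsd_series(tr, hvr, window_fraction = 1)
  # independent route: established superposition tool on the same atoms
  a <- tr$xyz[hvr, , 2]; b <- tr$xyz[hvr, , 1]
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a))))
  oracle <- rmsd(matrix(fitted, ncol = 3, byrow = TRUE), b)
  expect_equal(r$rmsd[2], oracle, tolerance = 1e-8)
  # and the series is just the frame-wise geometry kernel
  expect_equal(r$rmsd[2], rmsd(a, b, superpose = TRUE), tolerance = 1e-12)
})

test_that("RDF: single pair, lattice peak, and normalisation identity", {
  # two atoms 1.0 nm apart: all counts in the bin containing 1.0
  atoms <- data.frame(index = 1:2, name = c("A", "B"), resno = 1:2,
                      resname = "X", segid = "")
  xyz <- array(c(1, 1, 1, 2, 1, 1), dim = c(2, 3, 1))
  tr <- memtraj(atoms, xyz, c(6, 6, 6))
  r <- compute_rdf(tr, 1, 2, r_max = 2, dr = 0.1)
  expect_equal(sum(r$counts), 1)
  expect_equal(r$r[which(r$counts > 0)], 1.05)   # bin [1.0, 1.1)

  # simple cubic lattice of spacing a: the first nonzero bin contains a
  a_sp <- 1.0; ncell <- 4
  g <- expand.grid(x = 0:(ncell - 1), y = 0:(ncell - 1), z = 0:(ncell - 1))
  lat <- as.matrix(g) * a_sp
  atoms2 <- data.frame(index = seq_len(nrow(lat)), name = "A",
                       resno = seq_len(nrow(lat)), resname = "X", segid = "")
  tr2 <- memtraj(atoms2, array(lat, dim = c(nrow(lat), 3, 1)),
                 rep(ncell * a_sp, 3))
  r2 <- compute_rdf(tr2, seq_len(nrow(lat)), seq_len(nrow(lat)),
                    r_max = 1.9, dr = 0.05)
  first_peak <- r2$r[which(r2$counts > 0)[1]]
  expect_lt(abs(first_peak - a_sp), 0.05)

  # normalisation: integral of rho*g*4*pi*r^2*dr = mean neighbour count
  set.seed(28)
  n <- 600
  rnd <- matrix(stats::runif(n * 3, 0, 6), ncol = 3)
  atoms3 <- data.frame(index = 1:n, name = "A", resno = 1:n,
                       resname = "X", segid = "")
  tr3 <- memtraj(atoms3, array(rnd, dim = c(n, 3, 1)), c(6, 6, 6))
  r3 <- compute_rdf(tr3, 1:n, 1:n, r_max = 2.5, dr = 0.1)
  edges <- seq(0, 2.5, by = 0.1)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  rho <- (n - 1) / 216
  integral <- sum(rho * r3$g * shell)
  neighbours <- sum(r3$counts) / n
  expect_lt(abs(integral - neighbours) / neighbours, 0.01)

  expect_error(compute_rdf(tr3, 1:n, 1:n, r_max = 5), "half the smallest")
  expect_error(compute_rdf(tr3, integer(0), 1:n, r_max = 2), "empty")
})
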