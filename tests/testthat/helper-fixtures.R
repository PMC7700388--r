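# Shared test helpers: random rigid motions and tiny literal fixtures.

# Uniform random rotation matrix from a random quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Apply a rigid motion (rotation R then translation t) to N x 3 rows.
rigid_move <- function(xyz, R = random_rotation(), t = stats::rnorm(3)) {
  sweep(xyz %*% t(R), 2, t, FUN = "+")
}

# Minimal single-frame GRO text: 3 atoms, 5x5x5 nm box.
tiny_gro_lines <- function() {
  c("tiny t= 0.00000",
    "    3",
    "    1DOP      P    1   1.000   2.000   3.000",
    "    2DOP      P    2   2.500   2.500   2.500",
    "    3KRS     CA    3   0.100   0.200   0.300",
    "   5.00000   5.00000   5.00000")
}

# Minimal multi-model PDB text (coordinates in Angstrom).
tiny_pdb_lines <- function() {
  c("CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1           1",
    "MODEL        1",
    "ATOM      1  P   DOP A   1      10.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  CA  KRS A   5       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  KRS A   9       4.000   5.000   6.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  P   DOP A   1      11.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  CA  KRS A   5       1.000   2.000   3.500  1.00  0.00           C",
    "ATOM      3  CA  KRS A   9       4.000   5.000   6.500  1.00  0.00           C",
    "ENDMDL",
    "END")
}

# A quick noise-free fixed-orientation synthetic trajectory.
quick_traj <- function(n_frames = 5, theta = 80, phi = 105,
                       depth_far = 1.73, seed = 42, ...) {
  spec <- synthetic_spec(jitter_sigma = 0, n_frames = n_frames,
                         theta = theta, phi = phi, depth_far = depth_far,
                         angle_process = "fixed", seed = seed, ...)
  generate_trajectory(spec)
}
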