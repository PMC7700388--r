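test_that("noise-free slab hits the bilayer targets exactly", {
  spec <- synthetic_spec(jitter_sigma = 0, target_apl = 0.679,
                         target_thickness = 3.84, n_frames = 1,
                         angle_process = "fixed", seed = 1)
  slab <- build_slab(spec)
  mf <- assign_leaflets(slab$xyz, which(slab$atoms$resname == "DOP"))
  expect_equal(area_per_lipid(slab$box, mf), 0.679, tolerance = 1e-12)
  expect_equal(bilayer_thickness(slab$xyz, mf), 3.84, tolerance = 1e-12)
})

test_that("sterol condensation rescales the effective area per lipid", {
  spec <- synthetic_spec(chol_fraction = 0.3, condensation_factor = 0.77,
                         jitter_sigma = 0, n_frames = 1,
                         angle_process = "fixed", seed = 1)
  slab <- build_slab(spec)
  expect_equal(slab$apl_effective, 0.77 * 0.679)
  mf <- assign_leaflets(slab$xyz, which(slab$atoms$resname == "DOP"),
                        seq_len(nrow(slab$atoms)))
  expect_equal(area_per_lipid(slab$box, mf), 0.77 * 0.679, tolerance = 1e-12)
})

test_that("spec validation rejects unusable parameters", {
  expect_error(synthetic_spec(jitter_sigma = 2, target_thickness = 3.8),
               "leaflet")
  expect_error(synthetic_spec(chol_fraction = 1.2), "chol_fraction")
  expect_error(synthetic_spec(target_apl = -1), "positive")
  expect_error(synthetic_spec(n_frames = 0), "n_frames")
})

test_that("the rigid template exposes exactly the marker geometry", {
  tpl <- build_protein_template()
  expect_equal(colMeans(tpl$xyz), c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  ca <- tpl$atoms$name == "CA"
  marker_res <- c(5, 9, 132, 156, 163, 183)
  for (res in marker_res)
    expect_equal(sum(ca & tpl$atoms$resno == res), 1)
  expect_equal(tpl$inter_vector_angle, 45)
  # the inter-vector angle is a fixed property of the scaffold
  i <- function(res) which(ca & tpl$atoms$resno == res)
  u <- tpl$xyz[i(9), ] - tpl$xyz[i(5), ]
  v <- tpl$xyz[i(163), ] - tpl$xyz[i(156), ]
  expect_equal(acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi, 45,
               tolerance = 1e-9)
  expect_gte(45, 30)   # vectors far from parallel: angles well conditioned
  # z order parameter of the rigid scaffold: the literature OS1 separation
  expect_equal(sqrt(sum((tpl$xyz[i(132), ] - tpl$xyz[i(183), ])^2)), 1.86,
               tolerance = 1e-12)
  expect_equal(sum(tpl$atoms$resname == "FAR"), 5)
  expect_equal(sum(tpl$atoms$resname == "GTP"), 5)
  expect_equal(sum(tpl$atoms$resno %in% 180:184), 20)
})

test_that("protein placement realises requested angles to machine precision", {
  tpl <- build_protein_template()
  pl <- place_protein(tpl, 80, 105, 1.73, 7, c(10, 10, 14))
  expect_equal(pl$realized_theta, 80, tolerance = 1e-9)
  expect_equal(pl$realized_phi, 105, tolerance = 1e-9)

  set.seed(33)
  worst <- 0
  for (i in 1:1000) {
    theta <- stats::runif(1, 1, 179)
    fr <- memorient:::phi_feasible(theta, 45)
    phi <- stats::runif(1, fr[1] + 1e-6, fr[2] - 1e-6)
    pl <- place_protein(tpl, theta, phi, 1.5, 7, c(10, 10, 14))
    worst <- max(worst, abs(pl$realized_theta - theta),
                 abs(pl$realized_phi - phi))
  }
  expect_lt(worst, 1e-6)
})

test_that("placement at Theta = 0 forces Phi to the template angle", {
  tpl <- build_protein_template()
  pl <- place_protein(tpl, 0, 45, 1.5, 7, c(10, 10, 14))
  expect_equal(pl$realized_theta, 0, tolerance = 1e-9)
  expect_equal(pl$realized_phi, 45, tolerance = 1e-9)
  expect_error(place_protein(tpl, 0, 90, 1.5, 7, c(10, 10, 14)),
               "infeasible")
})

test_that("infeasible requests error with the attainable interval, never clamp", {
  tpl <- build_protein_template()
  expect_error(place_protein(tpl, 80, 160, 1.5, 7, c(10, 10, 14)),
               "attainable Phi interval is \\[35, 125\\]")
  expect_error(place_protein(tpl, 80, 10, 1.5, 7, c(10, 10, 14)),
               "infeasible")
})

test_that("generation is deterministic: same spec and seed, identical bytes", {
  spec <- synthetic_spec(n_frames = 8, angle_process = "gaussian_drift",
                         depth_process = "two_state", seed = 99)
  g1 <- generate_trajectory(spec)
  g2 <- generate_trajectory(spec)
  expect_identical(g1$trajectory$xyz, g2$trajectory$xyz)
  expect_identical(g1$truth, g2$truth)
  f1 <- withr::local_tempfile(fileext = ".gro")
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(g1$trajectory, f1)
  write_trajectory(g2$trajectory, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("drifting angles stay in range and fluctuate about the request", {
  spec <- synthetic_spec(angle_process = "gaussian_drift", angle_sigma = 8,
                         theta = 80, phi = 105, n_frames = 400,
                         jitter_sigma = 0, seed = 55)
  tru <- generate_trajectory(spec)$truth
  expect_true(all(tru$theta_realized >= 0 & tru$theta_realized <= 180))
  expect_true(all(tru$phi_realized >= 0 & tru$phi_realized <= 180))
  expect_lt(abs(mean(tru$theta_realized) - 80), 8)
  expect_lt(abs(mean(tru$phi_realized) - 105), 8)
  # realised always equals requested: requests are honoured, not clamped
  expect_equal(tru$theta_realized, tru$theta_req, tolerance = 1e-9)
  expect_equal(tru$phi_realized, tru$phi_req, tolerance = 1e-9)
})

test_that("full-loop recovery on 20 random noise-free specs", {
  set.seed(66)
  for (i in 1:20) {
    theta <- stats::runif(1, 10, 170)
    fr <- memorient:::phi_feasible(theta, 45)
    phi <- stats::runif(1, fr[1] + 0.5, fr[2] - 0.5)
    spec <- synthetic_spec(
      target_apl = stats::runif(1, 0.52, 0.68),
      target_thickness = stats::runif(1, 3.8, 4.4),
      theta = theta, phi = phi,
      depth_far = stats::runif(1, 1.2, 3.9),
      jitter_sigma = 0, n_frames = 4, angle_process = "fixed",
      seed = 1000 + i)
    gen <- generate_trajectory(spec)
    tr <- gen$trajectory
    met <- bilayer_metrics(tr, window_fraction = 1)
    expect_equal(mean(met$area_per_lipid), spec$target_apl, tolerance = 1e-9)
    expect_equal(mean(met$thickness), spec$target_thickness,
                 tolerance = 1e-9)
    ore <- orientation_records(tr, window_fraction = 1)
    expect_equal(ore$theta, rep(theta, 4), tolerance = 1e-6)
    expect_equal(ore$phi, rep(phi, 4), tolerance = 1e-6)
    d <- depth_series(tr, resolve_selection(tr, "far_group"),
                      resolve_selection(tr, "lipid_P"), 1)
    expect_equal(d$depth, rep(spec$depth_far, 4), tolerance = 1e-9)
  }
})
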