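test_that("order parameter z is the marker separation", {
  xyz <- rbind(c(0, 0, 4), c(0, 0, 1), c(3, 4, 0), c(0, 0, 0))
  expect_equal(order_parameter_z(xyz, 2, 1), 3.0)
  expect_equal(order_parameter_z(xyz, 4, 3), 5.0)
  # projection mode keeps only the normal component
  expect_equal(order_parameter_z(xyz, 4, 3, mode = "projection"), 0)
  expect_equal(order_parameter_z(xyz, 2, 1, mode = "projection"), 3.0)
})

test_that("tilt angles against the normal match their definitions", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 0, -1), c(0, 1, 1))
  expect_equal(order_parameter_theta(xyz, 1, 2)$degrees, 0)
  expect_equal(order_parameter_theta(xyz, 1, 2)$cosine, 1)
  expect_equal(order_parameter_theta(xyz, 1, 3)$degrees, 90)
  expect_equal(order_parameter_phi(xyz, 1, 4)$degrees, 180)
  expect_equal(order_parameter_phi(xyz, 1, 5)$degrees, 45)
  expect_error(order_parameter_theta(xyz, 1, 1), "coincident")
})

test_that("the three literature OS centres classify to their own labels", {
  expect_equal(classify_os(1.86, -0.5), "OS1")
  expect_equal(classify_os(4.97, 1.0), "OS2")
  expect_equal(classify_os(3.33, 0.9), "OS0")
  expect_equal(classify_os(c(1.86, 4.97, 3.33), c(-0.5, 1, 0.9)),
               c("OS1", "OS2", "OS0"))
})

test_that("OS labels are stable under sub-gap perturbations", {
  model <- os_region_model()
  cen <- model$centers
  set.seed(4)
  # half the smallest normalised inter-centre distance
  norm_d <- function(a, b) sqrt(((a[1] - b[1]) / model$z_scale)^2 +
                                ((a[2] - b[2]) / model$cos_scale)^2)
  gap <- min(norm_d(cen[1, ], cen[2, ]), norm_d(cen[1, ], cen[3, ]),
             norm_d(cen[2, ], cen[3, ]))
  for (lab in rownames(cen)) {
    for (i in 1:30) {
      ang <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 0, 0.49 * gap)
      z <- cen[lab, 1] + r * cos(ang) * model$z_scale
      ct <- cen[lab, 2] + r * sin(ang) * model$cos_scale
      expect_equal(classify_os(z, ct, model), lab)
    }
  }
})

test_that("density map: degenerate, uniform and Gaussian cases", {
  # all records identical -> one occupied bin with probability 1
  m <- density_map(rep(2, 10), rep(3, 10), n_bins = 10)
  expect_equal(sum(m$prob), 1, tolerance = 1e-12)
  expect_equal(max(m$prob), 1)
  expect_equal(m$mode[1], 2, tolerance = 0.11)
  expect_equal(m$mode[2], 3, tolerance = 0.11)

  # uniform sampling: every bin probability ~ 1/100 (multinomial bound)
  set.seed(14)
  n <- 1e5
  m2 <- density_map(stats::runif(n), stats::runif(n), n_bins = 10,
                    x_range = c(0, 1), y_range = c(0, 1))
  expect_equal(sum(m2$prob), 1, tolerance = 1e-12)
  expect_true(all(abs(m2$prob - 0.01) < 0.002))

  # Gaussian cloud at the active-state orientation: mode bin holds the centre
  th <- stats::rnorm(5000, 80, 8); ph <- stats::rnorm(5000, 105, 8)
  m3 <- density_map(th, ph, n_bins = 20)
  # mode bin within one bin of the bin holding the centre
  bw_x <- diff(m3$x_breaks[1:2]); bw_y <- diff(m3$y_breaks[1:2])
  expect_lte(abs(m3$mode[1] - 80), 1.5 * bw_x)
  expect_lte(abs(m3$mode[2] - 105), 1.5 * bw_y)
})

test_that("density-map marginals equal directly binned 1D histograms", {
  set.seed(15)
  x <- stats::rnorm(2000); y <- stats::rnorm(2000)
  m <- density_map(x, y, n_bins = 25)
  hx <- graphics::hist(x, breaks = m$x_breaks, plot = FALSE)$counts / 2000
  hy <- graphics::hist(y, breaks = m$y_breaks, plot = FALSE)$counts / 2000
  expect_equal(m$marginal_x, hx, tolerance = 1e-12)
  expect_equal(m$marginal_y, hy, tolerance = 1e-12)
  expect_error(density_map(numeric(0), numeric(0)), "at least one")
})

test_that("OS occupancy fractions sum to one and recover a known mixture", {
  expect_equal(os_occupancy(rep("OS1", 10)),
               c(OS1 = 1, OS0 = 0, OS2 = 0))
  expect_equal(os_occupancy(c("OS1", "OS2")),
               c(OS1 = 0.5, OS0 = 0, OS2 = 0.5))
  expect_error(os_occupancy(character(0)), "no records")

  # 70/20/10 mixture drawn at the three centres with small noise
  set.seed(16)
  n <- 5000
  lab <- sample(c("OS1", "OS0", "OS2"), n, TRUE, prob = c(0.7, 0.2, 0.1))
  cen <- os_region_model()$centers
  z <- cen[lab, 1] + stats::rnorm(n, 0, 0.15)
  ct <- cen[lab, 2] + stats::rnorm(n, 0, 0.05)
  occ <- os_occupancy(classify_os(z, ct))
  expect_equal(sum(occ), 1)
  expect_lt(max(abs(occ - c(OS1 = 0.7, OS0 = 0.2, OS2 = 0.1))), 0.03)
})

test_that("Theta and Phi are invariant under translation and rotation about z", {
  template <- build_protein_template()
  set.seed(17)
  for (i in 1:100) {
    theta <- stats::runif(1, 5, 175)
    fr <- memorient:::phi_feasible(theta, template$inter_vector_angle)
    phi <- stats::runif(1, fr[1], fr[2])
    pl <- place_protein(template, theta, phi, 1.5, 7, c(10, 10, 14))
    ang <- stats::runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                 3, byrow = TRUE)
    moved <- sweep(pl$xyz %*% t(Rz), 2, c(stats::rnorm(2), 0), FUN = "+")
    a <- template$atoms
    i5 <- which(a$name == "CA" & a$resno == 5)
    i9 <- which(a$name == "CA" & a$resno == 9)
    i156 <- which(a$name == "CA" & a$resno == 156)
    i163 <- which(a$name == "CA" & a$resno == 163)
    expect_equal(order_parameter_theta(moved, i5, i9)$degrees, theta,
                 tolerance = 1e-8)
    expect_equal(order_parameter_phi(moved, i156, i163)$degrees, phi,
                 tolerance = 1e-8)
  }
})

test_that("angle recovery error shrinks as marker separation grows", {
  set.seed(18)
  sigma <- 0.05
  err_for_sep <- function(L) {
    mean(replicate(2000, {
      a <- stats::rnorm(3, 0, sigma)
      b <- c(0, 0, L) + stats::rnorm(3, 0, sigma)
      angle_to_normal(b - a)$degrees
    }))
  }
  errs <- vapply(c(1, 2, 4) * 1.2, err_for_sep, numeric(1))
  expect_true(all(diff(errs) < 0))
})
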