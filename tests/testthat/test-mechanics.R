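# Viscoelastic element law, wall/anchor/freeze tethers, and the
# relaxation-time calibration.

test_that("element force follows the d0^2 E spring law", {
  d0 <- 8.33e-6; E <- 50
  # rest state: zero force
  expect_equal(element_force(c(0, 0), c(d0, 0), d0, d0, E), c(0, 0))
  # stretched to twice the rest length: magnitude d0^2 E, attractive
  f <- element_force(c(0, 0), c(2 * d0, 0), d0, d0, E)
  expect_equal(f, c(d0^2 * E, 0), tolerance = 1e-12)
  expect_true(f[1] > 0)  # pulls node m toward m'
  # swapping endpoints negates the force
  f2 <- element_force(c(2 * d0, 0), c(0, 0), d0, d0, E)
  expect_equal(f2, -f, tolerance = 1e-12)
  # compressed: repulsive
  fc <- element_force(c(0, 0), c(d0 / 2, 0), d0, d0, E)
  expect_true(fc[1] < 0)
  expect_error(element_force(c(1, 1), c(1, 1), d0, d0, E), "coincident")
})

test_that("internal element forces obey Newton's third law globally", {
  mesh <- small_semicircle()
  set.seed(5)
  mesh$pos <- mesh$pos + matrix(rnorm(2 * mesh$Q, sd = 5e-6), mesh$Q, 2)
  f <- element_forces_all(mesh, 50)
  scale <- max(abs(f))
  expect_lt(max(abs(colSums(f))) / scale, 1e-12)
})

test_that("rest-length update matches the dashpot law and its limits", {
  d0 <- 8.33e-6; E <- 50; eta <- 5e4
  # fixed point at current_length == d
  expect_equal(update_rest_length(d0, d0, d0, E, eta, 1e-3), d0)
  # stated increment at twice the rest length
  dn <- update_rest_length(d0, 2 * d0, d0, E, eta, 1e-3)
  # the increment is six orders below d0, so compare after cancellation
  expect_equal(dn - d0, (E * d0 / eta) * 1 * 1e-3, tolerance = 1e-9)
  expect_equal(dn - d0, 8.33e-12, tolerance = 1e-3)
  # infinite eta: purely elastic spring, rest length frozen
  expect_identical(update_rest_length(d0, 2 * d0, d0, E, Inf, 10), d0)
})

test_that("held at constant stretch, d relaxes to the length with the Maxwell timescale", {
  d0 <- 1e-5; E <- 50; eta <- 5e4; L <- 1.01e-5   # small gap: linear regime
  # fine-step numerical integration of the autonomous ODE as oracle
  oracle <- function(t_end, dt) {
    d <- d0
    for (i in seq_len(round(t_end / dt)))
      d <- d + dt * (E * d0 / eta) * (L / d - 1)
    d
  }
  tau <- eta * L / (E * d0)   # linearized decay time of (L - d)
  d_tau <- oracle(tau, tau / 5e4)
  # the gap L - d decays by 1/e at t = tau
  gap0 <- L - d0
  expect_equal((L - d_tau) / gap0, exp(-1), tolerance = 0.02)
  # coarse forward-Euler (the production path) agrees with the fine oracle
  d_coarse <- d0
  for (i in seq_len(1000))
    d_coarse <- update_rest_length(d_coarse, L, d0, E, eta, tau / 1000)
  expect_equal(d_coarse, d_tau, tolerance = 1e-3)
})

test_that("wall chain forces: tethers restore, neighbor springs cancel internally", {
  w <- wall_chain(1e-3, 2.5e-5, 0, A = 8.33e-2, B = 6.25e-2)
  expect_equal(max(abs(wall_forces(w))), 0)
  # displace one node vertically: tether contributes (0, -B delta)
  delta <- 1e-7
  w2 <- w; w2$pos[5, 2] <- delta
  f <- wall_forces(w2)
  tether <- w2$B * (w2$pos0[5, ] - w2$pos[5, ])
  expect_equal(tether, c(0, -w2$B * delta))
  # net force on a rigidly translated chain is -B * total displacement
  w3 <- w; w3$pos[, 1] <- w3$pos[, 1] + 3e-8
  f3 <- wall_forces(w3)
  expect_equal(colSums(f3), c(-w3$B * 3e-8 * nrow(w3$pos), 0),
               tolerance = 1e-12)
})

test_that("anchor forces act only on anchored nodes", {
  mesh <- single_triangle_mesh()
  expect_equal(max(abs(anchor_forces(mesh, 6.25e-2))), 0)
  mesh$pos[1, ] <- mesh$pos[1, ] + c(1e-7, 0)
  mesh$pos[3, ] <- mesh$pos[3, ] + c(5e-7, 5e-7)  # apex is not anchored
  f <- anchor_forces(mesh, 6.25e-2)
  expect_equal(f[1, ], c(-6.25e-2 * 1e-7, 0))
  expect_equal(f[3, ], c(0, 0))
})

test_that("freeze tethers release exactly at t_freeze (half-open)", {
  mesh <- single_triangle_mesh()
  mesh$pos[3, ] <- mesh$pos[3, ] + c(0, 2e-7)
  Dstiff <- 8.33e-2
  f_before <- freeze_forces(mesh, Dstiff, 5, 20)
  expect_equal(f_before[3, ], c(0, -Dstiff * 2e-7))
  expect_equal(max(abs(freeze_forces(mesh, Dstiff, 20, 20))), 0)
  expect_equal(max(abs(freeze_forces(mesh, Dstiff, 25, 20))), 0)
})

test_that("relaxation-time calibration inverts correctly", {
  expect_equal(dashpot_viscosity_for_tau(50, 1080, 1.02e3), 53490)
  # forward check: plug back in
  expect_equal(relaxation_time(50, 53490, 1.02e3), 1080)
  expect_equal(relaxation_time(50, 5e4, 1.02e3), 1010.2)
  expect_equal(dashpot_viscosity_for_tau(50, 1080, 0), 50 * 1080)
  expect_error(dashpot_viscosity_for_tau(1e-3, 1, 1.02e3), "unachievable")
  expect_identical(relaxation_time(50, Inf), Inf)
})
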