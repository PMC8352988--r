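# Monod kinetics, biomass bookkeeping, and the stochastic boundary
# triangle-spawning rule.

test_that("Monod rate saturates at mu_max with half-saturation at K", {
  mu_max <- 2e-4; K <- 1e-4
  expect_equal(monod_rate(0, mu_max, K), 0)
  expect_equal(monod_rate(K, mu_max, K), mu_max / 2)
  expect_equal(monod_rate(1e-3, mu_max, K), 2e-4 * (10 / 11))
  expect_equal(monod_rate(1e-3, mu_max, K), 1.818e-4, tolerance = 1e-3)
  cs <- seq(0, 1e-2, length.out = 50)
  expect_true(all(diff(monod_rate(cs, mu_max, K)) > 0))
  expect_true(all(monod_rate(cs, mu_max, K) < mu_max))
})

test_that("biomass increment is mean-rate times biomass times dt", {
  mesh <- list(Q = 637L, N = 1183L, m0 = 1.23e-14)
  dt <- 1e-3; mu_max <- 2e-4
  expect_equal(biomass_increment(mesh, rep(0, mesh$Q), dt), 0)
  dM <- biomass_increment(mesh, rep(mu_max, mesh$Q), dt)
  expect_equal(dM, mu_max * 1183 * 1.23e-14 * 1e-3, tolerance = 1e-12)
  expect_equal(dM, 2.91e-18, tolerance = 1e-2)
  # linear in dt and N
  expect_equal(biomass_increment(mesh, rep(mu_max, mesh$Q), 2 * dt), 2 * dM)
  mesh2 <- mesh; mesh2$N <- 2 * mesh$N
  expect_equal(biomass_increment(mesh2, rep(mu_max, mesh$Q), dt), 2 * dM)
})

test_that("spawn probabilities are Monod-weighted over the fluid boundary", {
  mesh <- small_semicircle()
  bnd <- boundary_nodes(mesh)
  k <- length(bnd$fluid)
  rates <- rep(1e-4, mesh$Q)
  sp <- spawn_probabilities(mesh, rates, bnd)
  expect_equal(sp$p, rep(1 / k, k))
  expect_false(sp$uniform_fallback)
  # one node with rate 3x among 5: gets 3/7 -- craft via direct weights
  rates2 <- rep(0, mesh$Q)
  rates2[bnd$fluid] <- 1e-4
  rates2[bnd$fluid[3]] <- 3e-4
  sp2 <- spawn_probabilities(mesh, rates2, bnd)
  expect_equal(sp2$p[3], 3 / (k + 2), tolerance = 1e-12)
  expect_equal(sum(sp2$p), 1)
  # all-zero rates fall back to uniform
  sp3 <- spawn_probabilities(mesh, rep(0, mesh$Q), bnd)
  expect_true(sp3$uniform_fallback)
  expect_equal(sum(sp3$p), 1)
})

test_that("inverse-CDF site sampling follows the cumulative-sum rule", {
  expect_equal(sample_spawn_site(c(1, 0, 0), 0.73), 1L)
  expect_equal(sample_spawn_site(rep(0.25, 4), 0.6), 3L)
  expect_equal(sample_spawn_site(rep(0.25, 4), 0.2), 1L)
  expect_equal(sample_spawn_site(rep(0.25, 4), 0.99), 4L)
  # empirical frequencies match p within 3-sigma multinomial bounds
  p <- c(0.5, 0.3, 0.15, 0.05)
  set.seed(12)
  n <- 1e5
  draws <- tabulate(vapply(runif(n), function(x) sample_spawn_site(p, x),
                           integer(1)), 4)
  sig <- sqrt(n * p * (1 - p))
  expect_true(all(abs(draws - n * p) < 3 * sig))
})

test_that("candidate triangles are isosceles with area exactly a0, outward", {
  mesh <- small_semicircle()
  bnd <- boundary_nodes(mesh)
  a0 <- mesh$a0
  for (site in bnd$fluid[c(2, 10, length(bnd$fluid) %/% 2)]) {
    cand <- construct_candidate(mesh, site, a0, bnd)
    expect_equal(cand$height, 2 * a0 / cand$base_length, tolerance = 1e-14)
    tri_area <- abs(polygon_signed_area(rbind(
      mesh$pos[cand$base[1], ], mesh$pos[cand$base[2], ], cand$apex)))
    expect_equal(tri_area, a0, tolerance = 1e-12)
    # apex on the fluid side: outside the current polygon
    poly <- mesh$pos[bnd$cycle, ]
    expect_false(points_in_polygon(cand$apex[1], cand$apex[2], poly))
    # isosceles: apex equidistant from the two base nodes
    d1 <- sqrt(sum((cand$apex - mesh$pos[cand$base[1], ])^2))
    d2 <- sqrt(sum((cand$apex - mesh$pos[cand$base[2], ])^2))
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("try_spawn outcomes update topology and preserve Euler's identity", {
  mesh <- small_semicircle()
  bnd <- boundary_nodes(mesh)
  euler <- function(m) m$Q - m$S + m$N
  # generic convex arc site: apex spawn adds one node, two edges, a triangle
  site <- bnd$fluid[length(bnd$fluid) %/% 2]
  cand <- construct_candidate(mesh, site, mesh$a0, bnd)
  res <- try_spawn(mesh, cand, epsilon_merge = 1e-9, wall_y = 0, bnd = bnd)
  expect_equal(res$outcome, "apex_spawned")
  expect_equal(res$mesh$Q, mesh$Q + 1L)
  expect_equal(res$mesh$S, mesh$S + 2L)
  expect_equal(res$mesh$N, mesh$N + 1L)
  expect_equal(euler(res$mesh), 1L)
  # ear fill: reposition the site's cycle successor onto the candidate
  # apex, so the notch (pred, site, succ) is closed by one new edge
  m2 <- mesh
  bnd2 <- boundary_nodes(m2)
  k <- match(site, bnd2$cycle)
  succ <- bnd2$cycle[k %% length(bnd2$cycle) + 1]
  cand2 <- construct_candidate(m2, site, m2$a0, bnd2)
  m2$pos[succ, ] <- cand2$apex + c(1e-7, 5e-8)
  r2 <- try_spawn(m2, cand2, epsilon_merge = 1e-5, wall_y = 0, bnd = bnd2)
  expect_equal(r2$outcome, "merged")
  expect_equal(r2$mesh$Q, m2$Q)
  expect_equal(r2$mesh$S, m2$S + 1L)
  expect_equal(r2$mesh$N, m2$N + 1L)
  expect_equal(euler(r2$mesh), 1L)
  # and the filled triangle uses the repositioned node, not a fresh one
  newtri <- r2$mesh$tri[r2$mesh$N, ]
  expect_setequal(newtri, c(cand2$base, succ))
  # a candidate whose apex would dip below the wall is rejected
  low <- bnd$fluid[1]   # first arc node next to the wall
  candw <- construct_candidate(mesh, low, mesh$a0, bnd)
  candw$apex[2] <- -1e-6
  resw <- try_spawn(mesh, candw, epsilon_merge = 1e-9, wall_y = 0, bnd = bnd)
  expect_equal(resw$outcome, "rejected")
})

test_that("growth_step floors the triangle count and carries the residue", {
  cfg <- preset_ci(E = 50, nutrient_config = "full")
  set.seed(2)
  mesh <- small_semicircle()
  led <- new_ledger(mesh)
  # no nutrient: nothing happens
  gs0 <- growth_step(mesh, led, matrix(0, cfg$Nx, cfg$Ny), cfg$dt, cfg)
  expect_equal(gs0$deltaM, 0)
  expect_equal(gs0$mesh$N, mesh$N)
  # craft delta_N + dM/m0 = 0.4 + 0.7: one spawn, residue 0.1
  mesh$delta_N <- 0.4
  cm <- matrix(cfg$K, cfg$Nx, cfg$Ny)        # Gamma = mu_max/2 everywhere
  dt <- 0.7 / ((cfg$mu_max / 2) * mesh$N)
  gs <- growth_step(mesh, led, cm, dt, cfg)
  expect_equal(gs$deltaM / mesh$m0, 0.7, tolerance = 1e-12)
  expect_equal(gs$spawned, 1L)
  expect_equal(gs$mesh$N, mesh$N + 1L)
  expect_equal(gs$mesh$delta_N, 0.1, tolerance = 1e-9)
  # ledger identity M = (N + delta_N) m0
  expect_equal(gs$ledger$M, (gs$mesh$N + gs$mesh$delta_N) * gs$mesh$m0,
               tolerance = 1e-12)
  expect_equal(gs$mesh$Q - gs$mesh$S + gs$mesh$N, 1L)
})

test_that("clamped uniform nutrient gives exponential biomass growth", {
  # twenty simulated minutes at the closed-form rate Gamma(c0)
  cfg <- preset_ci(E = 50, nutrient_config = "full")
  set.seed(4)
  mesh <- small_semicircle()
  led <- new_ledger(mesh)
  cm <- matrix(cfg$c0, cfg$Nx, cfg$Ny)
  M0 <- led$M
  dt <- 1
  for (i in seq_len(1200)) {
    gs <- growth_step(mesh, led, cm, dt, cfg)
    mesh <- gs$mesh; led <- gs$ledger
  }
  rate <- log(led$M / M0) / 1200
  expect_equal(rate, monod_rate(cfg$c0, cfg$mu_max, cfg$K), tolerance = 0.05)
  expect_equal(mesh$Q - mesh$S + mesh$N, 1L)
  expect_true(mesh$delta_N >= 0 && mesh$delta_N < 1)
})
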