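# Nutrient advection-diffusion-reaction and the source strip.

test_that("source strip covers the configured bottom-row cells", {
  cfg <- default_config(nutrient_config = "none")
  expect_length(build_source(cfg)$cells, 0)
  cfg <- default_config(nutrient_config = "full")
  s <- build_source(cfg)
  expect_length(s$cells, cfg$Nx)
  # all in grid row j = 2 (one grid width above the wall row)
  expect_true(all((s$cells - 1) %/% cfg$Nx == 1))
  # down and up strips are mirror images about the biofilm center
  cd <- default_config(nutrient_config = "down")
  cu <- default_config(nutrient_config = "up")
  xd <- ((build_source(cd)$cells - 1) %% cd$Nx) * cd$h
  xu <- ((build_source(cu)$cells - 1) %% cu$Nx) * cu$h
  ctr <- cd$biofilm_center_x
  expect_true(all(xd > ctr + cd$margin))
  expect_true(all(xu < ctr - cu$margin))
  expect_equal(length(xd), sum((0:(cd$Nx - 1)) * cd$h > ctr + cd$margin))
})

test_that("node concentrations average the four cell corners", {
  h <- 1e-4
  cmat <- matrix(0, 16, 12)
  # uniform field: every node sees the same value
  cmat[] <- 7e-4
  pts <- cbind(runif(5) * 15 * h, runif(5) * 11 * h)
  expect_equal(concentration_at_nodes(cmat, pts, h), rep(7e-4, 5))
  # node exactly on a grid point: its cell is the one on the lower-index
  # side; corners (0, 0, 0, 4) average to 1
  cmat[] <- 0
  cmat[5, 5] <- 4   # grid point (4h, 4h)
  val <- concentration_at_nodes(cmat, matrix(c(4 * h, 4 * h), 1), h)
  expect_equal(val, 1)
  # field linear in x: the average sits at the cell center, not the node
  cmat <- matrix((0:15) * h, 16, 12) * 3
  val <- concentration_at_nodes(cmat, matrix(c(6.2 * h, 3.5 * h), 1), h)
  expect_equal(val, 3 * 6.5 * h)   # cell [6h, 7h]: mean of corners
})

test_that("uptake region matches a brute-force winding-number oracle", {
  mesh <- small_semicircle()
  poly <- biofilm_polygon(mesh)
  Nx <- 40; Ny <- 26; h <- 1.25e-4
  reg <- uptake_region(Nx, Ny, h, poly)
  gg <- expand.grid(i = 0:(Nx - 1), j = 0:(Ny - 1))
  oracle <- winding_inside(gg$i * h, gg$j * h, poly)
  # compare away from the boundary curve, where on-edge conventions differ
  edist <- vapply(seq_len(nrow(gg)), function(q) {
    x <- gg$i[q] * h; y <- gg$j[q] * h
    x1 <- poly[, 1]; y1 <- poly[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    dx <- x2 - x1; dy <- y2 - y1
    tt <- pmin(pmax(((x - x1) * dx + (y - y1) * dy) /
                      pmax(dx^2 + dy^2, 1e-300), 0), 1)
    sqrt(min((x1 + tt * dx - x)^2 + (y1 + tt * dy - y)^2))
  }, numeric(1))
  clear <- edist > 1e-6 * h
  lin <- gg$i + Nx * gg$j + 1L
  expect_setequal(reg[reg %in% lin[clear]], lin[clear & oracle])
  # points lying on the boundary count as inside
  expect_true(all(lin[!clear] %in% reg))
  # cardinality is near area/h^2 and is translation invariant (periodic)
  area <- sum(triangle_areas(mesh$pos, mesh$tri))
  expect_gt(length(reg), 0.3 * area / h^2)
  expect_lt(length(reg), 3 * area / h^2)
  poly2 <- poly; poly2[, 1] <- poly2[, 1] + Nx * h
  expect_equal(length(uptake_region(Nx, Ny, h, poly2)), length(reg))
})

test_that("reaction field distributes demand by Monod weights", {
  cm <- matrix(0, 8, 8)
  K <- 1e-4; mu_max <- 2e-4; Y <- 0.553; h <- 1e-4; dt <- 1e-3
  expect_equal(max(abs(reaction_field(cm, 1:4, 0, dt, Y, mu_max, K, h))), 0)
  # uniform concentration: uniform uptake
  cm[] <- 5e-4
  r <- reaction_field(cm, 1:6, 3e-15, dt, Y, mu_max, K, h)
  expect_equal(length(unique(round(r[1:6], 20))), 1)
  expect_true(all(r[1:6] < 0))
  expect_equal(max(abs(r[7:64])), 0)
  # two cells at K and 3K split uptake 2:3
  cm[] <- 0; cm[1] <- K; cm[2] <- 3 * K
  r <- reaction_field(cm, 1:2, 3e-15, dt, Y, mu_max, K, h)
  expect_equal(r[1] / r[2], (1 / 2) / (3 / 4), tolerance = 1e-12)
  # discrete mass balance: sum r h^2 dt = -deltaM / Y
  expect_equal(sum(r) * h^2 * dt, -3e-15 / Y, tolerance = 1e-12)
  expect_error(reaction_field(cm, integer(0), 1e-15, dt, Y, mu_max, K, h),
               "empty")
})

test_that("transport conserves mass without source or reaction", {
  set.seed(9)
  Nx <- 32; Ny <- 32; h <- 1e-4
  cm <- matrix(0, Nx, Ny); cm[10, 12] <- 1e-3   # point release
  u <- matrix(2e-6 * runif(Nx * Ny), Nx, Ny)
  v <- matrix(-1e-6 * runif(Nx * Ny), Nx, Ny)
  m0 <- sum(cm) * h^2
  for (i in 1:1000) cm <- adr_step(cm, u, v, 1e-2, 1e-10, h)$c
  expect_equal(sum(cm) * h^2, m0, tolerance = 1e-12)
  expect_true(all(cm >= 0))
  # uniform field with no reaction is a fixed point
  cu <- matrix(4e-4, Nx, Ny)
  out <- adr_step(cu, u * 0, v * 0, 1e-2, 1e-10, h)$c
  expect_equal(out, cu)
})

test_that("advection transports a bump at the flow speed", {
  Nx <- 64; Ny <- 8; h <- 1e-4
  x <- (0:(Nx - 1)) * h
  cm <- matrix(exp(-((x - 16 * h) / (4 * h))^2), Nx, Ny)
  uconst <- 1e-4
  u <- matrix(uconst, Nx, Ny); v <- matrix(0, Nx, Ny)
  dt <- 0.5   # CFL = 0.5
  nsteps <- 40
  for (i in seq_len(nsteps)) cm <- adr_step(cm, u, v, dt, 0, h)$c
  # center of mass displaced by u t within one cell
  xc <- sum(x * cm[, 1]) / sum(cm[, 1])
  expect_equal(xc, 16 * h + uconst * dt * nsteps, tolerance = h)
  # first-order upwind diffuses but must preserve positivity and mass
  expect_true(all(cm >= 0))
})

test_that("stability violations refuse to step with diagnostics", {
  cm <- matrix(1e-3, 8, 8); u <- matrix(1, 8, 8)
  expect_error(adr_step(cm, u, u * 0, 1, 1e-10, 1e-4), "CFL")
  expect_error(adr_step(cm, u * 0, u * 0, 1, 1e-5, 1e-4), "diffusive")
})

test_that("source clamp holds strip cells at c0", {
  cfg <- default_config(nutrient_config = "full")
  src <- build_source(cfg)
  cm <- matrix(0, cfg$Nx, cfg$Ny)
  u <- matrix(0, cfg$Nx, cfg$Ny)
  out <- adr_step(cm, u, u, cfg$dt, cfg$D_c, cfg$h, source = src)$c
  expect_equal(unique(out[src$cells]), cfg$c0)
})
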