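# Semicircular mesh generation and topology queries.

test_that("full-scale semicircle mesh matches the expected geometry", {
  m <- generate_semicircle_mesh(1.5e-4, 8.33e-6, 5e-3)
  # disk-like triangulation: Euler characteristic 1
  expect_equal(m$Q - m$S + m$N, 1L)
  # triangle count within 15% of the reference mesh (1183 triangles);
  # exact counts are generator-dependent, the identity above is exact
  expect_lt(abs(m$N - 1183) / 1183, 0.15)
  # average triangle area and per-triangle biomass
  expect_equal(m$a0, (pi * 1.5e-4^2 / 2) / m$N)
  expect_equal(m$m0, 1120 * 1.75e-18 * 2.1e17 * 1e-6 * m$a0)
  # mesh quality: worst radius ratio above 0.3
  expect_gt(min(mesh_quality(m)), 0.3)
  # flat edge on y = 0, marked anchored
  expect_true(all(m$pos[m$anchored, 2] == 0))
  expect_gt(sum(m$anchored), 10)
  # polygon area equals summed triangle area and the half-disk area
  poly <- biofilm_polygon(m)
  expect_equal(polygon_signed_area(poly),
               sum(triangle_areas(m$pos, m$tri)), tolerance = 1e-9)
  expect_equal(polygon_signed_area(poly), pi * 1.5e-4^2 / 2,
               tolerance = 0.01)
  # area-weighted centroid at the half-disk closed form (cx, 4r/(3pi))
  com <- center_of_mass(m)
  expect_equal(com[1], 5e-3, tolerance = 1e-3 * 1.5e-4)
  expect_equal(com[2], 4 * 1.5e-4 / (3 * pi), tolerance = 0.01)
  expect_error(generate_semicircle_mesh(1e-5, 8.33e-6, 0), "r_c")
})

test_that("mesh generation is deterministic", {
  m1 <- generate_semicircle_mesh(3.6e-4, 1.25e-4 / 3, 2.5e-3)
  m2 <- generate_semicircle_mesh(3.6e-4, 1.25e-4 / 3, 2.5e-3)
  expect_identical(m1$pos, m2$pos)
  expect_identical(m1$tri, m2$tri)
})

test_that("boundary cycle is CCW from the downstream-most anchored node", {
  m <- small_semicircle()
  bnd <- boundary_nodes(m)
  # starts at the anchored node with the largest x
  anchored_x <- m$pos[m$anchored, 1]
  expect_equal(m$pos[bnd$cycle[1], 1], max(anchored_x))
  expect_true(m$anchored[bnd$cycle[1]])
  # counterclockwise: positive signed area
  expect_gt(polygon_signed_area(m$pos[bnd$cycle, ]), 0)
  # fluid-contact set: exactly the non-anchored boundary (arc) nodes
  expect_true(all(!m$anchored[bnd$fluid]))
  expect_setequal(bnd$fluid, setdiff(bnd$cycle, which(m$anchored)))
  # the arc nodes all sit near radius r_c
  rr <- sqrt((m$pos[bnd$fluid, 1] - 2.5e-3)^2 + m$pos[bnd$fluid, 2]^2)
  expect_true(all(abs(rr - 3.6e-4) < 0.1 * 3.6e-4))
})

test_that("single-triangle meshes expose the expected boundary and centroid", {
  m <- single_triangle_mesh()
  bnd <- boundary_nodes(m)
  expect_length(bnd$cycle, 3)
  expect_length(bnd$fluid, 1)      # only the apex touches the fluid
  expect_false(m$anchored[bnd$fluid])
  rt <- right_triangle_mesh()
  expect_equal(polygon_signed_area(biofilm_polygon(rt)), 0.5)
  expect_equal(center_of_mass(rt), colMeans(rt$pos))
  expect_equal(nrow(biofilm_polygon(rt)), 3)
})

test_that("center of mass is translation-equivariant", {
  m <- small_semicircle()
  com <- center_of_mass(m)
  m2 <- m
  m2$pos[, 1] <- m2$pos[, 1] + 1.5e-3
  m2$pos[, 2] <- m2$pos[, 2] + 2e-4
  expect_equal(center_of_mass(m2), com + c(1.5e-3, 2e-4), tolerance = 1e-12)
})

test_that("corrupt topology is reported", {
  m <- single_triangle_mesh()
  m$tri <- m$tri[0, , drop = FALSE]   # no triangles, no boundary
  expect_error(boundary_nodes(m), "boundary")
})
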