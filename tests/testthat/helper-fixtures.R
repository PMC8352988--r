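# Shared fixtures: tiny hand-made meshes and small configurations.

# single CCW triangle with the bottom side on y = 0 (anchored)
single_triangle_mesh <- function(kind = "stokes", side = 1) {
  pos <- rbind(c(0, 0), c(side, 0), c(side / 2, side * sqrt(3) / 2))
  mesh_from_triangulation(pos, matrix(c(1, 2, 3), 1), kind = kind)
}

# unit right triangle (legs on the axes)
right_triangle_mesh <- function() {
  pos <- rbind(c(0, 0), c(1, 0), c(0, 1))
  mesh_from_triangulation(pos, matrix(c(1, 2, 3), 1), kind = "stokes")
}

# small semicircular mesh at the reduced-preset scale (fast to build)
small_semicircle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_semicircle_mesh(3.6e-4, 1.25e-4 / 3, 2.5e-3)
    cache
  }
})

# independent point-in-polygon oracle: winding number via angle summation
winding_inside <- function(px, py, poly) {
  vapply(seq_along(px), function(q) {
    dx <- poly[, 1] - px[q]; dy <- poly[, 2] - py[q]
    if (any(dx^2 + dy^2 < 1e-24)) return(TRUE)   # on a vertex
    a <- atan2(dy, dx)
    da <- diff(c(a, a[1]))
    da <- ((da + pi) %% (2 * pi)) - pi
    abs(sum(da)) > pi
  }, logical(1))
}
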