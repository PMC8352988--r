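# Output writers: trajectory CSV (full precision, round-trip safe) and mesh
# snapshots in legacy ASCII VTK, with the concentration grid in a companion
# structured-points file. Snapshots are sufficient to restart analysis
# (geometry, connectivity, rest lengths, concentration), not the dynamics.

#' Write a trajectory to CSV
#'
#' Columns t, com_x, com_y, M, Q, S, N, consumed; values printed with 17
#' significant digits so a read-back reproduces them exactly.
#'
#' @param records trajectory data.frame from \code{\link{run_simulation}}.
#' @param path output file.
#' @export
write_trajectory <- function(records, path) {
  cols <- c("t", "com_x", "com_y", "M", "Q", "S", "N", "consumed")
  if (is.null(records) || nrow(records) == 0)
    stop("write_trajectory: empty record sequence")
  if (!all(cols %in% names(records)))
    stop("write_trajectory: records lack required columns")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  body <- do.call(paste, c(lapply(cols, function(cl)
    sprintf("%.17g", records[[cl]])), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path file written by \code{\link{write_trajectory}}.
#' @return trajectory data.frame.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write a mesh snapshot (legacy ASCII VTK)
#'
#' Writes the biofilm as a VTK unstructured grid: node coordinates, the
#' viscoelastic elements as line cells followed by the triangles, with the
#' creation and current rest lengths as cell data (triangles carry -1).
#' When an Eulerian field is supplied, its concentration grid goes to a
#' companion \code{<path>_conc.vtk} structured-points file.
#'
#' @param mesh a \code{biofilm_mesh}.
#' @param path output file (conventionally ending in .vtk).
#' @param field optional \code{eulerian_field} whose concentration is
#'   snapshotted alongside.
#' @export
write_mesh_snapshot <- function(mesh, path, field = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  Q <- mesh$Q; S <- mesh$S; N <- mesh$N
  writeLines(c("# vtk DataFile Version 3.0",
               "biofilm mesh snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", Q, "double")), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$pos[, 1], mesh$pos[, 2]), con)
  writeLines(paste("CELLS", S + N, 3 * S + 4 * N), con)
  writeLines(sprintf("2 %d %d", mesh$edges[, 1] - 1L, mesh$edges[, 2] - 1L),
             con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(paste("CELL_TYPES", S + N), con)
  writeLines(as.character(c(rep(3L, S), rep(5L, N))), con)
  writeLines(c(paste("CELL_DATA", S + N),
               "SCALARS rest_length_initial double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.17g", c(mesh$d0, rep(-1, N))), con)
  writeLines(c("SCALARS rest_length double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.17g", c(mesh$d, rep(-1, N))), con)
  writeLines(c(paste("POINT_DATA", Q), "SCALARS anchored int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$anchored)), con)
  if (!is.null(field)) {
    cpath <- sub("\\.vtk$", "", path)
    cpath <- paste0(cpath, "_conc.vtk")
    cc <- file(cpath, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 "concentration grid", "ASCII",
                 "DATASET STRUCTURED_POINTS",
                 paste("DIMENSIONS", field$Nx, field$Ny, 1),
                 sprintf("ORIGIN 0 0 0"),
                 sprintf("SPACING %.17g %.17g 1", field$h, field$h),
                 paste("POINT_DATA", field$Nx * field$Ny),
                 "SCALARS concentration double 1",
                 "LOOKUP_TABLE default"), cc)
    # VTK structured points vary x fastest
    writeLines(sprintf("%.17g", as.vector(field$c)), cc)
    close(cc)
  }
  invisible(path)
}

#' Read a mesh snapshot written by \code{\link{write_mesh_snapshot}}
#'
#' Reconstructs a \code{biofilm_mesh} sufficient for geometric analysis
#' (positions, elements with rest lengths, triangles, anchored flags).
#'
#' @param path snapshot file.
#' @return a \code{biofilm_mesh}.
#' @export
read_mesh_snapshot <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)
  Q <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pos <- do.call(rbind, lapply(ln[(ip + 1):(ip + Q)], function(s)
    as.numeric(strsplit(s, " ")[[1]][1:2])))
  ic <- grep("^CELLS", ln)
  ncell <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cells <- strsplit(ln[(ic + 1):(ic + ncell)], " ")
  sizes <- vapply(cells, function(x) as.integer(x[1]), integer(1))
  edges <- do.call(rbind, lapply(cells[sizes == 2], function(x)
    as.integer(x[2:3]) + 1L))
  tri <- do.call(rbind, lapply(cells[sizes == 3], function(x)
    as.integer(x[2:4]) + 1L))
  S <- nrow(edges); N <- nrow(tri)
  id0 <- grep("SCALARS rest_length_initial", ln)
  d0 <- as.numeric(ln[(id0 + 2):(id0 + 1 + S)])
  id1 <- grep("SCALARS rest_length ", ln)
  d <- as.numeric(ln[(id1 + 2):(id1 + 1 + S)])
  ia <- grep("SCALARS anchored", ln)
  anchored <- as.integer(ln[(ia + 2):(ia + 1 + Q)]) == 1L
  mesh <- list(pos = pos, pos0 = pos, edges = edges, d0 = d0, d = d,
               kind = rep("maxwell", S), tri = tri, anchored = anchored,
               Q = Q, S = S, N = N, delta_N = 0,
               a0 = mean(triangle_areas(pos, tri)), m0 = NA_real_)
  class(mesh) <- "biofilm_mesh"
  mesh
}
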