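heightfield_triangles <- function(grid) {
  n <- length(grid$x); m <- length(grid$z)
  idx <- function(i, j) (j - 1L) * n + i  # 1-based vertex index
  i <- rep(seq_len(n - 1L), times = m - 1L)
  j <- rep(seq_len(m - 1L), each = n - 1L)
  rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
        cbind(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
}

heightfield_vertices <- function(grid) {
  cbind(x = rep(grid$x, times = length(grid$z)),
        y = as.vector(grid$height),
        z = rep(grid$z, each = length(grid$x)))
}

#' Export a surface grid as a triangulated mesh or lattice table
#'
#' \code{write_surface_ply} writes ASCII PLY, \code{write_surface_vtk}
#' legacy-VTK polydata, \code{write_surface_csv} the raw lattice with
#' columns \code{x, z, height, area}. Mesh vertices are ordered
#' x-fastest; the height is the mesh y coordinate.
#'
#' @param grid a \code{surface_grid}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_surface_ply <- function(grid, path) {
  v <- heightfield_vertices(grid)
  f <- heightfield_triangles(grid) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(v, trim = TRUE, digits = 9), 1L, paste,
                   collapse = " "), con)
  writeLines(paste(3L, f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' @rdname write_surface_ply
#' @export
write_surface_vtk <- function(grid, path) {
  v <- heightfield_vertices(grid)
  f <- heightfield_triangles(grid) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "height-field surface",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(v), "float")), con)
  writeLines(apply(format(v, trim = TRUE, digits = 9), 1L, paste,
                   collapse = " "), con)
  writeLines(paste("POLYGONS", nrow(f), nrow(f) * 4L), con)
  writeLines(paste(3L, f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' @rdname write_surface_ply
#' @export
write_surface_csv <- function(grid, path) {
  df <- data.frame(x = rep(grid$x, times = length(grid$z)),
                   z = rep(grid$z, each = length(grid$x)),
                   height = as.vector(grid$height),
                   area = as.vector(grid$nodal_area))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
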