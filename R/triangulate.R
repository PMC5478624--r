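#' Delaunay triangulation of a nadir point cloud
#'
#' Triangulates the cloud over its (X, Y) footprint with the Delaunay
#' criterion and lifts the triangles to Z, producing the surface mesh used for
#' visual export. All statistics in the package are computed on the raster
#' grid; the mesh is an export artifact only.
#'
#' @param cloud A [point_cloud()].
#' @return An object of class `surface_mesh`: list with `vertices` (n x 3
#'   matrix, mm) and `faces` (m x 3 integer matrix of 1-based vertex indices).
#' @examples
#' pc <- point_cloud(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), c(800, 800, 800, 800)))
#' mesh <- triangulate(pc)
#' nrow(mesh$faces)  # 2
#' @export
triangulate <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  if (nrow(p) < 3) stop("degenerate triangulation: need at least 3 points")
  dd <- tryCatch(
    suppressMessages(deldir::deldir(p[, 1], p[, 2], round = FALSE)),
    error = function(e) stop("degenerate triangulation: ", conditionMessage(e)))
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0) stop("degenerate triangulation: points are collinear")
  faces <- t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
  structure(list(vertices = p, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}
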