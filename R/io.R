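# Readers/writers for the on-disk formats: 16-bit grayscale PNG depth maps
# (value = depth in mm, 0 = hole), NPY array containers, ASCII PLY clouds and
# meshes, and JSON/YAML intrinsics sidecars.

png_chunk <- function(type, data = raw(0)) {
  payload <- c(charToRaw(type), data)
  crc <- digest::digest(payload, algo = "crc32", serialize = FALSE)
  crc <- gsub(" ", "0", sprintf("%8s", crc))  # zero-pad to 8 hex digits
  c(writeBin(length(data), raw(), size = 4, endian = "big"),
    payload,
    as.raw(strtoi(substring(crc, seq(1, 7, 2), seq(2, 8, 2)), 16L)))
}

#' Write a depth matrix as 16-bit grayscale PNG
#'
#' Pixel value = depth in mm (rounded to integer, clipped to 0..65535);
#' 0 marks a hole. png::writePNG only emits 8-bit files, so the 16-bit
#' encoding is done directly (zlib-compressed scanlines with CRC32 chunks);
#' the result is a standard PNG readable by any PNG reader.
#'
#' @param depth A [depth_image()] or numeric matrix of depths, mm.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path) {
  m <- if (inherits(depth, "depth_image")) depth$values else as.matrix(depth)
  m <- round(m)
  m[m < 0] <- 0; m[m > 65535] <- 65535
  w <- ncol(m); h <- nrow(m)
  ihdr <- c(writeBin(c(w, h), raw(), size = 4, endian = "big"),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit, grayscale
  # scanlines: filter byte 0 + big-endian uint16 per pixel, row-major
  v <- as.integer(t(m))
  bytes <- matrix(as.raw(0), nrow = 1 + 2 * w, ncol = h)
  px <- matrix(c(as.raw(v %/% 256L), as.raw(v %% 256L)), nrow = 2, byrow = TRUE)
  bytes[-1, ] <- matrix(as.vector(px), nrow = 2 * w)
  idat <- memCompress(as.vector(bytes), type = "gzip")
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}

#' Read a 16-bit depth PNG into a depth image
#'
#' @param path PNG file path (pixel value = depth, mm; 0 = hole).
#' @param intrinsics Optional [camera_intrinsics()]; when `NULL` the sidecar
#'   (same path with extension `.json` or `.yaml`) is consulted, and failing
#'   that the package's Kinect-v1 defaults are used with a warning.
#' @param camera_height_mm Camera mounting height; overridden by the sidecar
#'   if present.
#' @return A [depth_image()].
#' @export
read_depth_png <- function(path, intrinsics = NULL, camera_height_mm = 800) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- round(img * 65535)
  if (is.null(intrinsics)) {
    sc <- read_intrinsics_sidecar(sidecar_path(path))
    if (!is.null(sc)) {
      intrinsics <- sc$intrinsics
      if (!is.null(sc$camera_height_mm)) camera_height_mm <- sc$camera_height_mm
    } else {
      warning("no intrinsics sidecar found for ", basename(path),
              "; using Kinect-v1 defaults")
    }
  }
  depth_image(m, intrinsics, camera_height_mm = camera_height_mm)
}

sidecar_path <- function(path) {
  base <- sub("\\.[^.]+$", "", path)
  for (ext in c(".json", ".yaml", ".yml")) {
    p <- paste0(base, ext)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Write an intrinsics sidecar (JSON or YAML by extension)
#'
#' @param intrinsics A [camera_intrinsics()].
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @param camera_height_mm Camera mounting height to record.
#' @return `path`, invisibly.
#' @export
write_intrinsics_sidecar <- function(intrinsics, path, camera_height_mm = 800) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  obj <- list(fx = intrinsics$fx, fy = intrinsics$fy,
              cx = intrinsics$cx, cy = intrinsics$cy,
              width = intrinsics$width, height = intrinsics$height,
              camera_height_mm = camera_height_mm)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

read_intrinsics_sidecar <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NULL)
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  list(intrinsics = camera_intrinsics(obj$fx, obj$fy, obj$cx, obj$cy,
                                      obj$width, obj$height),
       camera_height_mm = obj$camera_height_mm)
}

#' Write a 2D numeric matrix as an NPY array container
#'
#' Minimal NPY v1.0 writer for 2D arrays, dtype `<f8` (little-endian double),
#' C order.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(m, path) {
  m <- as.matrix(m)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  pad <- (64 - (10 + nchar(header) + 1) %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a 2D NPY array container
#'
#' Supports v1.0/v2.0 headers with dtypes `<f8`, `<f4`, `<u2`, `<i4`, `<i8`
#' (little-endian), C or Fortran order.
#'
#' @param path NPY file path.
#' @return Numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape <- as.integer(strsplit(gsub("[^0-9,]", "",
                                    sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1",
                                        header)), ",")[[1]])
  if (length(shape) != 2) stop("only 2D NPY arrays are supported")
  n <- prod(shape)
  v <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<u2" = readBin(con, "integer", n, size = 2, endian = "little",
                    signed = FALSE),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported NPY dtype: ", descr))
  if (fortran) matrix(v, shape[1], shape[2])
  else t(matrix(v, shape[2], shape[1]))
}

#' Export a point cloud or mesh as ASCII PLY
#'
#' Vertices in mm; meshes additionally carry triangular faces.
#'
#' @param x A [point_cloud()] or a `surface_mesh` from [triangulate()].
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "point_cloud")) {
    verts <- x$points; faces <- NULL
  } else if (inherits(x, "surface_mesh")) {
    verts <- x$vertices; faces <- x$faces
  } else stop("write_ply needs a point_cloud or surface_mesh")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               if (!is.null(faces)) c(sprintf("element face %d", nrow(faces)),
                                      "property list uchar int vertex_indices"),
               "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g", verts[, 1], verts[, 2], verts[, 3]), con)
  if (!is.null(faces))
    writeLines(sprintf("3 %d %d %d",
                       faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}

#' Export a surface decomposition to disk
#'
#' Writes the basal and block components as 16-bit PNG height maps (0.1 mm
#' per level, block residual offset by +3276.8 mm so negative residuals are
#' representable) plus a JSON metadata file recording the scale, offset,
#' filter scale and reference-plane coefficients.
#'
#' @param decomposition A [decompose_surface()] result.
#' @param dir Output directory (created if needed).
#' @param plane Optional [reference_plane()] recorded in the metadata.
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
export_decomposition <- function(decomposition, dir, plane = NULL,
                                 prefix = "surface") {
  stopifnot(inherits(decomposition, "surface_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- 10  # levels per mm
  offset <- 32768 / scale
  enc <- function(f, off) {
    z <- f$z; z[!f$valid] <- NA
    m <- (z + off) * scale
    m[is.na(m)] <- 0
    m
  }
  p_basal <- file.path(dir, paste0(prefix, "_basal.png"))
  p_block <- file.path(dir, paste0(prefix, "_block.png"))
  p_meta <- file.path(dir, paste0(prefix, "_decomposition.json"))
  write_depth_png(enc(decomposition$basal, 0), p_basal)
  write_depth_png(enc(decomposition$block, offset), p_block)
  jsonlite::write_json(
    list(scale_levels_per_mm = scale, block_offset_mm = offset,
         sigma_frac = decomposition$sigma_frac,
         sigma_px = decomposition$sigma_px,
         plane = if (!is.null(plane)) list(a = plane$a, b = plane$b,
                                           c = plane$c)),
    p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(basal = p_basal, block = p_block, metadata = p_meta))
}
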