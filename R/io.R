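#' Read and write binary STL surface meshes
#'
#' @param mesh A `surface_mesh`.
#' @param path File path.
#' @return `read_stl` returns a `surface_mesh` (vertices deduplicated
#'   exactly).
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "aneumorph binary STL"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  n <- mesh_face_normals(mesh)
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  block <- rbind(t(n), t(a), t(b), t(c))      # 12 floats per face
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", nf * 50)
  m <- matrix(raw, nrow = 50)
  floats <- readBin(as.vector(m[1:48, ]), "numeric", nf * 12, size = 4,
                    endian = "little")
  tri <- matrix(floats, ncol = 12, byrow = TRUE)
  pts <- rbind(tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE],
               tri[, 10:12, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- pts[uk, , drop = FALSE]
  faces <- cbind(vid[seq_len(nf)], vid[nf + seq_len(nf)],
                 vid[2 * nf + seq_len(nf)])
  surface_mesh(verts, faces)
}

#' Write a mesh plus its region labels and neck curve
#'
#' STL cannot carry labels, so a labeled mesh is stored as an STL file
#' plus a JSON sidecar (`<stem>_labels.json`) holding the per-face region
#' labels and the neck curve.
#'
#' @param mesh A `surface_mesh` or `labeled_surface_mesh`.
#' @param stem Output path without extension.
#' @return Invisibly, the written paths.
#' @export
write_mesh_bundle <- function(mesh, stem) {
  stl <- paste0(stem, ".stl")
  write_stl(mesh, stl)
  paths <- stl
  if (inherits(mesh, "labeled_surface_mesh")) {
    side <- paste0(stem, "_labels.json")
    jsonlite::write_json(list(
      face_region = as.character(mesh$face_region),
      neck_curve = mesh$neck_curve), side, digits = NA, auto_unbox = TRUE)
    paths <- c(paths, side)
  }
  invisible(paths)
}

#' @rdname write_mesh_bundle
#' @export
read_mesh_bundle <- function(stem) {
  mesh <- read_stl(paste0(stem, ".stl"))
  side <- paste0(stem, "_labels.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    mesh <- labeled_surface_mesh(mesh, meta$face_region,
                                 if (!is.null(meta$neck_curve))
                                   matrix(unlist(meta$neck_curve),
                                          ncol = 3) else NULL)
  }
  mesh
}

#' Read and write image volumes (NIfTI or MetaImage)
#'
#' NIfTI files go through RNifti; `.mha` MetaImage files (uncompressed,
#' local raw, float64) use a minimal reader/writer. The voxel-to-world
#' convention is world = origin + index * spacing (0-based indices).
#'
#' @param vol An `image_volume`.
#' @param path Destination ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `read_volume` returns an `image_volume`.
#' @export
write_volume <- function(vol, path) {
  if (grepl("\\.mha$", path)) {
    d <- dim(vol$data)
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             "CompressedData = False",
             "TransformMatrix = 1 0 0 0 1 0 0 0 1",
             paste("Offset =", paste(vol$origin, collapse = " ")),
             paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
             paste("DimSize =", paste(d, collapse = " ")),
             "ElementType = MET_DOUBLE",
             "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  } else {
    im <- RNifti::asNifti(vol$data)
    xf <- diag(c(vol$spacing, 1))
    xf[1:3, 4] <- vol$origin
    RNifti::qform(im) <- structure(xf, code = 2L)
    RNifti::pixdim(im) <- vol$spacing
    RNifti::writeNifti(im, path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.mha$", path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character()
    repeat {
      line <- readLines(con, n = 1)
      hdr <- c(hdr, line)
      if (grepl("^ElementDataFile", line)) break
    }
    gv <- function(key) {
      ln <- grep(paste0("^", key, " ="), hdr, value = TRUE)
      as.numeric(strsplit(sub(".*= *", "", ln), " +")[[1]])
    }
    d <- gv("DimSize")
    dat <- readBin(con, "numeric", prod(d), size = 8, endian = "little")
    image_volume(array(dat, d), gv("ElementSpacing"), gv("Offset"))
  } else {
    im <- RNifti::readNifti(path)
    xf <- RNifti::xform(im)
    image_volume(array(as.numeric(im), dim(im)),
                 spacing = RNifti::pixdim(im)[1:3],
                 origin = xf[1:3, 4])
  }
}

#' Read and write inlet waveforms as CSV
#'
#' Two columns: `t_seconds`, `q_mm3_per_s`.
#'
#' @param wave A `waveform`.
#' @param path CSV path.
#' @return `read_waveform_csv` returns a `waveform`.
#' @export
write_waveform_csv <- function(wave, path) {
  write.csv(data.frame(t_seconds = wave$times,
                       q_mm3_per_s = wave$flow_rates),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- read.csv(path)
  waveform(df$t_seconds, df$q_mm3_per_s)
}

#' Write and read a WSS field as per-timestep VTK files plus a manifest
#'
#' Each timestep becomes one legacy-VTK ASCII polydata file carrying the
#' mesh and a `wss` POINT_DATA vector array; a JSON manifest records the
#' period, timestep list and cycle landmarks.
#'
#' @param field A `wss_field`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return `read_wss_field` returns a `wss_field` (unlabeled mesh unless a
#'   label sidecar `stem_labels.json` is present in `dir`).
#' @export
write_wss_field <- function(field, dir, stem = "wss") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(field$times))
  for (k in seq_along(field$times)) {
    f <- file.path(dir, sprintf("%s_t%03d.vtk", stem, k - 1))
    write_vtk_polydata(field$mesh, f,
                       point_vectors = list(wss = field$vectors[, , k]))
    files[k] <- basename(f)
  }
  manifest <- list(period = max(field$times), times = field$times,
                   files = files, t_peak_systole = field$t_peak_systole,
                   t_end_diastole = field$t_end_diastole)
  mf <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, mf, digits = NA, auto_unbox = TRUE)
  if (inherits(field$mesh, "labeled_surface_mesh"))
    jsonlite::write_json(list(face_region = as.character(field$mesh$face_region),
                              neck_curve = field$mesh$neck_curve),
                         file.path(dir, paste0(stem, "_labels.json")),
                         digits = NA, auto_unbox = TRUE)
  invisible(mf)
}

#' @rdname write_wss_field
#' @export
read_wss_field <- function(dir, stem = "wss") {
  mf <- jsonlite::read_json(file.path(dir, paste0(stem, "_manifest.json")),
                            simplifyVector = TRUE)
  first <- read_vtk_polydata(file.path(dir, mf$files[1]))
  mesh <- first$mesh
  side <- file.path(dir, paste0(stem, "_labels.json"))
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    mesh <- labeled_surface_mesh(mesh, meta$face_region,
                                 if (!is.null(meta$neck_curve))
                                   matrix(unlist(meta$neck_curve), ncol = 3)
                                 else NULL)
  }
  nt <- length(mf$files)
  vec <- array(0, c(nrow(mesh$vertices), 3, nt))
  vec[, , 1] <- first$point_vectors$wss
  for (k in seq_len(nt)[-1])
    vec[, , k] <- read_vtk_polydata(file.path(dir, mf$files[k]))$point_vectors$wss
  wss_field(mesh, mf$times, vec, mf$t_peak_systole, mf$t_end_diastole)
}

#' Minimal legacy-VTK ASCII polydata writer/reader
#'
#' Writes POINTS, POLYGONS and optional POINT_DATA VECTORS/SCALARS blocks.
#'
#' @param mesh A `surface_mesh`.
#' @param path Destination `.vtk` path.
#' @param point_vectors Named list of n x 3 matrices.
#' @param point_scalars Named list of numeric vectors.
#' @return `read_vtk_polydata` returns a list with `mesh`, `point_vectors`,
#'   `point_scalars`.
#' @export
write_vtk_polydata <- function(mesh, path, point_vectors = list(),
                               point_scalars = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "aneumorph surface data",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4 * nf), con)
  write(t(cbind(3L, mesh$faces - 1L)), con, ncolumns = 4)
  if (length(point_vectors) || length(point_scalars))
    writeLines(sprintf("POINT_DATA %d", nv), con)
  for (nm in names(point_vectors)) {
    writeLines(sprintf("VECTORS %s double", nm), con)
    pv <- point_vectors[[nm]]
    writeLines(sprintf("%.17g %.17g %.17g", pv[, 1], pv[, 2], pv[, 3]), con)
  }
  for (nm in names(point_scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", point_scalars[[nm]]), con)
  }
  invisible(path)
}

#' @rdname write_vtk_polydata
#' @export
read_vtk_polydata <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  nums <- scan(text = lines[(ip + 1):length(lines)], what = numeric(),
               n = 3 * nv, quiet = TRUE)
  verts <- matrix(nums, ncol = 3, byrow = TRUE)
  ifc <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(lines[ifc], " +")[[1]][2])
  fn <- scan(text = lines[(ifc + 1):length(lines)], what = integer(),
             n = 4 * nf, quiet = TRUE)
  fm <- matrix(fn, ncol = 4, byrow = TRUE)
  mesh <- surface_mesh(verts, fm[, 2:4, drop = FALSE] + 1L)
  pv <- list(); ps <- list()
  for (iv in grep("^VECTORS", lines)) {
    nm <- strsplit(lines[iv], " +")[[1]][2]
    vals <- scan(text = lines[(iv + 1):length(lines)], what = numeric(),
                 n = 3 * nv, quiet = TRUE)
    pv[[nm]] <- matrix(vals, ncol = 3, byrow = TRUE)
  }
  for (is_ in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[is_], " +")[[1]][2]
    vals <- scan(text = lines[(is_ + 2):length(lines)], what = numeric(),
                 n = nv, quiet = TRUE)
    ps[[nm]] <- vals
  }
  list(mesh = mesh, point_vectors = pv, point_scalars = ps)
}

# md5 of a serialized R object (for provenance stamps)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
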