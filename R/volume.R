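#' 3-D scalar image volume
#'
#' A 3-D intensity array with anisotropic voxel spacing and a world origin.
#' Voxels are cell-centred: world = origin + (index - 1) * spacing, with
#' 1-based array indices, so `origin` is the world position of voxel
#' (1, 1, 1).
#'
#' @param data 3-D numeric array.
#' @param spacing Voxel spacing per axis (mm).
#' @param origin World coordinates of the first voxel centre (mm).
#' @param meta Optional list of provenance metadata.
#' @return An `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         meta = list()) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0),
            length(origin) == 3)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, intensity [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  if (length(x$meta$warnings))
    cat("  warnings:", paste(x$meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Voxel grid axes in world coordinates
#' @param vol An `image_volume`.
#' @return List of numeric vectors `x`, `y`, `z` (mm).
#' @export
volume_axes <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}

world_to_index <- function(vol, p) {
  round((as.numeric(p) - vol$origin) / vol$spacing) + 1
}
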