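#' Construct a voxel map on an MNI-aligned lattice
#'
#' A voxel map is a scalar field on an axis-aligned grid in MNI152 space.
#' Voxel centers sit at `origin + spacing * (index - 1)` along each axis.
#' Values are defined only where `mask` is `TRUE`; everywhere else they are
#' `NA`.
#'
#' @param dim Integer length-3 grid dimensions.
#' @param origin Numeric length-3 MNI coordinate (mm) of the first voxel
#'   center.
#' @param spacing Voxel edge length in mm (default 4).
#' @param values Numeric array of dimension `dim` (or `NULL` for all-`NA`).
#' @param mask Logical array of dimension `dim` (or `NULL` for all-`TRUE`).
#' @return An object of class `bg_voxel_map`.
#' @export
voxel_map <- function(dim, origin, spacing = 4, values = NULL, mask = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("`dim` must be three positive integers", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be three finite numbers", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim)
  mask <- array(as.logical(mask), dim)
  if (is.null(values)) values <- array(NA_real_, dim)
  values <- array(as.double(values), dim)
  values[!mask] <- NA_real_
  structure(
    list(dim = dim, origin = as.double(origin), spacing = as.double(spacing),
         values = values, mask = mask),
    class = "bg_voxel_map"
  )
}

#' @export
print.bg_voxel_map <- function(x, ...) {
  cat(sprintf("<bg_voxel_map> %dx%dx%d @ %g mm, origin (%g, %g, %g); %d/%d voxels in mask, %d defined\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3],
              sum(x$mask), prod(x$dim), sum(!is.na(x$values))))
  invisible(x)
}

#' Coordinates of in-mask voxel centers
#'
#' @param map A `bg_voxel_map`.
#' @param mask_only Return only in-mask voxels (default) or the full grid.
#' @return Matrix with one row per voxel (x, y, z in MNI mm), in array
#'   (column-major) order.
#' @export
voxel_centers <- function(map, mask_only = TRUE) {
  ax <- lapply(1:3, function(a) map$origin[a] + map$spacing * (seq_len(map$dim[a]) - 1))
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  if (mask_only) g[as.vector(map$mask), , drop = FALSE] else g
}

#' Rectangular (unmasked) voxel grid over a bounding box
#'
#' Convenience template used throughout the tests: an axis-aligned lattice
#' whose first voxel center is at the box minimum.
#'
#' @param box 2x3 matrix of (min, max) bounds per axis, in MNI mm.
#' @param spacing Voxel size in mm (default 4).
#' @return An all-`TRUE`-mask `bg_voxel_map` template.
#' @export
rect_grid <- function(box = default_brain_box(), spacing = 4) {
  box <- as.matrix(box)
  dim <- pmax(1L, as.integer(floor((box[2, ] - box[1, ]) / spacing)) + 1L)
  voxel_map(dim, origin = box[1, ], spacing = spacing)
}

#' Default brain-sized bounding box (MNI mm)
#'
#' Covers the extent of the MNI152 template head.
#' @return A 2x3 matrix of (min, max) bounds.
#' @export
default_brain_box <- function() {
  rbind(min = c(-90, -126, -72), max = c(90, 90, 108))
}

#' Synthetic ellipsoidal brain mask on the 4-mm grid
#'
#' A code-generated stand-in for a template brain mask: an ellipsoid
#' inscribed in the MNI152 head bounding box. It is synthetic -- a geometric
#' approximation, not tissue-derived -- and exists so that voxel-map
#' analyses run without any external template file.
#'
#' @param spacing Voxel size in mm (default 4).
#' @param shrink Fraction of each semi-axis to keep (default 0.9).
#' @return A masked `bg_voxel_map` template.
#' @export
synthetic_brain_mask <- function(spacing = 4, shrink = 0.9) {
  tmpl <- rect_grid(default_brain_box(), spacing)
  ctr <- colMeans(default_brain_box())
  semi <- shrink * (default_brain_box()[2, ] - default_brain_box()[1, ]) / 2
  g <- voxel_centers(tmpl, mask_only = FALSE)
  inside <- ((g[, 1] - ctr[1]) / semi[1])^2 +
    ((g[, 2] - ctr[2]) / semi[2])^2 +
    ((g[, 3] - ctr[3]) / semi[3])^2 <= 1
  voxel_map(tmpl$dim, tmpl$origin, spacing, mask = array(inside, tmpl$dim))
}

#' Replace the values of a voxel-map template
#'
#' @param map Template `bg_voxel_map`.
#' @param values Numeric vector over in-mask voxels (in `voxel_centers`
#'   order) or a full array.
#' @return A `bg_voxel_map` carrying the values.
#' @export
set_voxel_values <- function(map, values) {
  if (is.array(values) || length(values) == prod(map$dim)) {
    v <- array(as.double(values), map$dim)
  } else {
    if (length(values) != sum(map$mask))
      stop("`values` must cover the full grid or exactly the in-mask voxels",
           call. = FALSE)
    v <- array(NA_real_, map$dim)
    v[map$mask] <- as.double(values)
  }
  voxel_map(map$dim, map$origin, map$spacing, values = v, mask = map$mask)
}
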