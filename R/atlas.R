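#' Voxel grid and frontal-gyrus region atlas
#'
#' Reconstruction happens on a small rectangular voxel grid under the scalp
#' plane: x runs left(-)/right(+), y inferior/superior, z depth into the head
#' (all mm, z > 0). Six axis-aligned boxes at 12-25 mm depth stand in for the
#' AAL-derived left/right superior, middle and medial frontal gyri over which
#' reconstructed images are averaged.
#'
#' @name region-atlas
NULL

#' Region labels used throughout the package, in canonical order
#' @export
REGION_NAMES <- c("L-SFG", "R-SFG", "L-MFG", "R-MFG", "L-MedFG", "R-MedFG")

#' Construct a voxel grid
#'
#' @param shape Integer 3-vector (nx, ny, nz), voxel counts per axis.
#' @param spacing Voxel edge length, mm.
#' @param origin Coordinates of the corner of voxel (0,0,0), mm; the default
#'   centres the grid on the midline with z starting at the scalp.
#' @return Object of class `voxel_grid` with voxel-centre coordinate vectors.
#' @export
voxel_grid <- function(shape = c(24L, 12L, 8L), spacing = 5,
                       origin = c(-spacing * shape[1] / 2, 0, 0)) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("voxel grid error: all voxel counts must be >= 1")
  if (spacing <= 0) stop("voxel grid error: spacing must be > 0")
  centers <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 0.5) * spacing)
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         x = centers[[1]], y = centers[[2]], z = centers[[3]],
         n_voxels = prod(shape)),
    class = "voxel_grid"
  )
}

#' Voxel-centre coordinates as an (n_voxels x 3) matrix
#'
#' Voxels are linearized x-fastest (column-major over the (nx, ny, nz) array),
#' matching the sensitivity-matrix column order.
#' @param grid A `voxel_grid`.
#' @return Numeric matrix with columns x, y, z (mm).
#' @export
voxel_coordinates <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  g <- expand.grid(x = grid$x, y = grid$y, z = grid$z, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Default region-box configuration
#'
#' Boxes are given as inclusive 0-based voxel index ranges per axis. The
#' left/right members of each gyrus pair are mirror images across the x
#' midline of the default 24 x 12 x 8 grid, and the depth slab (z indices
#' 2..4 at 5 mm spacing) spans 12.5-22.5 mm voxel centres.
#'
#' @return Named list of boxes, each `list(x = c(lo, hi), y = ..., z = ...)`.
#' @export
default_atlas_config <- function() {
  list(
    "L-SFG"   = list(x = c(2L, 9L),   y = c(5L, 7L), z = c(2L, 4L)),
    "R-SFG"   = list(x = c(14L, 21L), y = c(5L, 7L), z = c(2L, 4L)),
    "L-MFG"   = list(x = c(2L, 9L),   y = c(2L, 4L), z = c(2L, 4L)),
    "R-MFG"   = list(x = c(14L, 21L), y = c(2L, 4L), z = c(2L, 4L)),
    "L-MedFG" = list(x = c(6L, 11L),  y = c(0L, 1L), z = c(2L, 4L)),
    "R-MedFG" = list(x = c(12L, 17L), y = c(0L, 1L), z = c(2L, 4L))
  )
}

#' Build a region atlas from axis-aligned boxes
#'
#' Labels each voxel of `grid` with 0 (unlabelled) or the 1-based index of
#' the region whose box contains it. Boxes must be pairwise disjoint, every
#' region non-empty, and left/right members of each gyrus pair mirror images
#' across the x midline.
#'
#' @param grid A `voxel_grid`.
#' @param config Region-box list as from [default_atlas_config()].
#' @return Object of class `region_atlas`: `grid`, integer `labels` (length
#'   n_voxels, x-fastest order), `region_names`.
#' @export
build_region_atlas <- function(grid, config = default_atlas_config()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(REGION_NAMES %in% names(config))) {
    stop("atlas config error: config must define all regions: ",
         paste(REGION_NAMES, collapse = ", "))
  }
  config <- config[REGION_NAMES]
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  labels <- integer(grid$n_voxels)
  ix <- (seq_len(grid$n_voxels) - 1L) %% nx
  iy <- ((seq_len(grid$n_voxels) - 1L) %/% nx) %% ny
  iz <- (seq_len(grid$n_voxels) - 1L) %/% (nx * ny)
  for (r in seq_along(config)) {
    b <- config[[r]]
    inside <- ix >= b$x[1] & ix <= b$x[2] &
      iy >= b$y[1] & iy <= b$y[2] &
      iz >= b$z[1] & iz <= b$z[2]
    if (!any(inside)) stop("atlas config error: region ", names(config)[r], " is empty")
    if (any(labels[inside] != 0L)) {
      stop("atlas config error: region ", names(config)[r],
           " overlaps region ", REGION_NAMES[labels[inside][labels[inside] != 0L][1]])
    }
    labels[inside] <- r
  }
  atlas <- structure(
    list(grid = grid, labels = labels, region_names = REGION_NAMES),
    class = "region_atlas"
  )
  .check_mirror_symmetry(atlas)
  atlas
}

# left/right regions of each gyrus pair must map onto each other under
# reflection of the x voxel index
.check_mirror_symmetry <- function(atlas) {
  nx <- atlas$grid$shape[1]
  v <- seq_along(atlas$labels) - 1L
  ix <- v %% nx
  mirrored <- (nx - 1L - ix) + (v %/% nx) * nx
  lab <- atlas$labels
  # swap L<->R region ids: (1,2), (3,4), (5,6)
  swap <- c(2L, 1L, 4L, 3L, 6L, 5L)
  expected <- integer(length(lab))
  expected[lab > 0L] <- swap[lab[lab > 0L]]
  if (!identical(expected, lab[mirrored + 1L])) {
    stop("atlas config error: left/right regions are not mirror-symmetric")
  }
  invisible(TRUE)
}

#' Voxel counts per region
#' @param atlas A `region_atlas`.
#' @return Named integer vector over the six regions.
#' @export
region_voxel_counts <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  counts <- tabulate(atlas$labels, nbins = length(atlas$region_names))
  names(counts) <- atlas$region_names
  counts
}

#' Export the atlas labelling as CSV (voxel index, ix, iy, iz, label, region)
#' @param atlas A `region_atlas`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_atlas_csv <- function(atlas, path) {
  nx <- atlas$grid$shape[1]; ny <- atlas$grid$shape[2]
  v <- seq_along(atlas$labels) - 1L
  df <- data.frame(
    voxel = v,
    ix = v %% nx,
    iy = (v %/% nx) %% ny,
    iz = v %/% (nx * ny),
    label = atlas$labels,
    region = c("unlabelled", atlas$region_names)[atlas$labels + 1L]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
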