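#' Linear DOT reconstruction
#'
#' A first-order (Rytov) linear forward model on the voxel grid is built
#' from the semi-infinite-medium diffusion Green's function with an
#' extrapolated-boundary image source. The inverse uses Tikhonov
#' regularization with a spatially variant (sensitivity-normalizing)
#' diagonal operator so that deep, weakly sensed voxels are not suppressed.
#'
#' @name dot-reconstruction
NULL

#' Tissue optical properties
#'
#' @param mua Named numeric, absorption coefficient per wavelength, mm^-1.
#' @param musp Named numeric or scalar, reduced scattering, mm^-1.
#' @return Object of class `optical_properties` with derived effective
#'   attenuation `mueff = sqrt(3 mua (mua + musp))` and diffusion
#'   coefficient `D = 1/(3 (mua + musp))` per wavelength.
#' @export
optical_properties <- function(mua = c(w760 = 0.017, w830 = 0.019),
                               musp = 1.0) {
  if (length(musp) == 1L) musp <- stats::setNames(rep(musp, length(mua)), names(mua))
  if (any(mua <= 0) || any(musp <= 0)) stop("optical properties must be positive")
  structure(
    list(mua = mua, musp = musp,
         mueff = sqrt(3 * mua * (mua + musp)),
         D = 1 / (3 * (mua + musp))),
    class = "optical_properties"
  )
}

# semi-infinite medium fluence Green's function with extrapolated boundary:
# positive point source at depth z0 below the surface, negative image source
# mirrored across the extrapolated boundary at -zb.
# `pos` is n x 3 (x, y, z>0 into the head), `src` is the surface location.
.greens_semi_inf <- function(src_xy, pos, mueff, D, musp, reff = 0.493) {
  z0 <- 1 / musp
  zb <- 2 * D * (1 + reff) / (1 - reff)
  dx <- pos[, 1] - src_xy[1]
  dy <- pos[, 2] - src_xy[2]
  r1 <- sqrt(dx^2 + dy^2 + (pos[, 3] - z0)^2)
  r2 <- sqrt(dx^2 + dy^2 + (pos[, 3] + z0 + 2 * zb)^2)
  r1 <- pmax(r1, 1e-6)
  r2 <- pmax(r2, 1e-6)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

#' Build the Rytov sensitivity matrix
#'
#' Row of channel c, voxel v:
#' \deqn{A[c, v] = \frac{G(r_s, r_v)\, G(r_v, r_d)}{G(r_s, r_d)}
#'   \frac{\Delta V}{\ln 10}}
#' so that `A %*% dmua` predicts the base-10 optical-density change of each
#' channel for a voxelwise absorption perturbation `dmua` (mm^-1). Source
#' and detector positions are synthesized per channel from the channel
#' midpoint, axis and nominal separation.
#'
#' @param layout A `probe_layout`.
#' @param grid A `voxel_grid` (all voxels at z > 0).
#' @param props An `optical_properties`.
#' @return Object of class `sensitivity_matrix`: list of per-wavelength
#'   matrices `A` (channels x voxels, entries >= 0), plus `grid`,
#'   `channel_ids`, `wavelengths`.
#' @export
build_sensitivity <- function(layout, grid, props = optical_properties()) {
  stopifnot(inherits(layout, "probe_layout"), inherits(grid, "voxel_grid"))
  vox <- voxel_coordinates(grid)
  if (any(vox[, 3] <= 0)) stop("geometry error: voxels must lie at z > 0")
  dV <- grid$spacing^3
  ch <- layout$channels
  wl <- paste0("w", layout$wavelengths)
  if (!all(wl %in% names(props$mua))) stop("optical properties missing wavelengths")
  A <- vector("list", length(wl))
  names(A) <- wl
  for (w in wl) {
    mueff <- props$mueff[[w]]; D <- props$D[[w]]; musp <- props$musp[[w]]
    m <- matrix(0, nrow(ch), nrow(vox))
    # G between two surface points, for the normalizing denominator
    z0 <- 1 / musp
    surf <- function(sx, sy, dxy) {
      .greens_semi_inf(c(sx, sy), matrix(c(dxy[1], dxy[2], z0), 1), mueff, D, musp)
    }
    for (i in seq_len(nrow(ch))) {
      gs <- .greens_semi_inf(c(ch$source_x[i], ch$source_y[i]), vox, mueff, D, musp)
      gd <- .greens_semi_inf(c(ch$detector_x[i], ch$detector_y[i]), vox, mueff, D, musp)
      gsd <- surf(ch$source_x[i], ch$source_y[i],
                  c(ch$detector_x[i], ch$detector_y[i]))
      m[i, ] <- pmax(gs * gd / gsd, 0) * dV / log(10)
    }
    rownames(m) <- ch$channel_id
    A[[w]] <- m
  }
  structure(
    list(A = A, grid = grid, channel_ids = ch$channel_id,
         wavelengths = layout$wavelengths),
    class = "sensitivity_matrix"
  )
}

#' Precompute the spatially variant regularized inverse operator
#'
#' With \eqn{L = diag(\sqrt{diag(A^T A)} + \beta\,\max\sqrt{diag(A^T A)})}
#' and \eqn{\tilde A = A L^{-1}}, the reconstruction is
#' \deqn{x = L^{-1} \tilde A^T (\tilde A \tilde A^T +
#'   \lambda\,\max diag(\tilde A \tilde A^T)\, I)^{-1} y.}
#' The dense (voxels x channels) operator is factorized once and reused for
#' every time point.
#'
#' @param A Sensitivity matrix for one wavelength (channels x voxels).
#' @param lambda_reg Relative Tikhonov weight (> 0).
#' @param beta Spatial-variance floor (> 0).
#' @return Matrix (voxels x channels) mapping measurements to voxel images.
#' @export
dot_inverse_operator <- function(A, lambda_reg = 0.01, beta = 0.1) {
  if (lambda_reg <= 0 || beta <= 0) stop("lambda_reg and beta must be > 0")
  colnorm <- sqrt(colSums(A^2))
  L <- colnorm + beta * max(colnorm)
  At <- sweep(A, 2, L, "/")          # A L^-1
  AAt <- tcrossprod(At)
  reg <- lambda_reg * max(diag(AAt))
  M <- solve(AAt + diag(reg, nrow(AAt)), At)  # (AAt + reg I)^-1 A~
  sweep(t(M), 1, L, "/")             # L^-1 A~^T (...)^-1
}

#' Invert measurements into voxel absorption images
#'
#' @param sens A `sensitivity_matrix`.
#' @param od An `od_series` whose channels match the sensitivity rows.
#' @param lambda_reg,beta Regularization parameters (see
#'   [dot_inverse_operator()]).
#' @return Object of class `mua_images`: list of per-wavelength matrices
#'   `dmua` (voxels x time, mm^-1) plus grid/time/events metadata.
#' @export
invert_dot <- function(sens, od, lambda_reg = 0.01, beta = 0.1) {
  stopifnot(inherits(sens, "sensitivity_matrix"), inherits(od, "od_series"))
  if (!identical(as.character(od$channel_ids), as.character(sens$channel_ids))) {
    stop("shape error: od channels do not match sensitivity channels")
  }
  wl <- paste0("w", od$wavelengths)
  dmua <- vector("list", length(wl))
  names(dmua) <- wl
  for (k in seq_along(wl)) {
    y <- od$od[, k, ]  # channels x time
    if (any(!is.finite(y))) stop("value error: non-finite optical density")
    Minv <- dot_inverse_operator(sens$A[[wl[k]]], lambda_reg, beta)
    dmua[[wl[k]]] <- Minv %*% y
  }
  structure(
    list(dmua = dmua, grid = sens$grid, time = od$time, events = od$events,
         sampling_rate = od$sampling_rate, wavelengths = od$wavelengths),
    class = "mua_images"
  )
}

# mua (mm^-1) = ln(10) * eps[(mM cm)^-1] * C[mM] / 10; inverse gives mM
.MUA_PER_CONC <- log(10) / 10

#' Unmix absorption images into chromophore images
#'
#' Per voxel and time point, solves the 2x2 extinction system (with the same
#' base-10/ln conversion used by the forward model) for oxy- and
#' deoxyhemoglobin concentration changes; total hemoglobin is their sum.
#'
#' @param imgs A `mua_images` with both wavelengths.
#' @param ext Extinction table, (mM cm)^-1.
#' @return Object of class `image_series`: matrices `hbo`, `hb`, `hbt`
#'   (voxels x time, mM/DPF).
#' @export
unmix_images <- function(imgs, ext = extinction_table()) {
  stopifnot(inherits(imgs, "mua_images"))
  wl <- paste0("w", imgs$wavelengths)
  E <- ext[wl, c("hbo", "hb")] * .MUA_PER_CONC
  if (abs(det(E)) < .Machine$double.eps) stop("numeric error: singular extinction matrix")
  Einv <- solve(E)
  hbo <- Einv[1, 1] * imgs$dmua[[wl[1]]] + Einv[1, 2] * imgs$dmua[[wl[2]]]
  hb <- Einv[2, 1] * imgs$dmua[[wl[1]]] + Einv[2, 2] * imgs$dmua[[wl[2]]]
  structure(
    list(hbo = hbo, hb = hb, hbt = hbo + hb, grid = imgs$grid,
         time = imgs$time, events = imgs$events,
         sampling_rate = imgs$sampling_rate),
    class = "image_series"
  )
}

# forward composition used by the synthetic generator: chromophore voxel
# images (mM) -> absorption perturbation images per wavelength (mm^-1)
.compose_dmua <- function(hbo, hb, wavelengths, ext = extinction_table()) {
  wl <- paste0("w", wavelengths)
  E <- ext[wl, c("hbo", "hb")] * .MUA_PER_CONC
  out <- lapply(seq_along(wl), function(k) E[k, 1] * hbo + E[k, 2] * hb)
  names(out) <- wl
  out
}

#' Average voxel images over atlas regions
#'
#' Unweighted mean over the voxels of each region, per time point and
#' chromophore; unlabelled voxels are ignored. Values are rescaled to the
#' reporting unit of 1e-4 mM/DPF and the time axis is re-expressed relative
#' to `tilt_start`.
#'
#' @param img An `image_series`.
#' @param atlas A `region_atlas` on the same grid.
#' @return A `region_series` (see [region_series()]).
#' @export
region_average <- function(img, atlas) {
  stopifnot(inherits(img, "image_series"), inherits(atlas, "region_atlas"))
  if (!identical(img$grid$shape, atlas$grid$shape)) {
    stop("shape error: image grid does not match atlas grid")
  }
  nreg <- length(atlas$region_names)
  take <- function(m) {
    out <- matrix(0, nreg, ncol(m))
    for (r in seq_len(nreg)) {
      out[r, ] <- colMeans(m[atlas$labels == r, , drop = FALSE])
    }
    out
  }
  region_series(
    hbo = take(img$hbo) / 1e-4, hb = take(img$hb) / 1e-4,
    time = img$time - img$events[["tilt_start"]],
    events = img$events - img$events[["tilt_start"]],
    sampling_rate = img$sampling_rate,
    region_names = atlas$region_names
  )
}

#' Construct a region-level hemodynamic series
#'
#' The canonical container for gyrus-averaged trajectories: 6 regions x
#' time for HbO, Hb and HbT in units of 1e-4 mM/DPF, time axis relative to
#' tilt onset.
#'
#' @param hbo,hb Region x time matrices (1e-4 mM/DPF); `hbt` is their sum.
#' @param time Time axis (s), 0 = tilt_start.
#' @param events Named event times on the same axis.
#' @param sampling_rate Hz.
#' @param region_names Region labels.
#' @return Object of class `region_series`.
#' @export
region_series <- function(hbo, hb, time, events, sampling_rate = 5,
                          region_names = REGION_NAMES) {
  stopifnot(identical(dim(hbo), dim(hb)), nrow(hbo) == length(region_names),
            ncol(hbo) == length(time))
  rownames(hbo) <- rownames(hb) <- region_names
  structure(
    list(hbo = hbo, hb = hb, hbt = hbo + hb, time = time, events = events,
         sampling_rate = sampling_rate, region_names = region_names),
    class = "region_series"
  )
}

#' Export a region series as tidy CSV
#' @param rs A `region_series`.
#' @param path Output CSV path.
#' @param subject Optional subject id column value.
#' @return `path`, invisibly.
#' @export
write_region_series_csv <- function(rs, path, subject = NA_character_) {
  nreg <- length(rs$region_names); nt <- length(rs$time)
  df <- do.call(rbind, lapply(c("hbo", "hb", "hbt"), function(ch) {
    m <- rs[[ch]]
    data.frame(subject = subject,
               region = rep(rs$region_names, times = nt),
               chromophore = ch,
               time_s = rep(rs$time, each = nreg),
               value = as.vector(m))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
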