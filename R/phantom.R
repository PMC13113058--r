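# ---------------------------------------------------------------------------
# Synthetic aortic-root CT phantoms.
#
# The phantom is a bent tube of elliptical cross-section running along the
# z axis, with three regions mimicking the segmented anatomy: LVOT (narrow),
# sinus of Valsalva (bulged) and ascending aorta. Contrast-filled lumen,
# a thin wall, and bright calcification blobs seeded on the annular ring give
# the three channels (CT / root mask / calcification mask) the same broad
# intensity structure as a contrast CT: with the [-79, 304] HU display window
# the lumen sits mid-scale and calcification saturates at 1.
# ---------------------------------------------------------------------------

#' Parameters for a synthetic aortic-root phantom
#'
#' @param grid_shape voxel grid (nx, ny, nz).
#' @param spacing voxel spacing in mm; the 1 x 1 x 2 mm default matches the
#'   resampling target of the preprocessing chain.
#' @param root_radius_mm outer tube radius at the ascending segment.
#' @param wall_mm wall thickness.
#' @param bend_mm lateral bow of the centerline.
#' @param background_HU,lumen_HU,wall_HU,calc_HU intensity palette; defaults
#'   40 / 300 / 80 / 800 so the display window behaves like contrast CT.
#' @param target_calc_volume_mm3 total calcification volume to deposit.
#' @param n_calc_blobs number of calcific deposits seeded on the annulus.
#' @param noise_sd additive Gaussian noise (HU).
#' @param seed RNG seed; the phantom is a pure function of (params, seed).
#' @return object of class `pvl_phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64L, 64L, 44L),
                           spacing = c(1, 1, 2),
                           root_radius_mm = 14,
                           wall_mm = 2,
                           bend_mm = 5,
                           background_HU = 40, lumen_HU = 300,
                           wall_HU = 80, calc_HU = 800,
                           target_calc_volume_mm3 = 600,
                           n_calc_blobs = 3L,
                           noise_sd = 20,
                           seed = 1L) {
  stopifnot(all(spacing > 0), target_calc_volume_mm3 >= 0,
            background_HU < lumen_HU, lumen_HU < calc_HU)
  structure(as.list(environment()), class = "pvl_phantom_params")
}

#' Generate one synthetic aortic-root CT phantom
#'
#' @param params a [phantom_params()] object.
#' @param patient_id identifier stored with the sample.
#' @return a `pvl_volume_sample`: list with `ct`, `root_mask`, `calc_mask`
#'   (3D arrays of identical shape), `spacing`, `patient_id` and the realized
#'   `calc_volume_mm3`.
#' @export
generate_phantom <- function(params = phantom_params(), patient_id = "P001") {
  p <- params
  with_seed(p$seed, {
    nx <- p$grid_shape[1]; ny <- p$grid_shape[2]; nz <- p$grid_shape[3]
    sx <- p$spacing[1]; sy <- p$spacing[2]; sz <- p$spacing[3]
    # physical coordinates of voxel centres
    xs <- (seq_len(nx) - 0.5) * sx
    ys <- (seq_len(ny) - 0.5) * sy
    zs <- (seq_len(nz) - 0.5) * sz
    zf <- zs / (nz * sz)                       # z as fraction of grid height
    cx0 <- nx * sx / 2; cy0 <- ny * sy / 2
    # centerline bows in x; root occupies the central 84% of z
    cx <- cx0 + p$bend_mm * sin(pi * zf)
    z_lo <- 0.08; z_hi <- 0.92
    ann_f <- 0.30                              # annular plane (z fraction)
    # outer radius profile: LVOT narrow, sinus bulge, ascending nominal
    r_out <- p$root_radius_mm *
      (0.85 + 0.15 * pmin(1, pmax(0, (zf - 0.20) / 0.15)) +
         0.30 * exp(-((zf - 0.42) / 0.09)^2))
    in_z <- zf >= z_lo & zf <= z_hi
    dx2 <- outer(xs, cx, function(x, c) (x - c)^2)   # nx x nz
    dy2 <- (ys - cy0)^2                              # ny
    # squared radial distance, nx x ny x nz
    r2 <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) r2[, , k] <- outer(dx2[, k], dy2, `+`)
    rr <- sqrt(r2)
    rout_arr <- array(rep(r_out, each = nx * ny), c(nx, ny, nz))
    inz_arr <- array(rep(in_z, each = nx * ny), c(nx, ny, nz))
    root_mask <- (rr <= rout_arr) & inz_arr
    lumen <- (rr <= rout_arr - p$wall_mm) & inz_arr
    ct <- array(p$background_HU, c(nx, ny, nz))
    ct[root_mask] <- p$wall_HU
    ct[lumen] <- p$lumen_HU
    # --- calcification: top-k voxels of a blob field on the annular ring ---
    vox_vol <- sx * sy * sz
    k_target <- round(p$target_calc_volume_mm3 / vox_vol)
    calc_mask <- array(0L, c(nx, ny, nz))
    if (k_target > 0) {
      z_ann <- ann_f * nz * sz
      zdist <- array(rep(abs(zs - z_ann), each = nx * ny), c(nx, ny, nz))
      ring <- zdist <= 8 & (rr >= rout_arr - p$wall_mm - 2) &
        (rr <= rout_arr + 1) & inz_arr
      cand <- which(ring)
      capacity <- length(cand)
      if (k_target > capacity) {
        stop(sprintf(paste0("infeasible target calcification volume: ",
                            "%.1f mm^3 requested but the annular ring holds ",
                            "at most %.1f mm^3 (%d voxels)"),
                     p$target_calc_volume_mm3, capacity * vox_vol, capacity))
      }
      ci <- arrayInd(cand, c(nx, ny, nz))
      px <- xs[ci[, 1]]; py <- ys[ci[, 2]]; pz <- zs[ci[, 3]]
      theta <- atan2(py - cy0, px - cx[ci[, 3]])
      blob_theta <- runif(p$n_calc_blobs, -pi, pi)
      blob_z <- z_ann + rnorm(p$n_calc_blobs, 0, 2)
      blob_sd_t <- runif(p$n_calc_blobs, 0.35, 0.8)   # angular width (rad)
      blob_sd_z <- runif(p$n_calc_blobs, 2.5, 5)      # axial width (mm)
      blob_amp <- runif(p$n_calc_blobs, 0.7, 1)
      field <- rep(0, capacity)
      for (b in seq_len(p$n_calc_blobs)) {
        dth <- atan2(sin(theta - blob_theta[b]), cos(theta - blob_theta[b]))
        field <- field + blob_amp[b] *
          exp(-0.5 * (dth / blob_sd_t[b])^2 -
                0.5 * ((pz - blob_z[b]) / blob_sd_z[b])^2)
      }
      field <- field + runif(capacity, 0, 1e-6)       # deterministic tie-break
      sel <- cand[order(field, decreasing = TRUE)[seq_len(k_target)]]
      calc_mask[sel] <- 1L
      ct[sel] <- p$calc_HU
    }
    ct <- ct + array(rnorm(nx * ny * nz, 0, p$noise_sd), c(nx, ny, nz))
    structure(list(patient_id = patient_id,
                   ct = ct,
                   root_mask = array(as.integer(root_mask), c(nx, ny, nz)),
                   calc_mask = calc_mask,
                   spacing = p$spacing,
                   calc_volume_mm3 = sum(calc_mask) * vox_vol,
                   params = p),
              class = "pvl_volume_sample")
  })
}

#' Calcification volume of a binary mask
#'
#' Total physical volume of the labeled voxels: `sum(mask) * sx*sy*sz` mm^3,
#' exactly.
#'
#' @param mask 3D binary array. @param spacing voxel spacing in mm.
#' @return volume in mm^3.
#' @export
compute_calcification_volume <- function(mask, spacing) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  stopifnot(length(spacing) == 3, all(spacing > 0))
  sum(mask) * prod(spacing)
}
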