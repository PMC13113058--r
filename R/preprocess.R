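# ---------------------------------------------------------------------------
# Preprocessing chain: resample -> window-normalize -> foreground crop ->
# resize, producing the fixed-shape 3-channel model input, plus the training
# augmentation (random crop + random intensity shift) and the deterministic
# inference tiling.
# ---------------------------------------------------------------------------

#' Preprocessing configuration
#'
#' Defaults follow the reference pipeline: resample to 1 x 1 x 2 mm, window
#' the CT to `[0, 1]` over `[-79, 304]` HU, crop around the foreground with a
#' 30-voxel margin, and stretch (anisotropically) to 192 x 128 x 96. The
#' desk-scale profile swaps in a small output shape.
#'
#' @param target_spacing resampling target (mm).
#' @param window HU window (lo, hi) mapped to `[0, 1]`.
#' @param margin foreground crop margin in voxels.
#' @param shape output shape of the resize step.
#' @export
preprocess_config <- function(target_spacing = c(1, 1, 2),
                              window = c(-79, 304),
                              margin = 30L,
                              shape = c(192L, 128L, 96L)) {
  if (window[1] >= window[2]) stop("window lower bound must be below upper")
  structure(list(target_spacing = target_spacing, window = window,
                 margin = as.integer(margin), shape = as.integer(shape)),
            class = "pvl_preprocess_config")
}

#' Resample a volume sample to a target voxel spacing
#'
#' CT is interpolated trilinearly, masks by nearest neighbour (so they stay
#' binary). The physical extent is preserved to within one voxel.
#'
#' @param sample a `pvl_volume_sample`.
#' @param target_spacing new (sx, sy, sz) in mm.
#' @export
resample_volume <- function(sample, target_spacing = c(1, 1, 2)) {
  stopifnot(all(target_spacing > 0))
  din <- dim(sample$ct)
  if (any(din < 2)) stop("resample: degenerate (single-slice) input")
  dout <- as.integer(pmax(1, round(din * sample$spacing / target_spacing)))
  res <- sample
  res$ct <- array(resize3(as.numeric(sample$ct), din, dout, 0L), dout)
  res$root_mask <- array(resize3(as.numeric(sample$root_mask), din, dout, 1L),
                         dout)
  res$calc_mask <- array(resize3(as.numeric(sample$calc_mask), din, dout, 1L),
                         dout)
  res$spacing <- target_spacing
  res
}

#' Window-normalize CT intensities to [0, 1]
#'
#' `x -> clip((x - lo) / (hi - lo), 0, 1)`; monotone non-decreasing, so
#' calcification (800 HU) saturates at 1 under the default window.
#'
#' @param ct numeric array/vector. @param lo,hi window bounds in HU.
#' @export
window_normalize <- function(ct, lo = -79, hi = 304) {
  if (lo >= hi) stop("window_normalize: lo must be < hi")
  if (any(!is.finite(ct))) stop("window_normalize: non-finite intensities")
  pmin(pmax((ct - lo) / (hi - lo), 0), 1)
}

#' Crop a sample around the segmentation foreground
#'
#' The crop box is the bounding box of the foreground (union of root and
#' calcification masks) dilated by `margin` voxels and clipped to the grid;
#' every mask voxel is retained by construction.
#'
#' @param sample a `pvl_volume_sample`. @param margin margin in voxels.
#' @export
crop_foreground <- function(sample, margin = 30L) {
  fg <- sample$root_mask > 0 | sample$calc_mask > 0
  if (!any(fg)) {
    stop("crop_foreground: empty root mask for sample ",
         sample$patient_id %||% "<unnamed>")
  }
  idx <- which(fg, arr.ind = TRUE)
  d <- dim(sample$ct)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  res <- sample
  res$ct <- sample$ct[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  res$root_mask <- sample$root_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                    drop = FALSE]
  res$calc_mask <- sample$calc_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                    drop = FALSE]
  res$crop_box <- cbind(lo = lo, hi = hi)
  res
}

#' Resize a sample to a fixed grid
#'
#' Trilinear for CT, nearest neighbour for masks (masks remain binary).
#' The stretch is anisotropic: no aspect-ratio padding.
#'
#' @param sample a `pvl_volume_sample`. @param shape target (nx, ny, nz).
#' @export
resize_volume <- function(sample, shape = c(192L, 128L, 96L)) {
  shape <- as.integer(shape)
  din <- dim(sample$ct)
  res <- sample
  res$ct <- array(resize3(as.numeric(sample$ct), din, shape, 0L), shape)
  res$root_mask <- array(resize3(as.numeric(sample$root_mask), din, shape, 1L),
                         shape)
  res$calc_mask <- array(resize3(as.numeric(sample$calc_mask), din, shape, 1L),
                         shape)
  res
}

#' Run the full preprocessing chain on a volume sample
#'
#' resample -> window-normalize -> crop foreground -> resize, returning the
#' stacked 3-channel model input.
#'
#' @param sample a `pvl_volume_sample`.
#' @param cfg a [preprocess_config()].
#' @return a `pvl_preprocessed` list: `channels` array (nx, ny, nz, 3) ordered
#'   (CT, root mask, calc mask) plus provenance fields.
#' @export
preprocess_volume <- function(sample, cfg = preprocess_config()) {
  rs <- resample_volume(sample, cfg$target_spacing)
  rs$ct <- window_normalize(rs$ct, cfg$window[1], cfg$window[2])
  cr <- crop_foreground(rs, cfg$margin)
  rz <- resize_volume(cr, cfg$shape)
  channels <- array(0, c(cfg$shape, 3L))
  channels[, , , 1] <- rz$ct
  channels[, , , 2] <- rz$root_mask
  channels[, , , 3] <- rz$calc_mask
  structure(list(channels = channels,
                 patient_id = sample$patient_id,
                 original_spacing = sample$spacing,
                 crop_box = cr$crop_box,
                 root_mask = rz$root_mask,
                 calc_mask = rz$calc_mask,
                 config = cfg),
            class = "pvl_preprocessed")
}

#' Write the preprocessing configuration beside outputs for provenance
#' @param cfg a [preprocess_config()]. @param path JSON file path.
#' @export
write_preprocess_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Augmentation configuration
#'
#' @param crop_size training patch edge length (64 in the reference setup;
#'   32 in the desk-scale profile).
#' @param intensity_shift_offset half-width of the uniform CT-channel shift.
#' @param intensity_shift_prob probability of applying the shift.
#' @export
augment_config <- function(crop_size = 64L, intensity_shift_offset = 0.40,
                           intensity_shift_prob = 0.50) {
  stopifnot(intensity_shift_offset >= 0,
            intensity_shift_prob >= 0, intensity_shift_prob <= 1)
  structure(list(crop_size = as.integer(crop_size),
                 intensity_shift_offset = intensity_shift_offset,
                 intensity_shift_prob = intensity_shift_prob),
            class = "pvl_augment_config")
}

#' Draw one random training patch
#'
#' Uniformly random valid crop offset; with the configured probability a
#' uniform shift in `[-offset, offset]` is added to the CT channel only and
#' re-clipped to `[0, 1]`. Masks are untouched. Consumes the current RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param vol a `pvl_preprocessed` (or plain 4D array).
#' @param cfg an [augment_config()].
#' @return list with `channels` (c^3 x 3 array) and `offset` (0-based).
#' @export
random_patch <- function(vol, cfg = augment_config()) {
  x <- if (is.list(vol)) vol$channels else vol
  d <- dim(x)[1:3]
  cs <- cfg$crop_size
  if (any(d < cs)) {
    stop("random_patch: volume ", paste(d, collapse = "x"),
         " smaller than patch ", cs)
  }
  off <- vapply(d, function(di) {
    if (di == cs) 0L else sample.int(di - cs + 1L, 1L) - 1L
  }, integer(1))
  patch <- x[off[1] + seq_len(cs), off[2] + seq_len(cs), off[3] + seq_len(cs),
             , drop = FALSE]
  shifted <- runif(1) < cfg$intensity_shift_prob
  if (shifted) {
    delta <- runif(1, -cfg$intensity_shift_offset, cfg$intensity_shift_offset)
    patch[, , , 1] <- pmin(pmax(patch[, , , 1] + delta, 0), 1)
  }
  list(channels = patch, offset = off, shifted = shifted)
}

#' Deterministic overlapping patch grid for inference
#'
#' Offsets advance by `stride` along each axis, with a final shifted patch
#' appended whenever the extent is not a multiple of the stride, so the union
#' of patches covers every voxel. Per-patch probabilities are averaged with
#' equal weights downstream.
#'
#' @param vol a `pvl_preprocessed` or 4D array.
#' @param patch_size patch edge length. @param stride step (default: patch).
#' @return list with `patches` (list of arrays), `offsets` (0-based matrix),
#'   `weights`.
#' @export
inference_patches <- function(vol, patch_size = 64L, stride = patch_size) {
  x <- if (is.list(vol)) vol$channels else vol
  d <- dim(x)[1:3]
  ps <- as.integer(patch_size)
  if (any(d < ps)) stop("inference_patches: volume smaller than patch")
  axis_offsets <- lapply(d, function(di) {
    off <- seq(0L, di - ps, by = stride)
    if (off[length(off)] != di - ps) off <- c(off, di - ps)
    off
  })
  grid <- expand.grid(axis_offsets[[1]], axis_offsets[[2]], axis_offsets[[3]])
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    o <- as.integer(grid[i, ])
    x[o[1] + seq_len(ps), o[2] + seq_len(ps), o[3] + seq_len(ps), ,
      drop = FALSE]
  })
  list(patches = patches, offsets = as.matrix(grid),
       weights = rep(1, nrow(grid)), patch_size = ps)
}
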