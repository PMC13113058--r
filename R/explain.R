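# ---------------------------------------------------------------------------
# Grad-CAM over the final convolutional stage of the imaging encoder.
# Channel weights are the spatial means of the gradient of the positive-class
# logit w.r.t. the final-stage feature maps; the ReLU'd weighted sum is
# trilinearly upsampled to the patch frame and stitched over the inference
# tiling by coverage-weighted averaging.
# ---------------------------------------------------------------------------

#' 3D Grad-CAM for one preprocessed volume
#'
#' @param model a trained `pvl_fusion_model`.
#' @param vol preprocessed 4D array (or `pvl_preprocessed`).
#' @param clin standardized covariate vector for the patient.
#' @param patch_size inference patch edge length.
#' @return a `pvl_cam` list: `cam` (3D array in [0, 1], same grid as `vol`),
#'   `p` (averaged predicted probability).
#' @export
gradcam3d <- function(model, vol, clin, patch_size = 64L) {
  x <- if (is.list(vol)) vol$channels else vol
  tiles <- inference_patches(x, patch_size = patch_size)
  d <- dim(x)[1:3]
  acc <- array(0, d)
  cov <- array(0, d)
  probs <- numeric(length(tiles$patches))
  for (i in seq_along(tiles$patches)) {
    fwd <- fusion_forward(model, tiles$patches[i],
                          matrix(clin, nrow = 1), training = FALSE)
    probs[i] <- fwd$p
    # gradient of the positive-class logit w.r.t. the encoder output tokens
    bwd <- fusion_backward(model, fwd$cache, dlogit = 1,
                           through_encoder = FALSE)
    tdims <- fwd$cache$enc_dims
    if (prod(tdims) < 1) stop("target layer has no spatial extent")
    A <- fwd$cache$enc$out$x                    # T x C feature maps
    G <- bwd$d_tokens$x                         # T x C gradients
    wts <- colMeans(G)                          # spatially averaged gradients
    cam_small <- pmax(as.vector(A %*% wts), 0)  # ReLU(sum_c w_c A_c)
    cam_up <- array(resize3(cam_small, tdims, rep(patch_size, 3L), 0L),
                    rep(patch_size, 3L))
    o <- as.integer(tiles$offsets[i, ])
    ix <- o[1] + seq_len(patch_size); iy <- o[2] + seq_len(patch_size)
    iz <- o[3] + seq_len(patch_size)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + cam_up
    cov[ix, iy, iz] <- cov[ix, iy, iz] + 1
  }
  cam <- acc / pmax(cov, 1)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  structure(list(cam = cam, p = mean(probs)), class = "pvl_cam")
}

.hot_colormap <- function(v) {
  # blue -> red -> yellow ramp on [0,1], returned as an RGB array
  r <- pmin(1, 2.5 * v)
  g <- pmin(1, pmax(0, 2.5 * v - 1))
  b <- pmax(0, 1 - 2.5 * v)
  array(c(r, g, b), c(dim(v), 3))
}

#' Export CT / heatmap / overlay PNG triplets at three axial levels
#'
#' Levels default to the upper, middle and lower thirds of the root mask's
#' z-extent (ascending aorta / annulus / LVOT panels). Files are written
#' deterministically as `<prefix>_L<z>_{ct,cam,overlay}.png`.
#'
#' @param cam a `pvl_cam` from [gradcam3d()].
#' @param vol the matching preprocessed volume (CT channel + root mask).
#' @param out_dir output directory.
#' @param levels axial slice indices; default picks thirds of the root.
#' @param alpha overlay opacity of the heatmap (0 reproduces the CT slice).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
export_overlay <- function(cam, vol, out_dir, levels = NULL, alpha = 0.4,
                           prefix = "case") {
  x <- if (is.list(vol)) vol$channels else vol
  d <- dim(x)[1:3]
  if (is.null(levels)) {
    zmask <- which(apply(x[, , , 2] > 0, 3, any))
    if (!length(zmask)) stop("root mask empty; cannot place axial levels")
    qs <- stats::quantile(zmask, c(5 / 6, 1 / 2, 1 / 6), names = FALSE)
    levels <- unique(as.integer(round(qs)))
  }
  levels <- sort(as.integer(levels))
  if (any(levels < 1 | levels > d[3])) {
    stop("requested axial level outside the volume (1..", d[3], ")")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (z in levels) {
    ct <- x[, , z, 1]
    hm <- cam$cam[, , z]
    gray <- array(rep(ct, 3), c(dim(ct), 3))
    color <- .hot_colormap(hm)
    hm3 <- array(rep(hm, 3), c(dim(hm), 3))
    overlay <- (1 - alpha * hm3) * gray + alpha * hm3 * color
    trio <- list(ct = gray, cam = color, overlay = overlay)
    for (nm in names(trio)) {
      fp <- file.path(out_dir, sprintf("%s_L%03d_%s.png", prefix, z, nm))
      png::writePNG(aperm(pmin(pmax(trio[[nm]], 0), 1), c(2, 1, 3)), fp)
      paths <- c(paths, fp)
    }
  }
  invisible(paths)
}
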