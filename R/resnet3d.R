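#' Configuration for the 3D ResNet-18 imaging encoder
#'
#' The encoder follows the canonical ResNet-18 layout transposed to 3D:
#' a stride-2 3x3x3 stem convolution, a stride-2 3x3x3 max-pool, then four
#' stages of two basic residual blocks with stage strides 1/2/2/2. The total
#' reduction is 32x per axis, so a 64^3 patch yields a 2x2x2 grid of spatial
#' tokens at the final stage. `width_factor` scales all stage widths; the
#' desk-scale profile uses 1/8 (stage widths 8/16/32/64).
#'
#' @param width_factor multiplier on the stage widths 64/128/256/512.
#' @param in_channels input channels (CT, root mask, calcification mask).
#' @param blocks residual blocks per stage (2,2,2,2 for ResNet-18).
#' @param stem_pool keep the stride-2 stem max-pool (the full-scale layout).
#' @param stage_strides per-stage first-block strides (1/2/2/2 for the
#'   full-scale 32x reduction). The desk-scale profile uses 1/2/2/1 so a
#'   32^3 patch still ends in a 2x2x2 token grid (16x reduction), preserving
#'   the spatial-token contract of the 64^3 full-scale input at negligible
#'   extra cost.
#' @return an object of class `pvl_encoder_config`.
#' @export
encoder_config <- function(width_factor = 1, in_channels = 3L,
                           blocks = c(2L, 2L, 2L, 2L), stem_pool = TRUE,
                           stage_strides = c(1L, 2L, 2L, 2L)) {
  widths <- as.integer(round(c(64, 128, 256, 512) * width_factor))
  if (any(widths < 1)) stop("width_factor too small: zero-width stage")
  structure(list(width_factor = width_factor, in_channels = as.integer(in_channels),
                 widths = widths, blocks = as.integer(blocks),
                 d_model = widths[4], stem_pool = isTRUE(stem_pool),
                 stage_strides = as.integer(stage_strides)),
            class = "pvl_encoder_config")
}

#' Build a randomly initialized 3D ResNet-18 encoder
#'
#' @param cfg an [encoder_config()].
#' @param seed integer seed for the He-initialized weights.
#' @return encoder object (list of layers plus its config).
#' @export
build_encoder <- function(cfg = encoder_config(), seed = 1L) {
  with_seed(seed, {
    layers <- list(
      stem_conv = conv3d_layer(cfg$in_channels, cfg$widths[1],
                               stride = c(2L, 2L, 2L)),
      stem_bn = bn_layer(cfg$widths[1]),
      stem_relu = relu_layer()
    )
    if (cfg$stem_pool) layers$stem_pool <- maxpool_layer()
    in_ch <- cfg$widths[1]
    for (stage in 1:4) {
      for (b in seq_len(cfg$blocks[stage])) {
        stride <- if (b == 1) rep(cfg$stage_strides[stage], 3L) else c(1L, 1L, 1L)
        nm <- sprintf("s%d_b%d", stage, b)
        layers[[nm]] <- resblock_layer(in_ch, cfg$widths[stage], stride)
        in_ch <- cfg$widths[stage]
      }
    }
    structure(list(layers = layers, cfg = cfg), class = "pvl_encoder")
  })
}

encoder_forward <- function(encoder, inp, training = TRUE) {
  seq_forward(encoder$layers, inp, training)
}

encoder_backward <- function(encoder, caches, dout) {
  b <- seq_backward(encoder$layers, caches, dout)
  names(b$grads) <- names(encoder$layers)
  b
}

#' Encode image patches into spatial tokens or a pooled vector
#'
#' Runs the encoder in inference mode (batch-norm running statistics).
#'
#' @param patches a (d1,d2,d3,3) array or list of such arrays.
#' @param encoder a [build_encoder()] object.
#' @param output `"tokens"` for per-sample token matrices (T x d_model, one
#'   token per final-stage spatial location) or `"pooled"` for an n x d_model
#'   matrix of globally average-pooled features.
#' @return list of token matrices, or a pooled feature matrix.
#' @export
encode_image <- function(patches, encoder, output = c("tokens", "pooled")) {
  output <- match.arg(output)
  if (is.array(patches)) patches <- list(patches)
  if (dim(patches[[1]])[4] != encoder$cfg$in_channels) {
    stop("encode_image: expected ", encoder$cfg$in_channels, " channels, got ",
         dim(patches[[1]])[4])
  }
  fm <- fmap_from_arrays(patches)
  out <- encoder_forward(encoder, fm, training = FALSE)$out
  if (output == "pooled") {
    forward(gap_layer(), out, training = FALSE)$out
  } else {
    lapply(seq_len(out$n), function(s) {
      L <- prod(out$dims)
      out$x[((s - 1) * L + 1):(s * L), , drop = FALSE]
    })
  }
}

# Evaluate R code with a temporary RNG state so generators and weight init
# are pure functions of their seed.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
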