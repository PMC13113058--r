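# ---------------------------------------------------------------------------
# Model B: 3D ResNet-18 imaging encoder + clinical MLP, fused by scaled
# dot-product cross-attention (image tokens as queries, clinical embedding
# tokens as keys/values), then a sigmoid classification head.
# ---------------------------------------------------------------------------

#' Fusion-module configuration
#'
#' The 64-dimensional clinical embedding is reshaped into `m_tokens` tokens of
#' 64/m dimensions before attention. With a single clinical token the softmax
#' over keys is identically 1 and the fused feature would collapse onto the
#' clinical value projection; m = 8 keeps the printed attention equation while
#' making the weights informative.
#'
#' @param clin_embed_dim clinical embedding width (64 in the reference setup).
#' @param m_tokens number of clinical tokens; must divide `clin_embed_dim`.
#' @param d_attn common projected dimension d of Q, K and V (the scaling
#'   denominator is sqrt(d)).
#' @param hidden width of the clinical MLP hidden layer.
#' @param qk_init_scale multiplier on the Q/K projection init scale. The
#'   default (0.1) starts the attention near-uniform over clinical tokens,
#'   so the fused feature begins as a clean mixture of clinical values and
#'   image-conditioned attention sharpens only as training warrants it.
#' @export
fusion_config <- function(clin_embed_dim = 64L, m_tokens = 8L, d_attn = 64L,
                          hidden = 32L, qk_init_scale = 0.1) {
  if (clin_embed_dim %% m_tokens != 0) {
    stop("clin_embed_dim must be divisible by m_tokens")
  }
  if (d_attn <= 0) stop("d_attn must be positive")
  if (qk_init_scale < 0) stop("qk_init_scale must be >= 0")
  structure(list(clin_embed_dim = as.integer(clin_embed_dim),
                 m_tokens = as.integer(m_tokens),
                 token_dim = as.integer(clin_embed_dim / m_tokens),
                 d_attn = as.integer(d_attn), hidden = as.integer(hidden),
                 qk_init_scale = qk_init_scale),
            class = "pvl_fusion_config")
}

#' Assemble the full multi-modal model
#'
#' @param encoder imaging encoder from [build_encoder()] (cloned, so the
#'   caller's copy is untouched).
#' @param n_covariates number of standardized clinical covariates.
#' @param fcfg a [fusion_config()].
#' @param seed seed for the fusion/clinical parameter init.
#' @return a `pvl_fusion_model` object.
#' @export
build_fusion_model <- function(encoder, n_covariates, fcfg = fusion_config(),
                               seed = 1L) {
  d_model <- encoder$cfg$d_model
  with_seed(seed, {
    clin <- list(fc1 = linear_layer(n_covariates, fcfg$hidden),
                 act = relu_mat_layer(),
                 fc2 = linear_layer(fcfg$hidden, fcfg$clin_embed_dim))
    qs <- fcfg$qk_init_scale %||% 1
    sd_q <- qs / sqrt(d_model)
    sd_k <- qs / sqrt(fcfg$token_dim)
    sd_kv <- 1 / sqrt(fcfg$token_dim)
    attn <- new_layer("attention",
                      Wq = matrix(rnorm(d_model * fcfg$d_attn, sd = sd_q),
                                  d_model, fcfg$d_attn),
                      Wk = matrix(rnorm(fcfg$token_dim * fcfg$d_attn, sd = sd_k),
                                  fcfg$token_dim, fcfg$d_attn),
                      Wv = matrix(rnorm(fcfg$token_dim * fcfg$d_attn, sd = sd_kv),
                                  fcfg$token_dim, fcfg$d_attn))
    head <- linear_layer(fcfg$d_attn, 1L, init_sd = 1 / sqrt(fcfg$d_attn))
    structure(list(encoder = clone_layers_encoder(encoder), clin = clin,
                   attn = attn, head = head, fcfg = fcfg,
                   n_covariates = as.integer(n_covariates)),
              class = "pvl_fusion_model")
  })
}

clone_layers_encoder <- function(encoder) {
  structure(list(layers = clone_layers(encoder$layers), cfg = encoder$cfg),
            class = "pvl_encoder")
}

clone_fusion_model <- function(model) {
  structure(list(encoder = clone_layers_encoder(model$encoder),
                 clin = clone_layers(model$clin),
                 attn = clone_layers(model$attn),
                 head = clone_layers(model$head),
                 fcfg = model$fcfg, n_covariates = model$n_covariates),
            class = "pvl_fusion_model")
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d)) V` with the softmax taken row-wise (over keys for
#' each query). Exported both as the fusion primitive and so that tests can
#' check it against a brute-force oracle.
#'
#' @param Q queries, T x d matrix. @param K keys, m x d. @param V values,
#'   m x dv. @param d scaling dimension; defaults to `ncol(Q)`.
#' @return list with `out` (T x dv) and row-stochastic `weights` (T x m).
#' @export
scaled_dot_attention <- function(Q, K, V, d = ncol(Q)) {
  if (d <= 0) stop("attention scaling dimension d must be positive")
  if (ncol(Q) != ncol(K)) stop("Q and K must share their projected dimension")
  S <- Q %*% t(K) / sqrt(d)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  list(out = A %*% V, weights = A)
}

#' Encode standardized clinical covariates into the 64-dim embedding
#'
#' @param model a `pvl_fusion_model`.
#' @param x numeric matrix (n x covariates) of standardized covariates, or a
#'   named numeric vector for a single record.
#' @return n x 64 embedding matrix.
#' @export
encode_clinical <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_covariates) {
    stop("encode_clinical: expected ", model$n_covariates,
         " covariates, got ", ncol(x))
  }
  if (any(!is.finite(x))) stop("encode_clinical: non-finite covariates")
  f <- seq_forward(model$clin, x, training = FALSE)
  f$out
}

#' Fuse imaging tokens with a clinical embedding by cross-attention
#'
#' Image tokens are projected to queries, the clinical embedding (reshaped to
#' m tokens) to keys and values; the attended token grid is mean-pooled into a
#' single fused vector.
#'
#' @param img_tokens T x d_model matrix of imaging tokens.
#' @param clin_embed length-64 clinical embedding vector.
#' @param model a `pvl_fusion_model` (for the learned projections).
#' @return list with `fused` (length d_attn), `weights` (T x m attention
#'   matrix) and the intermediate Q/K/V (used by the backward pass).
#' @export
cross_attention_fuse <- function(img_tokens, clin_embed, model) {
  fcfg <- model$fcfg
  tok <- matrix(clin_embed, nrow = fcfg$m_tokens, ncol = fcfg$token_dim,
                byrow = TRUE)
  Q <- img_tokens %*% model$attn$Wq
  K <- tok %*% model$attn$Wk
  V <- tok %*% model$attn$Wv
  att <- scaled_dot_attention(Q, K, V, d = fcfg$d_attn)
  list(fused = colMeans(att$out), weights = att$weights,
       Q = Q, K = K, V = V, tok = tok, img_tokens = img_tokens)
}

# Backward through cross_attention_fuse for one sample.
# dfused: length d_attn gradient. Returns gradients for the projections, the
# image tokens and the clinical embedding vector.
cross_attention_backward <- function(cache, dfused, model) {
  fcfg <- model$fcfg
  Tn <- nrow(cache$Q)
  A <- cache$weights
  dO <- matrix(dfused, nrow = Tn, ncol = fcfg$d_attn, byrow = TRUE) / Tn
  dA <- dO %*% t(cache$V)                     # T x m
  dV <- t(A) %*% dO                           # m x d
  dS <- A * (dA - rowSums(dA * A))            # softmax backward, T x m
  dS <- dS / sqrt(fcfg$d_attn)
  dQ <- dS %*% cache$K
  dK <- t(dS) %*% cache$Q
  dWq <- t(cache$img_tokens) %*% dQ
  dWk <- t(cache$tok) %*% dK
  dWv <- t(cache$tok) %*% dV
  dimg <- dQ %*% t(model$attn$Wq)
  dtok <- dK %*% t(model$attn$Wk) + dV %*% t(model$attn$Wv)
  dclin <- as.vector(t(dtok))                 # undo byrow reshape
  list(Wq = dWq, Wk = dWk, Wv = dWv, dimg = dimg, dclin = dclin)
}

#' Sigmoid classification head
#'
#' `p = sigmoid(W . F + b)` on the fused feature vector.
#'
#' @param fused fused feature vector (or n x d matrix).
#' @param W weight vector/matrix of the classification layer.
#' @param b bias.
#' @return probability in (0, 1).
#' @export
classify_fused <- function(fused, W, b) {
  if (is.null(dim(fused))) fused <- matrix(fused, nrow = 1)
  z <- as.vector(fused %*% matrix(W, ncol = 1) + b)
  1 / (1 + exp(-z))
}

#' Binary cross-entropy loss
#'
#' Probabilities are clamped to `[eps, 1 - eps]` so the loss is always finite.
#' Optional per-sample weights scale each term before averaging (used for the
#' class-balanced fine-tuning objective).
#'
#' @param y binary labels. @param p predicted probabilities.
#' @param weights optional per-sample weights. @param eps clamp epsilon.
#' @return scalar loss (non-negative).
#' @export
bce_loss <- function(y, p, weights = NULL, eps = 1e-7) {
  if (length(y) != length(p)) stop("bce_loss: length mismatch")
  if (length(y) < 1) stop("bce_loss: empty batch")
  if (!all(y %in% c(0, 1))) stop("bce_loss: labels must be binary")
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

# Gradient of the (weighted) BCE w.r.t. the logit z where p = sigmoid(z):
# dL/dz = w * (p - y) / N.
bce_logit_grad <- function(y, p, weights = NULL, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  w * (p - y) / length(y)
}

# ---------------------------------------------------------------------------
# Full forward/backward over a batch.
# patches: list of (d,h,w,3) arrays; clin: n x covariates matrix.
# ---------------------------------------------------------------------------

fusion_forward <- function(model, patches, clin, training = TRUE) {
  fm <- fmap_from_arrays(patches)
  enc <- encoder_forward(model$encoder, fm, training)
  n <- fm$n
  Tn <- prod(enc$out$dims)
  cl <- seq_forward(model$clin, clin, training)
  att <- vector("list", n)
  fused <- matrix(0, n, model$fcfg$d_attn)
  for (s in seq_len(n)) {
    tokens <- enc$out$x[((s - 1) * Tn + 1):(s * Tn), , drop = FALSE]
    att[[s]] <- cross_attention_fuse(tokens, cl$out[s, ], model)
    fused[s, ] <- att[[s]]$fused
  }
  hd <- forward(model$head, fused, training)
  logit <- as.vector(hd$out)
  list(p = 1 / (1 + exp(-logit)), logit = logit,
       cache = list(enc = enc, cl = cl, att = att, hd = hd$cache,
                    fused = fused, n = n, Tn = Tn, enc_dims = enc$out$dims))
}

# dlogit: length-n gradient of the loss w.r.t. the logits.
# through_encoder = FALSE stops after computing the gradient w.r.t. the
# encoder output tokens (used by Grad-CAM, where only that gradient matters).
fusion_backward <- function(model, cache, dlogit, through_encoder = TRUE) {
  hb <- backward(model$head, cache$hd, matrix(dlogit, ncol = 1))
  grads <- list(head = hb$grads)
  n <- cache$n
  Tn <- cache$Tn
  d_tokens <- matrix(0, n * Tn, ncol(cache$att[[1]]$img_tokens))
  dclin <- matrix(0, n, model$fcfg$clin_embed_dim)
  aWq <- aWk <- aWv <- NULL
  for (s in seq_len(n)) {
    ab <- cross_attention_backward(cache$att[[s]], hb$dx[s, ], model)
    d_tokens[((s - 1) * Tn + 1):(s * Tn), ] <- ab$dimg
    dclin[s, ] <- ab$dclin
    aWq <- if (is.null(aWq)) ab$Wq else aWq + ab$Wq
    aWk <- if (is.null(aWk)) ab$Wk else aWk + ab$Wk
    aWv <- if (is.null(aWv)) ab$Wv else aWv + ab$Wv
  }
  grads$attn <- list(Wq = aWq, Wk = aWk, Wv = aWv)
  clb <- seq_backward(model$clin, cache$cl$caches, dclin)
  names(clb$grads) <- names(model$clin)
  grads$clin <- clb$grads
  d_tok_fmap <- fmap(d_tokens, cache$enc_dims, n)
  if (through_encoder) {
    eb <- encoder_backward(model$encoder, cache$enc$caches, d_tok_fmap)
    grads$encoder <- eb$grads
  }
  list(grads = grads, d_tokens = d_tok_fmap)
}

fusion_param_refs <- function(model, encoder = TRUE) {
  refs <- c(if (encoder) collect_params(model$encoder$layers, "encoder."),
            collect_params(model$clin, "clin."),
            collect_params(model$attn, "attn."),
            collect_params(model$head, "head."))
  refs
}

# Batched inference over many volumes: tile each volume, run the fusion
# model over all tiles in chunks, average per-volume probabilities.
predict_volumes <- function(model, vols, clin_matrix, patch_size = 64L,
                            chunk = 16L) {
  tiles <- lapply(vols, inference_patches, patch_size = patch_size)
  patches <- unlist(lapply(tiles, `[[`, "patches"), recursive = FALSE)
  owner <- rep(seq_along(vols), vapply(tiles, function(t) length(t$patches),
                                       integer(1)))
  clin_rows <- clin_matrix[owner, , drop = FALSE]
  probs <- numeric(length(patches))
  for (start in seq(1, length(patches), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(patches))
    f <- fusion_forward(model, patches[idx],
                        clin_rows[idx, , drop = FALSE], training = FALSE)
    probs[idx] <- f$p
  }
  as.numeric(tapply(probs, owner, mean))
}

#' Predict the leak probability for one preprocessed volume
#'
#' Tiles the volume into patches with [inference_patches()], runs the model on
#' each patch and averages the per-patch probabilities.
#'
#' @param model a `pvl_fusion_model`.
#' @param vol a preprocessed (d1,d2,d3,3) array.
#' @param clin standardized covariate vector for the patient.
#' @param patch_size patch edge length.
#' @return averaged probability.
#' @export
predict_volume <- function(model, vol, clin, patch_size = 64L) {
  tiles <- inference_patches(vol, patch_size = patch_size)
  clin_m <- matrix(clin, nrow = length(tiles$patches), ncol = length(clin),
                   byrow = TRUE)
  f <- fusion_forward(model, tiles$patches, clin_m, training = FALSE)
  sum(f$p * tiles$weights) / sum(tiles$weights)
}

# ---------------------------------------------------------------------------
# Checkpointing: one file holding the parameter/buffer arrays, with a JSON
# sidecar describing the architecture so checkpoints are self-describing.
# ---------------------------------------------------------------------------

#' Save / load model checkpoints
#'
#' @param model a `pvl_fusion_model` or `pvl_encoder`.
#' @param path checkpoint file path; a `<path>.json` sidecar with the
#'   architecture configuration is written beside it.
#' @export
save_checkpoint <- function(model, path) {
  is_enc <- inherits(model, "pvl_encoder")
  root <- if (is_enc) model$layers else model[c("encoder", "clin", "attn", "head")]
  state <- list(params = get_param_values(collect_params(root)),
                buffers = get_param_values(collect_buffers(root)))
  cfg <- if (is_enc) {
    list(kind = "encoder", encoder = unclass(model$cfg))
  } else {
    list(kind = "fusion", encoder = unclass(model$encoder$cfg),
         fusion = unclass(model$fcfg), n_covariates = model$n_covariates)
  }
  saveRDS(list(config = cfg, state = state), path)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return for `load_checkpoint`, the reconstructed model.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config
  if (cfg$kind == "encoder") {
    enc <- build_encoder(do.call(encoder_config,
                                 cfg$encoder[c("width_factor", "in_channels",
                                               "blocks", "stem_pool",
                                               "stage_strides")]), seed = 1L)
    set_param_values(collect_params(enc$layers), ck$state$params)
    set_param_values(collect_buffers(enc$layers), ck$state$buffers)
    enc
  } else {
    enc <- build_encoder(do.call(encoder_config,
                                 cfg$encoder[c("width_factor", "in_channels",
                                               "blocks", "stem_pool",
                                               "stage_strides")]), seed = 1L)
    fcfg <- do.call(fusion_config,
                    cfg$fusion[c("clin_embed_dim", "m_tokens", "d_attn",
                                 "hidden", "qk_init_scale")])
    model <- build_fusion_model(enc, cfg$n_covariates, fcfg, seed = 1L)
    root <- model[c("encoder", "clin", "attn", "head")]
    set_param_values(collect_params(root), ck$state$params)
    set_param_values(collect_buffers(root), ck$state$buffers)
    model
  }
}
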