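#' @useDynLib pvlnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Minimal deep-learning engine.
#
# A feature map ("fmap") is a list(x, dims, n):
#   x    : (n * L) x C numeric matrix, L = prod(dims) voxel locations in
#          column-major order (first axis fastest), samples stacked row-wise
#   dims : c(d1, d2, d3) spatial extents
#   n    : batch size
# This layout makes batch norm and ReLU plain matrix ops and turns 3D
# convolution into im2col (C++) + one BLAS GEMM.
#
# Layers are environments so that parameters and optimizer state can be
# updated in place; every layer implements forward(inp, training) returning
# list(out, cache) and backward(cache, dout) returning list(dx, grads).
# ---------------------------------------------------------------------------

fmap <- function(x, dims, n) {
  stopifnot(nrow(x) == n * prod(dims))
  list(x = x, dims = as.integer(dims), n = as.integer(n))
}

# Stack a list of (d1,d2,d3,C) arrays into one fmap.
fmap_from_arrays <- function(arrays) {
  d <- dim(arrays[[1]])
  stopifnot(length(d) == 4)
  L <- prod(d[1:3])
  x <- do.call(rbind, lapply(arrays, function(a) {
    stopifnot(identical(dim(a), d))
    dim(a) <- c(L, d[4])
    a
  }))
  fmap(x, d[1:3], length(arrays))
}

# Extract sample s of an fmap as a (d1,d2,d3,C) array.
fmap_sample <- function(fm, s) {
  L <- prod(fm$dims)
  a <- fm$x[((s - 1) * L + 1):(s * L), , drop = FALSE]
  dim(a) <- c(fm$dims, ncol(fm$x))
  a
}

new_layer <- function(kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("pvl_", kind), "pvl_layer")
  e
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# -- convolution -------------------------------------------------------------

conv3d_layer <- function(in_ch, out_ch, ksize = c(3L, 3L, 3L),
                         stride = c(1L, 1L, 1L), pad = (ksize - 1L) %/% 2L) {
  K <- prod(ksize)
  new_layer("conv3d",
            in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
            ksize = as.integer(ksize), stride = as.integer(stride),
            pad = as.integer(pad),
            W = he_init(in_ch * K, out_ch, in_ch * K))
}

conv_out_dims <- function(dims, ksize, stride, pad) {
  as.integer((dims + 2L * pad - ksize) %/% stride + 1L)
}

forward.pvl_conv3d <- function(layer, inp, training = TRUE) {
  if (ncol(inp$x) != layer$in_ch) stop("conv3d: channel mismatch")
  odims <- conv_out_dims(inp$dims, layer$ksize, layer$stride, layer$pad)
  cols <- im2col3(inp$x, inp$dims, layer$ksize, layer$stride, layer$pad,
                  inp$n)
  out <- fmap(cols %*% layer$W, odims, inp$n)
  list(out = out, cache = list(cols = cols, idims = inp$dims, odims = odims,
                               n = inp$n))
}

backward.pvl_conv3d <- function(layer, cache, dout) {
  dW <- crossprod(cache$cols, dout$x)
  dcols <- dout$x %*% t(layer$W)
  dx <- col2im3(dcols, cache$idims, layer$ksize, layer$stride, layer$pad,
                layer$in_ch, cache$n)
  list(dx = fmap(dx, cache$idims, cache$n), grads = list(W = dW))
}

# -- batch normalization -----------------------------------------------------

bn_layer <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", ch = as.integer(ch), momentum = momentum, eps = eps,
            gamma = rep(1, ch), beta = rep(0, ch),
            run_mean = rep(0, ch), run_var = rep(1, ch))
}

# column-wise broadcast helpers (column-major recycling; faster than sweep)
.bycol <- function(v, m) rep(v, each = m)

forward.pvl_bn <- function(layer, inp, training = TRUE) {
  x <- inp$x
  m <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - .bycol(mu, m)
    v <- colMeans(xc * xc)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- x - .bycol(mu, m)
  }
  istd <- 1 / sqrt(v + layer$eps)
  xh <- xc * .bycol(istd, m)
  out <- xh * .bycol(layer$gamma, m) + .bycol(layer$beta, m)
  list(out = fmap(out, inp$dims, inp$n),
       cache = list(xh = xh, istd = istd, dims = inp$dims, n = inp$n,
                    training = training))
}

backward.pvl_bn <- function(layer, cache, dout) {
  dy <- dout$x
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xh)
  dbeta <- colSums(dy)
  dxh <- dy * .bycol(layer$gamma, m)
  if (cache$training) {
    # standard batch-norm backward through the batch statistics
    dx <- (dxh - .bycol(colMeans(dxh), m) -
             cache$xh * .bycol(colMeans(dxh * cache$xh), m)) *
      .bycol(cache$istd, m)
  } else {
    dx <- dxh * .bycol(cache$istd, m)
  }
  list(dx = fmap(dx, cache$dims, cache$n),
       grads = list(gamma = dgamma, beta = dbeta))
}

# -- ReLU --------------------------------------------------------------------

relu_layer <- function() new_layer("relu")

forward.pvl_relu <- function(layer, inp, training = TRUE) {
  mask <- inp$x > 0
  list(out = fmap(inp$x * mask, inp$dims, inp$n),
       cache = list(mask = mask, dims = inp$dims, n = inp$n))
}

backward.pvl_relu <- function(layer, cache, dout) {
  list(dx = fmap(dout$x * cache$mask, cache$dims, cache$n), grads = list())
}

# -- max pooling -------------------------------------------------------------

maxpool_layer <- function(ksize = c(3L, 3L, 3L), stride = c(2L, 2L, 2L),
                          pad = c(1L, 1L, 1L)) {
  new_layer("maxpool", ksize = as.integer(ksize), stride = as.integer(stride),
            pad = as.integer(pad))
}

forward.pvl_maxpool <- function(layer, inp, training = TRUE) {
  odims <- conv_out_dims(inp$dims, layer$ksize, layer$stride, layer$pad)
  res <- maxpool3_fwd(inp$x, inp$dims, layer$ksize, layer$stride, layer$pad,
                      inp$n)
  list(out = fmap(res$out, odims, inp$n),
       cache = list(argmax = res$argmax, Lin = nrow(inp$x),
                    odims = odims, idims = inp$dims, n = inp$n))
}

backward.pvl_maxpool <- function(layer, cache, dout) {
  dx <- maxpool3_bwd(dout$x, cache$argmax, cache$Lin)
  list(dx = fmap(dx, cache$idims, cache$n), grads = list())
}

# -- global average pooling: fmap -> n x C matrix ----------------------------

gap_layer <- function() new_layer("gap")

forward.pvl_gap <- function(layer, inp, training = TRUE) {
  L <- prod(inp$dims)
  idx <- rep(seq_len(inp$n), each = L)
  out <- rowsum(inp$x, idx, reorder = TRUE) / L
  list(out = out, cache = list(L = L, dims = inp$dims, n = inp$n))
}

backward.pvl_gap <- function(layer, cache, dout) {
  dx <- dout[rep(seq_len(cache$n), each = cache$L), , drop = FALSE] / cache$L
  list(dx = fmap(dx, cache$dims, cache$n), grads = list())
}

# -- dense layer on plain matrices ------------------------------------------

linear_layer <- function(in_dim, out_dim, init_sd = sqrt(2 / in_dim)) {
  new_layer("linear", in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
            W = matrix(rnorm(in_dim * out_dim, sd = init_sd), in_dim, out_dim),
            b = rep(0, out_dim))
}

forward.pvl_linear <- function(layer, inp, training = TRUE) {
  out <- sweep(inp %*% layer$W, 2, layer$b, `+`)
  list(out = out, cache = list(x = inp))
}

backward.pvl_linear <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

relu_mat_layer <- function() new_layer("relu_mat")

forward.pvl_relu_mat <- function(layer, inp, training = TRUE) {
  mask <- inp > 0
  list(out = inp * mask, cache = list(mask = mask))
}

backward.pvl_relu_mat <- function(layer, cache, dout) {
  list(dx = dout * cache$mask, grads = list())
}

# -- residual basic block ----------------------------------------------------

resblock_layer <- function(in_ch, out_ch, stride = c(1L, 1L, 1L)) {
  down <- any(stride != 1L) || in_ch != out_ch
  new_layer("resblock",
            conv1 = conv3d_layer(in_ch, out_ch, stride = stride),
            bn1 = bn_layer(out_ch),
            conv2 = conv3d_layer(out_ch, out_ch),
            bn2 = bn_layer(out_ch),
            down_conv = if (down) conv3d_layer(in_ch, out_ch,
                                               ksize = c(1L, 1L, 1L),
                                               stride = stride,
                                               pad = c(0L, 0L, 0L)),
            down_bn = if (down) bn_layer(out_ch),
            has_down = down)
}

forward.pvl_resblock <- function(layer, inp, training = TRUE) {
  f1 <- forward(layer$conv1, inp, training)
  f2 <- forward(layer$bn1, f1$out, training)
  a1 <- f2$out
  relu_mask1 <- a1$x > 0
  a1$x <- a1$x * relu_mask1
  f3 <- forward(layer$conv2, a1, training)
  f4 <- forward(layer$bn2, f3$out, training)
  if (layer$has_down) {
    s1 <- forward(layer$down_conv, inp, training)
    s2 <- forward(layer$down_bn, s1$out, training)
    skip <- s2$out
    skip_cache <- list(c1 = s1$cache, c2 = s2$cache)
  } else {
    skip <- inp
    skip_cache <- NULL
  }
  pre <- f4$out
  pre$x <- pre$x + skip$x
  relu_mask2 <- pre$x > 0
  pre$x <- pre$x * relu_mask2
  list(out = pre,
       cache = list(c1 = f1$cache, c2 = f2$cache, c3 = f3$cache,
                    c4 = f4$cache, skip = skip_cache,
                    m1 = relu_mask1, m2 = relu_mask2))
}

backward.pvl_resblock <- function(layer, cache, dout) {
  dpre <- dout
  dpre$x <- dpre$x * cache$m2
  grads <- list()
  b4 <- backward(layer$bn2, cache$c4, dpre)
  grads$bn2 <- b4$grads
  b3 <- backward(layer$conv2, cache$c3, b4$dx)
  grads$conv2 <- b3$grads
  da1 <- b3$dx
  da1$x <- da1$x * cache$m1
  b2 <- backward(layer$bn1, cache$c2, da1)
  grads$bn1 <- b2$grads
  b1 <- backward(layer$conv1, cache$c1, b2$dx)
  grads$conv1 <- b1$grads
  dx <- b1$dx
  if (layer$has_down) {
    bs2 <- backward(layer$down_bn, cache$skip$c2, dpre)
    grads$down_bn <- bs2$grads
    bs1 <- backward(layer$down_conv, cache$skip$c1, bs2$dx)
    grads$down_conv <- bs1$grads
    dx$x <- dx$x + bs1$dx$x
  } else {
    dx$x <- dx$x + dpre$x
  }
  list(dx = dx, grads = grads)
}

# -- generic dispatch --------------------------------------------------------

forward <- function(layer, inp, training = TRUE) UseMethod("forward")
backward <- function(layer, cache, dout) UseMethod("backward")

# Sequential container over a list of layers.
seq_forward <- function(layers, inp, training = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- forward(layers[[i]], inp, training)
    inp <- f$out
    caches[[i]] <- f$cache
  }
  list(out = inp, caches = caches)
}

seq_backward <- function(layers, caches, dout, accumulate = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- backward(layers[[i]], caches[[i]], dout)
    dout <- b$dx
    grads[[i]] <- b$grads
  }
  list(dx = dout, grads = grads)
}

# ---------------------------------------------------------------------------
# Parameter bookkeeping: walk a model structure, returning references
# (environment + field name) for every trainable array. BN running stats are
# buffers, not parameters.
# ---------------------------------------------------------------------------

.param_fields <- list(conv3d = "W", bn = c("gamma", "beta"),
                      linear = c("W", "b"),
                      attention = c("Wq", "Wk", "Wv"))
.buffer_fields <- list(bn = c("run_mean", "run_var"))
.sub_layer_fields <- list(resblock = c("conv1", "bn1", "conv2", "bn2",
                                       "down_conv", "down_bn"))

collect_params <- function(layer, prefix = "") {
  out <- list()
  if (inherits(layer, "pvl_layer")) {
    for (f in .param_fields[[layer$kind]] %||% character()) {
      out[[paste0(prefix, f)]] <- list(env = layer, field = f)
    }
    for (sub in .sub_layer_fields[[layer$kind]] %||% character()) {
      child <- layer[[sub]]
      if (!is.null(child)) {
        out <- c(out, collect_params(child, paste0(prefix, sub, ".")))
      }
    }
  } else if (is.list(layer)) {
    nms <- names(layer) %||% as.character(seq_along(layer))
    for (i in seq_along(layer)) {
      out <- c(out, collect_params(layer[[i]], paste0(prefix, nms[i], ".")))
    }
  }
  out
}

get_param_values <- function(refs) {
  lapply(refs, function(r) get(r$field, envir = r$env))
}

set_param_values <- function(refs, values) {
  for (i in seq_along(refs)) {
    assign(refs[[i]]$field, values[[i]], envir = refs[[i]]$env)
  }
  invisible(NULL)
}

collect_buffers <- function(layer, prefix = "") {
  out <- list()
  if (inherits(layer, "pvl_layer")) {
    for (f in .buffer_fields[[layer$kind]] %||% character()) {
      out[[paste0(prefix, f)]] <- list(env = layer, field = f)
    }
    for (sub in .sub_layer_fields[[layer$kind]] %||% character()) {
      child <- layer[[sub]]
      if (!is.null(child)) {
        out <- c(out, collect_buffers(child, paste0(prefix, sub, ".")))
      }
    }
  } else if (is.list(layer)) {
    nms <- names(layer) %||% as.character(seq_along(layer))
    for (i in seq_along(layer)) {
      out <- c(out, collect_buffers(layer[[i]], paste0(prefix, nms[i], ".")))
    }
  }
  out
}

# Deep copy of a layer / layer list (fresh environments).
clone_layers <- function(layer) {
  if (inherits(layer, "pvl_layer")) {
    e <- new.env(parent = emptyenv())
    for (nm in ls(layer, all.names = TRUE)) {
      v <- get(nm, envir = layer)
      assign(nm, if (inherits(v, "pvl_layer")) clone_layers(v) else v, envir = e)
    }
    class(e) <- class(layer)
    e
  } else if (is.list(layer)) {
    lapply(layer, clone_layers)
  } else {
    layer
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

count_params <- function(layer) {
  sum(vapply(get_param_values(collect_params(layer)), length, integer(1)))
}
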