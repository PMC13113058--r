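# Adam with decoupled-from-nothing classic L2 (weight decay added to the
# gradient, as in torch's Adam(weight_decay=)). State lives beside the
# parameter references so a model can be trained across calls.

adam_state <- function(refs, lr = 1e-4, weight_decay = 1e-5,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  vals <- get_param_values(refs)
  list(refs = refs, lr = lr, wd = weight_decay, beta1 = beta1, beta2 = beta2,
       eps = eps, t = 0L,
       m = lapply(vals, function(v) v * 0),
       v = lapply(vals, function(v) v * 0))
}

# grads: named list aligned with opt$refs (same names/order).
adam_step <- function(opt, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    p <- get(r$field, envir = r$env)
    g <- grads[[names(opt$refs)[i]]]
    if (is.null(g)) next
    if (opt$wd > 0) g <- g + opt$wd * p
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    lr_i <- opt$lr * (opt$lr_scale[i] %||% 1)
    step <- lr_i * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    assign(r$field, p - step, envir = r$env)
  }
  opt
}

# Flatten the nested per-layer gradient lists produced by seq_backward /
# composite backward calls into the flat named form adam_step expects.
flatten_grads <- function(grads, prefix = "") {
  out <- list()
  if (is.list(grads) && is.null(dim(grads))) {
    nms <- names(grads) %||% as.character(seq_along(grads))
    for (i in seq_along(grads)) {
      g <- grads[[i]]
      if (is.list(g)) {
        out <- c(out, flatten_grads(g, paste0(prefix, nms[i], ".")))
      } else if (!is.null(g)) {
        out[[paste0(prefix, nms[i])]] <- g
      }
    }
  }
  out
}

# Sum two flat gradient lists (for gradient accumulation across branches).
add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
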