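# Fingerprint model: a CNN trunk ending in global average pooling (the
# fingerprint layer) plus a linear identity head. Two profiles share the
# contract: "tiny" (3 conv blocks, configurable fingerprint dimension,
# trainable on a CPU) and "resnet34" (the reference backbone; 512-d
# fingerprints, forward pass only).

#' Create a fingerprint network
#'
#' Builds a randomly initialised convolutional network that maps 224x224 RGB
#' patches to (i) an identity classification vector of length `n_identities`
#' and (ii) a fingerprint: the feature vector from the final global-average
#' pooled layer, taken immediately before the identity head.
#'
#' @param n_identities Number of identity classes (core indices during
#'   training, e.g. 207 for a 207-core array).
#' @param profile `"tiny"` (3 conv blocks after a 4x4 average-pool stem;
#'   trainable at desk scale), `"tiny2"` (a 2x2 stem and 4 conv blocks:
#'   twice the input resolution for nuclear-scale texture, ~4x the compute)
#'   or `"resnet34"` (the reference residual backbone whose pooled feature
#'   layer is 512-dimensional).
#' @param fingerprint_dim Fingerprint length `D`. Configurable for the tiny
#'   profile (default 32); fixed at 512 for `"resnet34"`.
#' @param normalize Input normalization applied inside the forward pass:
#'   `"center"` (map `[0, 1]` to `[-1, 1]`; the default) or `"standardize"`
#'   (per-patch zero mean/unit variance). Standardization largely removes
#'   global stain/brightness differences at the input; centering preserves
#'   them, leaving style invariance to the loss -- the trainable profiles
#'   rely on batch normalization for conditioning either way.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `fp_model`.
#' @examples
#' m <- fp_model(n_identities = 8, profile = "tiny", fingerprint_dim = 16, seed = 1)
#' x <- array(runif(224 * 224 * 3), c(224, 224, 3))
#' out <- predict(m, x)
#' dim(out$fingerprint)
#' @export
fp_model <- function(n_identities, profile = c("tiny", "tiny2", "resnet34"),
                     fingerprint_dim = NULL, normalize = NULL, seed = 1L) {
  profile <- match.arg(profile)
  if (!is.null(normalize)) {
    normalize <- match.arg(normalize, c("standardize", "center"))
  }
  if (!is.numeric(n_identities) || n_identities < 1) {
    invalid_arg("n_identities must be a positive integer")
  }
  n_identities <- as.integer(n_identities)
  model <- with_seed(derive_seed(seed, 101L), {
    if (profile == "tiny") {
      D <- if (is.null(fingerprint_dim)) 32L else as.integer(fingerprint_dim)
      layers <- list(
        list(type = "avgpool", k = 4L),
        new_conv(3L, 16L, 3L, 1L, 1L), new_bn_t(16L), list(type = "relu"),
        list(type = "maxpool", k = 2L, stride = 2L, pad = 0L),
        new_conv(16L, 32L, 3L, 1L, 1L), new_bn_t(32L), list(type = "relu"),
        list(type = "maxpool", k = 2L, stride = 2L, pad = 0L),
        new_conv(32L, D, 3L, 1L, 1L), new_bn_t(D), list(type = "relu")
      )
      list(layers = layers, D = D)
    } else if (profile == "tiny2") {
      D <- if (is.null(fingerprint_dim)) 32L else as.integer(fingerprint_dim)
      layers <- list(
        list(type = "avgpool", k = 2L),
        new_conv(3L, 16L, 3L, 1L, 1L), new_bn_t(16L), list(type = "relu"),
        list(type = "maxpool", k = 2L, stride = 2L, pad = 0L),
        new_conv(16L, 32L, 3L, 1L, 1L), new_bn_t(32L), list(type = "relu"),
        list(type = "maxpool", k = 2L, stride = 2L, pad = 0L),
        new_conv(32L, 32L, 3L, 1L, 1L), new_bn_t(32L), list(type = "relu"),
        list(type = "maxpool", k = 2L, stride = 2L, pad = 0L),
        new_conv(32L, D, 3L, 1L, 1L), new_bn_t(D), list(type = "relu")
      )
      list(layers = layers, D = D)
    } else {
      if (!is.null(fingerprint_dim) && fingerprint_dim != 512L) {
        invalid_arg("the resnet34 profile has a fixed 512-dimensional fingerprint")
      }
      list(layers = resnet34_trunk(), D = 512L)
    }
  })
  # zero-initialised head: initial logits are uniform, so early CE gradients
  # reflect the features rather than random head noise
  head <- list(W = matrix(0, model$D, n_identities), b = numeric(n_identities))
  structure(list(profile = profile, n_identities = n_identities,
                 fingerprint_dim = model$D, layers = model$layers,
                 head = head, input_size = 224L, seed = as.integer(seed),
                 normalize = normalize %||% "center"),
            class = "fp_model")
}

# Standard 34-layer residual trunk: 7x7/2 stem, 3-4-6-3 basic blocks at
# 64/128/256/512 channels, global average pool -> 512 features.
resnet34_trunk <- function() {
  stem <- list(
    new_conv(3L, 64L, 7L, 2L, 3L), new_bn(64L), list(type = "relu"),
    list(type = "maxpool", k = 3L, stride = 2L, pad = 1L)
  )
  stage <- function(cin, cout, n, stride1) {
    lapply(seq_len(n), function(i) {
      s <- if (i == 1L) stride1 else 1L
      ci <- if (i == 1L) cin else cout
      down <- if (s != 1L || ci != cout) {
        list(conv = new_conv(ci, cout, 1L, s, 0L), bn = new_bn(cout))
      }
      list(type = "block", conv1 = new_conv(ci, cout, 3L, s, 1L), bn1 = new_bn(cout),
           conv2 = new_conv(cout, cout, 3L, 1L, 1L), bn2 = new_bn(cout), down = down)
    })
  }
  c(stem, stage(64L, 64L, 3L, 1L), stage(64L, 128L, 4L, 2L),
    stage(128L, 256L, 6L, 2L), stage(256L, 512L, 3L, 2L))
}

# Coerce patch input to an [H, W, 3, B] batch. Accepts a single [H,W,3]
# array, a list of such arrays, or an [H,W,3,B] array.
as_patch_batch <- function(x) {
  if (is.list(x)) {
    stopifnot(length(x) >= 1L)
    d <- dim(x[[1]])
    out <- array(0, c(d, length(x)))
    for (i in seq_along(x)) out[, , , i] <- x[[i]]
    return(out)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(array(x, c(dim(x), 1L)))
  stopifnot(is.array(x), length(dim(x)) == 4L)
  x
}

# Full forward pass. Returns logits (n_identities x B) and fingerprints
# (D x B); with keep_cache = TRUE also per-layer caches for backprop (tiny
# profile layers only). `training` switches batch-norm to batch statistics.
nn_forward <- function(model, x, keep_cache = FALSE, training = FALSE) {
  x <- as_patch_batch(x)
  if (dim(x)[1] != model$input_size || dim(x)[2] != model$input_size || dim(x)[3] != 3L) {
    invalid_arg(sprintf("expected %dx%dx3 input patches",
                        model$input_size, model$input_size))
  }
  norm <- model$normalize %||% "center"
  if (norm == "standardize") {
    # Per-patch standardization (global mean/sd over all pixels and
    # channels): the trunk has no normalization layers, so this is what
    # keeps activations and gradients well-scaled. Channel offsets (color)
    # are preserved relative to each other.
    d <- dim(x)
    m2 <- x; dim(m2) <- c(d[1] * d[2] * d[3], d[4])
    mu <- colMeans(m2)
    sd_ <- sqrt(colMeans(m2^2) - mu^2) + 1e-6
    x <- array(sweep(sweep(m2, 2, mu), 2, sd_, "/"), d)
  } else if (norm == "center") {
    x <- 2 * (x - 0.5)
  }
  caches <- if (keep_cache) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      r <- conv_fwd(x, ly, keep_cache)
      if (keep_cache) { caches[[i]] <- r; x <- r$y } else x <- r
    } else if (ly$type == "relu") {
      if (keep_cache) caches[[i]] <- list(mask = x > 0)
      x <- relu_fwd(x)
    } else if (ly$type == "maxpool") {
      r <- maxpool_fwd(x, ly, keep_cache)
      if (keep_cache) { caches[[i]] <- r; x <- r$y } else x <- r
    } else if (ly$type == "avgpool") {
      r <- avgpool_fwd(x, ly, keep_cache)
      if (keep_cache) { caches[[i]] <- r; x <- r$y } else x <- r
    } else if (ly$type == "bnorm_t") {
      r <- bn_t_fwd(x, ly, training = training, keep_cache = keep_cache)
      if (keep_cache) { caches[[i]] <- r; x <- r$y } else x <- r
    } else if (ly$type == "bnorm") {
      x <- bnorm_fwd(x, ly)
    } else if (ly$type == "block") {
      x <- block_fwd(x, ly)
    } else stop("unknown layer type: ", ly$type)
  }
  gap_in_dim <- dim(x)
  fp <- gap_fwd(x)                                   # D x B
  logits <- crossprod(model$head$W, fp) + model$head$b
  out <- list(logits = logits, fingerprint = fp)
  if (keep_cache) {
    out$caches <- caches
    out$gap_in_dim <- gap_in_dim
  }
  out
}

# Backprop for the tiny profile. dlogits: n_id x B; dfp: D x B contribution
# arriving directly at the fingerprint layer (from the fingerprint-distance
# loss), may be NULL. Returns grads mirroring the parameter structure.
nn_backward <- function(model, fwd, dlogits, dfp = NULL) {
  dW_head <- fwd$fingerprint %*% t(dlogits)
  db_head <- rowSums(dlogits)
  df <- model$head$W %*% dlogits
  if (!is.null(dfp)) df <- df + dfp
  dx <- gap_bwd(df, fwd$gap_in_dim)
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    cc <- fwd$caches[[i]]
    if (ly$type == "conv") {
      r <- conv_bwd(dx, ly, cc)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dx <- r$dx
    } else if (ly$type == "bnorm_t") {
      r <- bn_t_bwd(dx, ly, cc)
      grads[[i]] <- list(dW = r$dW, db = r$db,
                         rmean = cc$new_rmean, rvar = cc$new_rvar)
      dx <- r$dx
    } else if (ly$type == "relu") {
      dx <- dx * cc$mask
    } else if (ly$type == "maxpool") {
      dx <- maxpool_bwd(dx, ly, cc)
    } else if (ly$type == "avgpool") {
      dx <- avgpool_bwd(dx, ly, cc)
    } else stop("backward not implemented for layer type: ", ly$type)
  }
  list(layers = grads, head = list(dW = dW_head, db = db_head))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(p) lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))
  st <- list(t = 0L, layers = vector("list", length(model$layers)),
             head = list(m = zero_like(model$head), v = zero_like(model$head)))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type %in% c("conv", "bnorm_t")) {
      p <- list(W = ly$W, b = ly$b)
      st$layers[[i]] <- list(m = zero_like(p), v = zero_like(p))
    }
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(model, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    pn <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    attributes(pn) <- attributes(p)   # keep matrix/vector shape intact
    list(p = pn, m = m, v = v)
  }
  for (i in seq_along(model$layers)) {
    if (is.null(grads$layers[[i]])) next
    ly <- model$layers[[i]]
    uW <- upd(ly$W, grads$layers[[i]]$dW, st$layers[[i]]$m$W, st$layers[[i]]$v$W)
    ub <- upd(ly$b, grads$layers[[i]]$db, st$layers[[i]]$m$b, st$layers[[i]]$v$b)
    model$layers[[i]]$W <- uW$p; st$layers[[i]]$m$W <- uW$m; st$layers[[i]]$v$W <- uW$v
    model$layers[[i]]$b <- ub$p; st$layers[[i]]$m$b <- ub$m; st$layers[[i]]$v$b <- ub$v
    if (ly$type == "bnorm_t") {   # refresh running stats from this step
      model$layers[[i]]$rmean <- grads$layers[[i]]$rmean
      model$layers[[i]]$rvar <- grads$layers[[i]]$rvar
    }
  }
  uW <- upd(model$head$W, grads$head$dW, st$head$m$W, st$head$v$W)
  ub <- upd(model$head$b, grads$head$db, st$head$m$b, st$head$v$b)
  model$head$W <- uW$p; st$head$m$W <- uW$m; st$head$v$W <- uW$v
  model$head$b <- ub$p; st$head$m$b <- ub$m; st$head$v$b <- ub$v
  list(model = model, state = st)
}

#' Run the network on patches
#'
#' @param object An [fp_model].
#' @param x A single 224x224x3 array, a list of them, or an
#'   `[224, 224, 3, B]` batch array, values in `[0, 1]`.
#' @param type `"both"` (default), `"fingerprint"`, `"logits"` or `"prob"`
#'   (softmax over identities).
#' @param ... Unused.
#' @return For `"both"` a list with `logits` (`n_identities x B`) and
#'   `fingerprint` (`D x B`) matrices; otherwise the single requested matrix.
#' @export
predict.fp_model <- function(object, x,
                             type = c("both", "fingerprint", "logits", "prob"), ...) {
  type <- match.arg(type)
  out <- nn_forward(object, x)
  switch(type,
         both = out[c("logits", "fingerprint")],
         fingerprint = out$fingerprint,
         logits = out$logits,
         prob = apply(out$logits, 2, function(z) { z <- z - max(z); e <- exp(z); e / sum(e) }))
}

#' @export
print.fp_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(ly) {
    if (ly$type == "conv") length(ly$W) + length(ly$b)
    else if (ly$type == "block") {
      length(ly$conv1$W) + length(ly$conv2$W) +
        (if (is.null(ly$down)) 0 else length(ly$down$conv$W))
    } else 0
  }, numeric(1))) + length(x$head$W) + length(x$head$b)
  cat(sprintf("<fp_model> profile=%s  identities=%d  fingerprint_dim=%d  ~%.2fM params\n",
              x$profile, x$n_identities, x$fingerprint_dim, n_par / 1e6))
  invisible(x)
}
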