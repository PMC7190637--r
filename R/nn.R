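# Minimal CNN engine on base R + BLAS. Convolution is im2col + GEMM; batches
# are [H, W, C, B] arrays. The trainable path (used by the tiny profile)
# implements backprop for avgpool/conv/relu/non-overlapping maxpool/global
# average pool/linear; the Resnet-34 profile additionally uses batch-norm and
# residual blocks, forward only.

# memoised im2col index tables keyed on geometry
.idx_cache <- new.env(parent = emptyenv())

# Linear indices into a padded [Hp, Wp, C, B] volume: a (B*P) x K matrix,
# P = outH*outW output positions (row-major in (oi, oj)), K = k*k*C kernel
# taps. Row block b holds image b.
im2col_idx <- function(Hp, Wp, C, B, k, s, outH, outW) {
  key <- paste(Hp, Wp, C, B, k, s, outH, outW, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  oi <- rep(seq_len(outH), times = outW)            # P
  oj <- rep(seq_len(outW), each = outH)
  ki <- rep(seq_len(k), times = k * C)              # K
  kj <- rep(rep(seq_len(k), each = k), times = C)
  kc <- rep(seq_len(C), each = k * k)
  row0 <- (oi - 1L) * s                              # P
  col0 <- (oj - 1L) * s
  # idx[p, t] = (row0[p]+ki[t]) + (col0[p]+kj[t]-1)*Hp + (kc[t]-1)*Hp*Wp
  idx <- outer(row0, ki, "+") +
    outer(col0, kj - 1L, "+") * Hp +
    matrix((kc - 1L) * Hp * Wp, nrow = outH * outW, ncol = k * k * C, byrow = TRUE)
  P <- outH * outW
  if (B > 1L) {
    idx <- idx[rep(seq_len(P), B), , drop = FALSE] +
      rep((seq_len(B) - 1L) * (Hp * Wp * C), each = P)
  }
  storage.mode(idx) <- "integer"  # all volumes here stay far below 2^31
  .idx_cache[[key]] <- idx
  idx
}

pad_batch <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

conv_fwd <- function(x, ly, keep_cache = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  k <- ly$k; s <- ly$stride; p <- ly$pad
  outH <- (H + 2 * p - k) %/% s + 1L
  outW <- (W + 2 * p - k) %/% s + 1L
  xp <- pad_batch(x, p)
  dp <- dim(xp)
  idx <- im2col_idx(dp[1], dp[2], C, B, k, s, outH, outW)
  dim(xp) <- NULL   # plain vector: a k*k*C == 4 column idx must not be
                    # mistaken for coordinate-tuple indexing
  cols <- matrix(xp[idx], nrow = nrow(idx))
  dim(xp) <- dp
  out <- cols %*% ly$W                       # (B*P) x Cout
  out <- out + rep(ly$b, each = nrow(out))
  y <- aperm(array(out, c(outH, outW, B, ncol(ly$W))), c(1, 2, 4, 3))
  if (!keep_cache) return(y)
  list(y = y, cols = cols, idx = idx, pdim = dp, outH = outH, outW = outW)
}

conv_bwd <- function(dy, ly, cache) {
  dp <- cache$pdim; B <- dp[4]
  P <- cache$outH * cache$outW
  dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), nrow = P * B)   # (B*P) x Cout
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(ly$W)
  dxp <- numeric(prod(dp))
  idx <- cache$idx
  for (j in seq_len(ncol(idx))) {
    jj <- idx[, j]
    dxp[jj] <- dxp[jj] + dcols[, j]
  }
  dim(dxp) <- dp
  p <- ly$pad
  dx <- if (p > 0) dxp[p + seq_len(dp[1] - 2 * p), p + seq_len(dp[2] - 2 * p), , , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# Pooling runs the channel dimension through the batch slot so the im2col
# table is channel-free.
pool_cols <- function(x, k, s, p) {
  d <- dim(x)
  xr <- array(x, c(d[1], d[2], 1L, d[3] * d[4]))
  xp <- pad_batch(xr, p)
  dp <- dim(xp)
  outH <- (d[1] + 2 * p - k) %/% s + 1L
  outW <- (d[2] + 2 * p - k) %/% s + 1L
  idx <- im2col_idx(dp[1], dp[2], 1L, d[3] * d[4], k, s, outH, outW)
  dim(xp) <- NULL
  list(cols = matrix(xp[idx], nrow = nrow(idx)), idx = idx, pdim = dp,
       outH = outH, outW = outW, d = d)
}

# Non-overlapping k x k average pool by reshaping (column-major layout: the
# row index runs fastest, so consecutive k-blocks fold onto the first axis).
avgpool_fwd <- function(x, ly, keep_cache = FALSE) {
  d <- dim(x); k <- ly$k
  H2 <- d[1] %/% k; W2 <- d[2] %/% k
  a <- .colMeans(x, k, length(x) %/% k)        # fold rows, no reshape copy
  dim(a) <- c(H2, k, W2 * d[3] * d[4])         # then fold columns
  y <- a[, 1, ]
  for (j in 2:k) y <- y + a[, j, ]
  y <- array(y / k, c(H2, W2, d[3], d[4]))
  if (!keep_cache) return(y)
  list(y = y, d = d)
}

avgpool_bwd <- function(dy, ly, cache) {
  d <- cache$d; k <- ly$k
  dy <- dy / (k * k)
  dy[rep(seq_len(d[1] %/% k), each = k), rep(seq_len(d[2] %/% k), each = k), , ,
     drop = FALSE]
}

# 2x2 stride-2 max pool via strided quadrant views; the general (k, stride,
# pad) form -- needed only forward, for the Resnet stem -- goes through
# pool_cols.
maxpool_fwd <- function(x, ly, keep_cache = FALSE) {
  d <- dim(x)
  if (ly$k == 2L && ly$stride == 2L && ly$pad == 0L &&
      d[1] %% 2L == 0L && d[2] %% 2L == 0L) {
    oi <- seq(1L, d[1], 2L); oj <- seq(1L, d[2], 2L)
    q <- list(x[oi, oj, , , drop = FALSE],     x[oi + 1L, oj, , , drop = FALSE],
              x[oi, oj + 1L, , , drop = FALSE], x[oi + 1L, oj + 1L, , , drop = FALSE])
    y <- q[[1]]
    am <- array(1L, dim(y))
    for (id in 2:4) {
      sel <- q[[id]] > y
      y[sel] <- q[[id]][sel]
      am[sel] <- id
    }
    if (!keep_cache) return(y)
    return(list(y = y, am = am, d = d, fast = TRUE))
  }
  pc <- pool_cols(x, ly$k, ly$stride, ly$pad)
  am <- max.col(pc$cols, ties.method = "first")
  m <- pc$cols[cbind(seq_along(am), am)]
  y <- array(m, c(pc$outH, pc$outW, pc$d[3], pc$d[4]))
  if (!keep_cache) return(y)
  stopifnot(ly$stride >= ly$k)  # backward assumes non-overlapping windows
  list(y = y, pc = pc, am = am, fast = FALSE)
}

maxpool_bwd <- function(dy, ly, cache) {
  if (isTRUE(cache$fast)) {
    d <- cache$d
    dx <- array(0, d)
    oi <- seq(1L, d[1], 2L); oj <- seq(1L, d[2], 2L)
    dx[oi, oj, , ]           <- dy * (cache$am == 1L)
    dx[oi + 1L, oj, , ]      <- dy * (cache$am == 2L)
    dx[oi, oj + 1L, , ]      <- dy * (cache$am == 3L)
    dx[oi + 1L, oj + 1L, , ] <- dy * (cache$am == 4L)
    return(dx)
  }
  pc <- cache$pc
  dxp <- numeric(prod(pc$pdim))
  tgt <- pc$idx[cbind(seq_along(cache$am), cache$am)]
  dxp[tgt] <- as.vector(dy)
  dim(dxp) <- pc$pdim
  p <- ly$pad
  if (p > 0) dxp <- dxp[p + seq_len(pc$d[1]), p + seq_len(pc$d[2]), , , drop = FALSE]
  array(dxp, pc$d)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }

bnorm_fwd <- function(x, ly) {
  d <- dim(x); HW <- d[1] * d[2]
  sc <- ly$gamma / sqrt(ly$var + ly$eps)
  sh <- ly$beta - ly$mean * sc
  x * as.vector(rep(sc, each = HW)) + as.vector(rep(sh, each = HW))
}

block_fwd <- function(x, blk) {  # Resnet basic block, inference only
  h <- conv_fwd(x, blk$conv1)
  h <- relu_fwd(bnorm_fwd(h, blk$bn1))
  h <- bnorm_fwd(conv_fwd(h, blk$conv2), blk$bn2)
  sc <- if (is.null(blk$down)) x else bnorm_fwd(conv_fwd(x, blk$down$conv), blk$down$bn)
  relu_fwd(h + sc)
}

gap_fwd <- function(x) {  # [H,W,C,B] -> C x B
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), nrow = d[3])
}

gap_bwd <- function(df, d) {  # df: C x B, d: input dims
  g <- rep(as.vector(df), each = d[1] * d[2]) / (d[1] * d[2])
  array(g, d)
}

# Trainable batch normalization (per channel over batch and space).
# Parameters live in $W (scale gamma) and $b (shift beta) so the optimiser
# treats them like any other layer; running statistics serve eval mode.
new_bn_t <- function(c) {
  list(type = "bnorm_t", W = rep(1, c), b = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = 0.1, eps = 1e-5)
}

bn_channel_stats <- function(x) {
  d <- dim(x)
  m2 <- x; dim(m2) <- c(d[1] * d[2], d[3] * d[4])
  cs <- colMeans(m2)
  cq <- colMeans(m2 * m2)
  dim(cs) <- c(d[3], d[4]); dim(cq) <- c(d[3], d[4])
  mu <- rowMeans(cs)
  list(mu = mu, var = pmax(rowMeans(cq) - mu^2, 0))
}

bn_t_fwd <- function(x, ly, training = FALSE, keep_cache = FALSE) {
  d <- dim(x); HW <- d[1] * d[2]
  if (training) {
    st <- bn_channel_stats(x)
    mu <- st$mu; va <- st$var
  } else {
    mu <- ly$rmean; va <- ly$rvar
  }
  invstd <- 1 / sqrt(va + ly$eps)
  mu_v <- rep(rep(mu, each = HW), times = d[4])
  is_v <- rep(rep(invstd, each = HW), times = d[4])
  xhat <- (x - mu_v) * is_v
  y <- xhat * rep(rep(ly$W, each = HW), times = d[4]) +
    rep(rep(ly$b, each = HW), times = d[4])
  if (!keep_cache) return(y)
  list(y = y, xhat = xhat, invstd = invstd,
       new_rmean = (1 - ly$momentum) * ly$rmean + ly$momentum * mu,
       new_rvar = (1 - ly$momentum) * ly$rvar + ly$momentum * va)
}

bn_t_bwd <- function(dy, ly, cache) {
  d <- dim(dy); HW <- d[1] * d[2]
  N <- HW * d[4]
  per_channel_sum <- function(a) {
    m2 <- a; dim(m2) <- c(HW, d[3] * d[4])
    cs <- colSums(m2); dim(cs) <- c(d[3], d[4])
    rowSums(cs)
  }
  dgamma <- per_channel_sum(dy * cache$xhat)
  dbeta <- per_channel_sum(dy)
  g_v <- rep(rep(ly$W, each = HW), times = d[4])
  dxhat <- dy * g_v
  s1 <- per_channel_sum(dxhat)
  s2 <- per_channel_sum(dxhat * cache$xhat)
  is_v <- rep(rep(cache$invstd, each = HW), times = d[4])
  s1_v <- rep(rep(s1, each = HW), times = d[4])
  s2_v <- rep(rep(s2, each = HW), times = d[4])
  dx <- is_v / N * (N * dxhat - s1_v - cache$xhat * s2_v)
  list(dx = dx, dW = dgamma, db = dbeta)
}

new_conv <- function(cin, cout, k, stride = 1L, pad = 0L) {
  fan <- k * k * cin
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin, cout = cout,
       W = matrix(rnorm(fan * cout, sd = sqrt(2 / fan)), fan, cout),
       b = numeric(cout))
}

new_bn <- function(c) list(type = "bnorm", gamma = rep(1, c), beta = numeric(c),
                           mean = numeric(c), var = rep(1, c), eps = 1e-5)
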