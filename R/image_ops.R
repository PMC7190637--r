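# Raster helpers. All package rasters are base R arrays indexed [row, col] or
# [row, col, channel] with values in [0, 1]; EBImage uses an (x, y) layout, so
# the wrappers below transpose on the way in and out.

# Bilinear resize of a matrix or [H, W, 3] array to target_h x target_w.
resize_bilinear <- function(x, target_h, target_w) {
  stopifnot(target_h >= 1, target_w >= 1)
  if (is.matrix(x)) {
    img <- EBImage::Image(t(x))
    out <- EBImage::resize(img, w = target_w, h = target_h)
    return(t(EBImage::imageData(out)))
  }
  stopifnot(is_rgb_array(x))
  img <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = target_w, h = target_h)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

# Otsu threshold of a numeric matrix with values in [0, 1].
otsu_threshold <- function(m) {
  stopifnot(is.matrix(m))
  EBImage::otsu(EBImage::Image(t(m)), range = c(0, 1))
}

# Downsample a matrix by block-averaging with integer factor f (used for the
# coarse foreground scan before tiling).
block_downsample <- function(m, f) {
  h <- (nrow(m) %/% f) * f
  w <- (ncol(m) %/% f) * f
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  hi <- (seq_len(h) - 1L) %/% f
  wi <- (seq_len(w) - 1L) %/% f
  acc <- rowsum(m, hi)          # sum rows within blocks
  acc <- t(rowsum(t(acc), wi))  # then columns
  acc / (f * f)
}

# Saturation channel (max - min over RGB), the usual foreground cue for H&E:
# tissue is colorful, glass background is near-gray/white.
saturation <- function(rgb) {
  stopifnot(is_rgb_array(rgb))
  pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3]) - pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
}

# Rotate an [H, W, C] array (or matrix) by k * 90 degrees counter-clockwise.
rot90_array <- function(x, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(x)
  if (!is.matrix(x) && k == 2L) {           # fast path: no transpose needed
    return(x[rev(seq_len(dim(x)[1])), rev(seq_len(dim(x)[2])), , drop = FALSE])
  }
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  apply_one <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (is.matrix(x)) return(apply_one(x))
  out <- lapply(seq_len(dim(x)[3]), function(c) apply_one(x[, , c]))
  array(unlist(out), dim = c(dim(out[[1]]), dim(x)[3]))
}

# Horizontal flip (mirror columns).
flip_h <- function(x) {
  if (is.matrix(x)) return(x[, rev(seq_len(ncol(x))), drop = FALSE])
  x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}

# Modal (most frequent, after 8-bit quantization) color of the 1-px border of
# an RGB raster; used as padding color when a core does not fill its square.
border_mode_color <- function(rgb) {
  stopifnot(is_rgb_array(rgb))
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  idx <- rbind(
    cbind(1L, seq_len(w)), cbind(h, seq_len(w)),
    cbind(seq_len(h), 1L), cbind(seq_len(h), w)
  )
  px <- sapply(1:3, function(c) rgb[cbind(idx, c)])
  key <- apply(round(px * 255), 1, paste, collapse = ",")
  top <- names(sort(table(key), decreasing = TRUE))[1]
  as.numeric(strsplit(top, ",")[[1]]) / 255
}
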