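# Core-image preparation and patch plumbing. Pixel conventions throughout:
# 0-based (row, col) origins, half-open intervals. A prepared core is a
# target_px x target_px raster at mpp_out um/px (defaults 1600 px at 0.5,
# i.e. an ~800 um core square).

#' Prepare a raw core image
#'
#' Rescales to the working resolution by bilinear resampling and center-crops
#' (or, if the rescaled raster is short and `pad = TRUE`, symmetrically pads
#' with the modal border color) to a square.
#'
#' @param raw `[H, W, 3]` RGB array in `[0, 1]`.
#' @param mpp_in Resolution of `raw` in microns per pixel.
#' @param mpp_out Target resolution (default 0.5 um/px).
#' @param target_px Target square side (default 1600 px).
#' @param pad Pad with background color when the rescaled raster is smaller
#'   than the target; if `FALSE`, a short raster is a size error.
#' @param core_index,patient_id,style_id Optional metadata carried on the
#'   result.
#' @return A `core_image` object (`pixels`, `mpp`, `prepared = TRUE`,
#'   `pad_color` when padding occurred).
#' @export
prepare_core <- function(raw, mpp_in, mpp_out = 0.5, target_px = 1600L,
                         pad = TRUE, core_index = NA_integer_,
                         patient_id = NA_integer_, style_id = NA_character_) {
  stopifnot(is_rgb_array(raw), mpp_in > 0, mpp_out > 0)
  f <- mpp_in / mpp_out
  h <- dim(raw)[1]; w <- dim(raw)[2]
  th <- round(h * f); tw <- round(w * f)
  x <- if (th == h && tw == w) raw else resize_bilinear(raw, th, tw)
  pad_color <- NULL
  if (th < target_px || tw < target_px) {
    if (!pad) {
      stop_if_not(FALSE, "raster smaller than target and padding disabled",
                  "tissuefp_size_error")
    }
    pad_color <- border_mode_color(x)
    canvas <- array(rep(pad_color, each = target_px * target_px),
                    c(target_px, target_px, 3))
    r0 <- (max(target_px, th) - th) %/% 2
    c0 <- (max(target_px, tw) - tw) %/% 2
    rr <- seq_len(min(th, target_px))
    cc <- seq_len(min(tw, target_px))
    # crop any long axis before placing
    xr0 <- (th - min(th, target_px)) %/% 2
    xc0 <- (tw - min(tw, target_px)) %/% 2
    canvas[r0 + rr, c0 + cc, ] <- x[xr0 + rr, xc0 + cc, , drop = FALSE]
    x <- canvas
  } else if (th > target_px || tw > target_px) {
    r0 <- (th - target_px) %/% 2
    c0 <- (tw - target_px) %/% 2
    x <- x[r0 + seq_len(target_px), c0 + seq_len(target_px), , drop = FALSE]
  }
  structure(list(pixels = x, core_index = core_index, patient_id = patient_id,
                 style_id = style_id, mpp = mpp_out, prepared = TRUE,
                 pad_color = pad_color),
            class = "core_image")
}

#' @export
print.core_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<core_image> core %s patient %s style %s  %dx%d px @ %.2f um/px\n",
              x$core_index, x$patient_id, x$style_id, d[1], d[2], x$mpp))
  invisible(x)
}

#' Split a prepared core into left and right halves
#'
#' Columns are 0-based and half-open: the left half is columns `[0, W/2)`,
#' the right half `[W/2, W)`, so the two halves partition the raster exactly
#' and share no column.
#'
#' @param core A prepared `core_image` (or a bare `[H, W, 3]` array).
#' @return List with `left` and `right` `[H, W/2, 3]` arrays; each carries
#'   attributes `side` and `col_offset` (0-based first column).
#' @export
split_halves <- function(core) {
  px <- if (inherits(core, "core_image")) {
    stop_if_not(isTRUE(core$prepared), "core has not been prepared",
                "tissuefp_state_error")
    core$pixels
  } else core
  stopifnot(is_rgb_array(px))
  w <- dim(px)[2]
  half <- w %/% 2
  left <- px[, seq_len(half), , drop = FALSE]
  right <- px[, half + seq_len(w - half), , drop = FALSE]
  attr(left, "side") <- "left";  attr(left, "col_offset") <- 0L
  attr(right, "side") <- "right"; attr(right, "col_offset") <- half
  list(left = left, right = right)
}

#' Sample a random patch from a half (or any raster)
#'
#' The 0-based origin (top-left pixel) is uniform over all positions at which
#' a `patch_px` square fits: rows `0..H-patch_px`, cols `0..W-patch_px`.
#' Randomness is taken from the current RNG stream (`set.seed()` upstream for
#' reproducibility).
#'
#' @param half Raster (`[H, W, 3]`), e.g. one element of [split_halves].
#' @param patch_px Patch side (default 224).
#' @param core_index Optional provenance.
#' @return A `patch_sample`: list with `pixels`, `origin` (0-based
#'   `c(row, col)`), `side`, `core_index`.
#' @export
sample_patch <- function(half, patch_px = 224L, core_index = NA_integer_) {
  stopifnot(is_rgb_array(half))
  H <- dim(half)[1]; W <- dim(half)[2]
  if (H < patch_px || W < patch_px) {
    stop_if_not(FALSE, sprintf("half (%dx%d) smaller than patch size %d", H, W, patch_px),
                "tissuefp_size_error")
  }
  r0 <- sample.int(H - patch_px + 1L, 1L) - 1L
  c0 <- sample.int(W - patch_px + 1L, 1L) - 1L
  structure(list(pixels = half[r0 + seq_len(patch_px), c0 + seq_len(patch_px), ,
                               drop = FALSE],
                 origin = c(row = r0, col = c0),
                 side = attr(half, "side") %||% NA_character_,
                 core_index = core_index),
            class = "patch_sample")
}

#' Patch augmentation configuration
#'
#' @param rotate Apply a random right-angle rotation (0/90/180/270).
#' @param flip Apply a random horizontal mirror.
#' @param mult_jitter Multiplicative (contrast) jitter amplitude `b`: factor
#'   drawn from `[1 - b, 1 + b]`.
#' @param add_jitter Additive (brightness) jitter amplitude `c`: offset drawn
#'   from `[-c, c]`.
#' @param grayscale Convert to luminance replicated over the 3 channels
#'   (default `TRUE`: identity training is about architecture, not color).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(rotate = TRUE, flip = TRUE, mult_jitter = 0.1,
                           add_jitter = 0.1, grayscale = TRUE) {
  structure(list(rotate = rotate, flip = flip, mult_jitter = mult_jitter,
                 add_jitter = add_jitter, grayscale = grayscale),
            class = "augment_config")
}

#' Augment a patch
#'
#' Applies, in order: right-angle rotation (+ optional mirror),
#' multiplicative and additive brightness/contrast jitter, optional grayscale
#' conversion (luminance replicated to 3 channels), then clips to `[0, 1]`.
#' Randomness comes from the current RNG stream; `rot_k`/`do_flip` force the
#' geometric part (used to apply identical geometry to a style pair).
#'
#' @param patch A `patch_sample` or `[H, W, 3]` array.
#' @param config An [augment_config].
#' @param rot_k Force rotation to `rot_k * 90` degrees (0..3); `NULL` = random.
#' @param do_flip Force the mirror flag; `NULL` = random.
#' @return An `[H, W, 3]` array.
#' @export
augment_patch <- function(patch, config = augment_config(), rot_k = NULL,
                          do_flip = NULL) {
  x <- if (inherits(patch, "patch_sample")) patch$pixels else patch
  stopifnot(is_rgb_array(x))
  if (config$rotate) {
    if (is.null(rot_k)) rot_k <- sample.int(4L, 1L) - 1L
  } else rot_k <- rot_k %||% 0L
  if (config$flip) {
    if (is.null(do_flip)) do_flip <- runif(1) < 0.5
  } else do_flip <- do_flip %||% FALSE
  if (rot_k != 0L) x <- rot90_array(x, rot_k)
  if (do_flip) x <- flip_h(x)
  if (config$mult_jitter > 0) {
    x <- x * runif(1, 1 - config$mult_jitter, 1 + config$mult_jitter)
  }
  if (config$add_jitter > 0) {
    x <- x + runif(1, -config$add_jitter, config$add_jitter)
  }
  if (config$grayscale) x <- gray_to_rgb(luminance(x))
  clip01(x)
}

#' Restyle an image between registered site styles
#'
#' The built-in implementation inverts the parametric stain composition of
#' `from_style` (undo brightness and gamma, then solve the 3x2 linear stain
#' system per pixel for the nuclear/cytoplasm channels) and re-renders the
#' recovered morphology with `to_style`. Morphology is preserved by
#' construction. Alternatively, `dir` names a directory of externally
#' restyled twins (e.g. produced by a GAN) keyed by core index, returned
#' bit-exactly.
#'
#' @param image `[H, W, 3]` RGB array.
#' @param from_style,to_style Style tokens registered in `styles`.
#' @param styles Named list of [style_params] (default [builtin_styles]).
#' @param dir Optional directory of pre-restyled twins
#'   (`core_<index>_<style>.png`); when given, `core_index` selects the file.
#' @param core_index Core index for file-backed lookup.
#' @param seed Seed for the re-render's hue jitter.
#' @return `[H, W, 3]` RGB array in the target style.
#' @export
restyle <- function(image, from_style, to_style, styles = builtin_styles(),
                    dir = NULL, core_index = NULL, seed = 1L) {
  if (!is.null(dir)) {
    stopifnot(!is.null(core_index))
    path <- file.path(dir, sprintf("core_%04d_%s.png", core_index, to_style))
    stop_if_not(file.exists(path), paste0("no restyled twin at ", path),
                "tissuefp_config_error")
    return(png_to_array(png::readPNG(path)))
  }
  for (s in c(from_style, to_style)) {
    stop_if_not(!is.null(styles[[s]]), paste0("unknown style: ", s),
                "tissuefp_config_error")
  }
  if (identical(from_style, to_style)) return(image)
  morph <- invert_style(image, styles[[from_style]])
  render_style(morph, styles[[to_style]], seed = seed)
}

# Recover (nuclear, cytoplasm) channels from a parametric render: undo
# brightness and gamma, then per-pixel least squares on
#   background - pixel = n * (background - H) + c * (background - E).
invert_style <- function(image, style) {
  stopifnot(is_rgb_array(image))
  x <- clip01(image - style$brightness)^(1 / style$gamma)
  d <- dim(x)
  A <- cbind(style$background - style$hematoxylin,
             style$background - style$eosin)           # 3 x 2
  Ainv <- solve(crossprod(A)) %*% t(A)                 # 2 x 3 pseudo-inverse
  rhs <- matrix(style$background, 3, d[1] * d[2]) -
    t(matrix(x, ncol = 3))                             # 3 x (H*W)
  nc <- Ainv %*% rhs                                   # 2 x (H*W)
  nuc <- clip01(matrix(nc[1, ], d[1], d[2]))
  cyt <- clip01(matrix(nc[2, ], d[1], d[2]))
  cyt <- pmin(cyt, 1 - nuc)
  list(nuclear = nuc, cytoplasm = cyt)
}

# png::readPNG returns [H, W, C] with C in {1, 2, 3, 4}; normalize to RGB.
png_to_array <- function(x) {
  if (is.matrix(x)) return(gray_to_rgb(x))
  if (dim(x)[3] == 2L) return(gray_to_rgb(x[, , 1]))
  if (dim(x)[3] == 4L) return(x[, , 1:3, drop = FALSE])
  x
}
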