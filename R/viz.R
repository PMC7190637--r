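# Heatmaps and embeddings. Three heatmap kinds share one container:
#   identity_prob in [0, 1]  - probability mass on the correct patient
#   similarity    in [0, 1]  - 1 - normalized fingerprint distance / 2
#   marker_score  in [-1, 1] - tanh marker prediction (black -1 .. white +1)
# Grid geometry always follows the tiling formula floor((L - patch)/stride)+1.

new_heatmap <- function(values, kind, patch_px, stride, provenance = list()) {
  structure(list(values = values, kind = kind, patch_px = patch_px,
                 stride = stride, provenance = provenance),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<heat_map> kind=%s  grid %dx%d  patch %d stride %d  range [%.3f, %.3f]\n",
              x$kind, nrow(x$values), ncol(x$values), x$patch_px, x$stride,
              rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.heat_map <- function(x, ...) {
  pal <- switch(x$kind,
                identity_prob = grDevices::colorRampPalette(c("blue", "white", "red"))(64),
                similarity = grDevices::colorRampPalette(c("blue", "white", "red"))(64),
                marker_score = grDevices::gray.colors(64, 0, 1))
  zlim <- if (x$kind == "marker_score") c(-1, 1) else c(0, 1)
  graphics::image(t(x$values)[, rev(seq_len(nrow(x$values)))], col = pal,
                  zlim = zlim, axes = FALSE, main = x$kind, ...)
  invisible(x)
}

#' Evenly distribute cores over patients
#'
#' Builds a core-index -> patient-id layout in which core indices are
#' contiguous per patient and core counts differ by at most one (e.g. 207
#' cores over 104 patients: patients 1..103 contribute 2 cores, patient 104
#' one).
#'
#' @param n_cores,n_patients Totals (`n_cores >= n_patients`).
#' @return Named integer vector (names = core index as character).
#' @export
make_layout <- function(n_cores, n_patients) {
  stopifnot(n_cores >= n_patients, n_patients >= 1)
  sizes <- rep(n_cores %/% n_patients, n_patients)
  extra <- n_cores %% n_patients
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  layout <- rep(seq_len(n_patients), times = sizes)
  names(layout) <- seq_len(n_cores)
  layout
}

#' Aggregate per-core identity probabilities to patients
#'
#' Sums the probabilities of cores belonging to the same patient, so a
#' 207-long core softmax becomes a 104-long patient distribution; total
#' probability mass is conserved.
#'
#' @param probs Numeric vector over cores (or matrix with one column per
#'   observation).
#' @param layout Named vector core index -> patient id (see [make_layout]).
#' @return Vector (or matrix) over patients, names = patient ids.
#' @export
aggregate_to_patients <- function(probs, layout) {
  if (is.matrix(probs)) {
    stopifnot(nrow(probs) == length(layout))
    return(rowsum(probs, group = as.integer(layout)))
  }
  stopifnot(length(probs) == length(layout))
  drop(rowsum(matrix(probs, ncol = 1), group = as.integer(layout)))
}

#' Identity heatmap of a core
#'
#' Tiles the core with overlapping patches (default stride 45 px = 80%
#' linear overlap at 224 px), computes the softmax identity distribution per
#' patch, aggregates core probabilities to patients via `layout`, and stores
#' the probability assigned to the core's own patient.
#'
#' @param model An [fp_model] or `fp_fit` trained on this layout's identity
#'   space.
#' @param core A `core_image`.
#' @param layout Named vector core index -> patient id.
#' @param stride Tiling stride (default `round(0.2 * 224) = 45`).
#' @param grayscale Match the model's training input convention.
#' @return A `heat_map` of kind `identity_prob`.
#' @export
identity_heatmap <- function(model, core, layout, stride = 45L,
                             grayscale = TRUE) {
  if (inherits(model, "fp_fit")) model <- model$model
  if (model$n_identities != length(layout)) {
    stop_if_not(FALSE, "model identity count does not match layout",
                "tissuefp_config_error")
  }
  px <- core$pixels
  org <- tile_origins(dim(px)[1], dim(px)[2], 224L, stride)
  patches <- lapply(seq_len(nrow(org)), function(i) {
    p <- px[org[i, 1] + 1:224, org[i, 2] + 1:224, , drop = FALSE]
    if (grayscale) gray_to_rgb(luminance(p)) else p
  })
  pr <- predict(model, patches, type = "prob")          # n_id x n_patches
  pat <- aggregate_to_patients(pr, layout)              # n_patients x n_patches
  own <- as.character(layout[[as.character(core$core_index)]])
  heat <- pat[match(own, rownames(pat)), ]
  nr <- length(unique(org[, 1])); nc <- length(unique(org[, 2]))
  new_heatmap(matrix(heat, nr, nc), "identity_prob", 224L, as.integer(stride),
              list(core_index = core$core_index, patient_id = core$patient_id))
}

#' Fingerprint-similarity heatmap between two halves
#'
#' The reference half is summarised by the normalized mean of its normalized
#' patch fingerprints; each query patch's similarity is
#' `1 - d/2` where `d` is the Euclidean distance between unit-norm
#' fingerprints (so similarity lies in `[0, 1]`; 1 = identical direction).
#'
#' @param model An [fp_model] or `fp_fit`.
#' @param query_half,reference_half Rasters (e.g. from [split_halves]).
#' @param stride Tiling stride (default 112).
#' @param grayscale Match training convention.
#' @return A `heat_map` of kind `similarity`.
#' @export
similarity_heatmap <- function(model, query_half, reference_half,
                               stride = 112L, grayscale = TRUE) {
  if (inherits(model, "fp_fit")) model <- model$model
  fp_of <- function(half) {
    org <- tile_origins(dim(half)[1], dim(half)[2], 224L, stride)
    patches <- lapply(seq_len(nrow(org)), function(i) {
      p <- half[org[i, 1] + 1:224, org[i, 2] + 1:224, , drop = FALSE]
      if (grayscale) gray_to_rgb(luminance(p)) else p
    })
    list(org = org, fp = extract_fingerprints(model, patches)$fingerprints)
  }
  ref <- fp_of(reference_half)
  ref_fp <- unitize(colMeans(t(apply(ref$fp, 1, unitize))))
  qu <- fp_of(query_half)
  sims <- apply(qu$fp, 1, function(f) 1 - l2norm(unitize(f) - ref_fp) / 2)
  nr <- length(unique(qu$org[, 1])); nc <- length(unique(qu$org[, 2]))
  new_heatmap(matrix(sims, nr, nc), "similarity", 224L, as.integer(stride), list())
}

#' Marker-prediction heatmap of a slide
#'
#' Scores every non-overlapping foreground patch with the marker head and
#' maps scores linearly to grayscale: -1 -> black, +1 -> white. Background
#' grid cells are NA in the value grid, rendered mid-gray and flagged in the
#' `foreground` attribute of the raster.
#'
#' @param head A trained `marker_head`.
#' @param model An [fp_model] or `fp_fit` providing fingerprints.
#' @param slide A slide (see [render_slide] / [tile_slide]).
#' @param grayscale Match training convention.
#' @return A `heat_map` of kind `marker_score`; element `raster` of its
#'   provenance holds the grayscale matrix with attribute `foreground`.
#' @export
marker_heatmap <- function(head, model, slide, grayscale = TRUE) {
  if (inherits(model, "fp_fit")) model <- model$model
  tile_px <- round(112 / slide$mpp)
  nr <- dim(slide$pixels)[1] %/% tile_px
  nc <- dim(slide$pixels)[2] %/% tile_px
  patches <- tile_slide(slide)
  vals <- matrix(NA_real_, nr, nc)
  if (length(patches) > 0) {
    arrays <- lapply(patches, function(p) {
      if (grayscale) gray_to_rgb(luminance(p$pixels)) else p$pixels
    })
    fps <- extract_fingerprints(model, arrays)$fingerprints
    sc <- head_scores(head, fps)
    for (i in seq_along(patches)) {
      r <- patches[[i]]$origin[1] %/% tile_px + 1L
      c <- patches[[i]]$origin[2] %/% tile_px + 1L
      vals[r, c] <- sc[i]
    }
  }
  raster <- (vals + 1) / 2
  fg <- !is.na(vals)
  raster[!fg] <- 0.5
  attr(raster, "foreground") <- fg
  hm <- new_heatmap(vals, "marker_score", 224L, as.integer(tile_px),
                    list(slide_id = slide$slide_id, raster = raster))
  hm
}

#' 2-D embedding of fingerprints with cluster patch retrieval
#'
#' Runs seeded tSNE on a fingerprint matrix, shades each point by its score
#' on a blue (-1) - green (0) - red (+1) ramp, and, for user-supplied
#' center coordinates in the embedding space, returns the `k_patches`
#' nearest points.
#'
#' @param fingerprints `n x D` matrix (n >= 10).
#' @param scores Length-n vector in `[-1, 1]` used for shading (e.g. marker
#'   predictions).
#' @param seed tSNE seed.
#' @param centers Optional `m x 2` matrix of embedding-space coordinates.
#' @param k_patches Patches returned per center (default 5).
#' @param perplexity tSNE perplexity.
#' @param n_iter tSNE iterations.
#' @return An `fp_embedding`: `coords` (n x 2), `scores`, `shade` (hex
#'   colors), and `clusters` (per center: indices + distances) when centers
#'   are given.
#' @export
embed_and_cluster <- function(fingerprints, scores, seed = 1L, centers = NULL,
                              k_patches = 5L, perplexity = 30, n_iter = 500L) {
  fingerprints <- as.matrix(fingerprints)
  stopifnot(nrow(fingerprints) >= 10L,
            length(scores) == nrow(fingerprints))
  Y <- tsne_embed(fingerprints, perplexity = perplexity, n_iter = n_iter,
                  seed = seed)
  ramp <- grDevices::colorRamp(c("blue", "green", "red"))
  shade <- grDevices::rgb(ramp(clip01((scores + 1) / 2)) / 255)
  clusters <- NULL
  if (!is.null(centers)) {
    centers <- matrix(centers, ncol = 2)
    clusters <- lapply(seq_len(nrow(centers)), function(i) {
      d <- sqrt(colSums((t(Y) - centers[i, ])^2))
      ord <- order(d)[seq_len(min(k_patches, nrow(Y)))]
      list(center = centers[i, ], index = ord, distance = d[ord])
    })
  }
  structure(list(coords = Y, scores = scores, shade = shade,
                 clusters = clusters),
            class = "fp_embedding")
}

#' @export
print.fp_embedding <- function(x, ...) {
  cat(sprintf("<fp_embedding> %d points%s\n", nrow(x$coords),
              if (!is.null(x$clusters))
                sprintf(", %d cluster centers", length(x$clusters)) else ""))
  invisible(x)
}

#' @export
plot.fp_embedding <- function(x, ...) {
  graphics::plot(x$coords, col = x$shade, pch = 16, cex = 0.6,
                 xlab = "tSNE 1", ylab = "tSNE 2", ...)
  if (!is.null(x$clusters)) {
    for (cl in x$clusters) graphics::points(cl$center[1], cl$center[2], pch = 4, cex = 1.5)
  }
  invisible(x)
}

#' Write a heatmap as PNG plus TSV of grid values
#'
#' @param hm A `heat_map`.
#' @param path Output path without extension; writes `<path>.png` and
#'   `<path>.tsv`.
#' @return Invisibly, the PNG path.
#' @export
write_heatmap <- function(hm, path) {
  vals <- hm$values
  if (hm$kind == "marker_score") {
    img <- (vals + 1) / 2
    img[is.na(img)] <- 0.5
  } else {
    ramp <- grDevices::colorRamp(c("blue", "white", "red"))
    v <- vals; v[is.na(v)] <- 0.5
    img <- array(ramp(clip01(as.vector(v))) / 255, c(dim(vals), 3))
  }
  png::writePNG(img, paste0(path, ".png"))
  utils::write.table(vals, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(path, ".png"))
}
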