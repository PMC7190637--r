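# The matching game: fingerprints for left halves (one staining style) are
# matched to right halves (another style) by nearest neighbour in fingerprint
# space. Scored per core and, by pooling each patient's halves, per patient.

tile_origins <- function(H, W, patch_px = 224L, stride = 112L) {
  if (H < patch_px || W < patch_px) {
    stop_if_not(FALSE, "raster smaller than one patch", "tissuefp_size_error")
  }
  r <- seq(0L, by = stride, length.out = (H - patch_px) %/% stride + 1L)
  c <- seq(0L, by = stride, length.out = (W - patch_px) %/% stride + 1L)
  cbind(row = rep(r, times = length(c)), col = rep(c, each = length(r)))
}

l2norm <- function(v) sqrt(sum(v^2))

unitize <- function(v) v / (l2norm(v) + 1e-12)

#' Aggregate fingerprint of one half of a core
#'
#' Tiles the half with `patch_px` patches at `stride` (default 50% overlap),
#' L2-normalizes each patch fingerprint, averages them and re-normalizes, so
#' the aggregate has unit norm by construction.
#'
#' @param model An [fp_model] or `fp_fit`.
#' @param core A `core_image` (see [core_image] / [prepare_core]).
#' @param side `"left"` or `"right"`.
#' @param stride Tiling stride in px.
#' @param patch_px Patch side in px.
#' @param grayscale Convert patches to grayscale before the forward pass
#'   (must match training).
#' @return A `half_fingerprint`: `core_index`, `patient_id`, `side`,
#'   `style_id`, `fp` (unit-norm vector).
#' @export
half_fingerprint <- function(model, core, side = c("left", "right"),
                             stride = 112L, patch_px = 224L, grayscale = TRUE) {
  side <- match.arg(side)
  if (inherits(model, "fp_fit")) model <- model$model
  half <- split_halves(core)[[side]]
  org <- tile_origins(dim(half)[1], dim(half)[2], patch_px, stride)
  patches <- lapply(seq_len(nrow(org)), function(i) {
    p <- half[org[i, 1] + seq_len(patch_px), org[i, 2] + seq_len(patch_px), ,
              drop = FALSE]
    if (grayscale) p <- gray_to_rgb(luminance(p))
    p
  })
  fps <- extract_fingerprints(model, patches)$fingerprints
  agg <- unitize(colMeans(t(apply(fps, 1, unitize))))
  structure(list(core_index = core$core_index, patient_id = core$patient_id,
                 side = side, style_id = core$style_id, fp = agg),
            class = "half_fingerprint")
}

fp_matrix <- function(halves) {
  stopifnot(length(halves) >= 1)
  t(vapply(halves, function(h) h$fp, numeric(length(halves[[1]]$fp))))
}

#' Match left fingerprints to nearest right fingerprints
#'
#' Each left item is independently assigned its Euclidean nearest neighbour
#' among the right items (no bijection constraint). Ties break toward the
#' lowest right core index.
#'
#' @param left,right Lists of `half_fingerprint` objects with equal
#'   fingerprint dimension.
#' @return Data frame with `left_core` and `matched_core`.
#' @export
match_nearest <- function(left, right) {
  stopifnot(length(left) >= 1, length(right) >= 1)
  L <- fp_matrix(left); R <- fp_matrix(right)
  if (ncol(L) != ncol(R)) invalid_arg("fingerprint dimensions differ")
  ridx <- vapply(right, function(h) h$core_index, numeric(1))
  ord <- order(ridx)           # ties -> lowest core index
  R <- R[ord, , drop = FALSE]; ridx <- ridx[ord]
  # squared distances via the Gram trick
  d2 <- outer(rowSums(L^2), rowSums(R^2), "+") - 2 * L %*% t(R)
  best <- max.col(-d2, ties.method = "first")
  data.frame(left_core = vapply(left, function(h) h$core_index, numeric(1)),
             matched_core = ridx[best])
}

#' Score a matching-game assignment
#'
#' Core accuracy is the fraction of left cores matched to their own index.
#' When the half fingerprints are supplied, a patient-pooled accuracy is also
#' computed: all of a patient's left-half fingerprints are averaged
#' (normalize, mean, re-normalize) into one patient fingerprint, likewise on
#' the right, and patients are matched by nearest neighbour.
#'
#' @param assignment Data frame from [match_nearest].
#' @param layout Named vector mapping core index -> patient id (e.g.
#'   `cohort$layout`).
#' @param left,right Optional lists of `half_fingerprint`s for patient
#'   pooling.
#' @return A `match_result`: `assignment`, `core_accuracy`,
#'   `patient_accuracy` (or `NA`), `n_cores`, `n_patients`.
#' @export
score_matching <- function(assignment, layout, left = NULL, right = NULL) {
  lc <- as.character(assignment$left_core)
  mc <- as.character(assignment$matched_core)
  if (!all(c(lc, mc) %in% names(layout))) {
    stop_if_not(FALSE, "assignment contains core indices missing from layout",
                "tissuefp_data_error")
  }
  core_acc <- mean(assignment$left_core == assignment$matched_core)
  pat_acc <- NA_real_
  n_pat <- length(unique(layout))
  if (!is.null(left) && !is.null(right)) {
    pool <- function(halves) {
      pid <- vapply(halves, function(h) layout[[as.character(h$core_index)]],
                    numeric(1))
      by_pat <- split(halves, pid)
      fps <- lapply(by_pat, function(hs) {
        unitize(colMeans(t(vapply(hs, function(h) unitize(h$fp),
                                  numeric(length(hs[[1]]$fp))))))
      })
      list(pid = as.numeric(names(by_pat)), fp = do.call(rbind, fps))
    }
    pl <- pool(left); pr <- pool(right)
    d2 <- outer(rowSums(pl$fp^2), rowSums(pr$fp^2), "+") - 2 * pl$fp %*% t(pr$fp)
    best <- max.col(-d2, ties.method = "first")
    pat_acc <- mean(pl$pid == pr$pid[best])
    n_pat <- length(pl$pid)
  }
  structure(list(assignment = assignment, core_accuracy = core_acc,
                 patient_accuracy = pat_acc,
                 n_cores = nrow(assignment), n_patients = n_pat),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d cores: core accuracy %.1f%% (chance %.2f%%)%s\n",
              x$n_cores, 100 * x$core_accuracy, 100 * chance_accuracy(x$n_cores),
              if (!is.na(x$patient_accuracy))
                sprintf("; %d patients: pooled accuracy %.1f%%",
                        x$n_patients, 100 * x$patient_accuracy) else ""))
  invisible(x)
}

#' Chance accuracy of the matching game
#'
#' With `n` cores, matching a left core to a uniformly random right core is
#' correct with probability `1/n` (0.48%, printed as 0.4% at one decimal, for
#' a 208-core array).
#'
#' @param n_cores Number of cores (>= 1).
#' @return `1 / n_cores`.
#' @export
chance_accuracy <- function(n_cores) {
  if (n_cores < 1) invalid_arg("n_cores must be >= 1")
  1 / n_cores
}

#' Run the full cross-style matching game on a synthetic cohort
#'
#' Computes left-half fingerprints in one site style and right-half
#' fingerprints in another (mirroring serial sections stained at two sites),
#' matches and scores them.
#'
#' @param model An [fp_model] or `fp_fit`.
#' @param cohort An [make_cohort] result.
#' @param left_style,right_style Style tokens.
#' @param grayscale Passed to [half_fingerprint].
#' @return A `match_result` (patient pooling included).
#' @export
matching_game <- function(model, cohort, left_style = "siteA",
                          right_style = "siteB", grayscale = TRUE) {
  if (inherits(model, "fp_fit")) model <- model$model
  lh <- lapply(seq_along(cohort$cores), function(ci)
    half_fingerprint(model, core_image(cohort, ci, left_style), "left",
                     grayscale = grayscale))
  rh <- lapply(seq_along(cohort$cores), function(ci)
    half_fingerprint(model, core_image(cohort, ci, right_style), "right",
                     grayscale = grayscale))
  score_matching(match_nearest(lh, rh), cohort$layout, lh, rh)
}

#' Cross-style matching and inter-style distance in one pass
#'
#' Renders each core once per style and computes the three half fingerprints
#' the style-invariance evaluation needs: left halves in `styles[1]` and
#' right halves in `styles[2]` for the matching game, plus right halves in
#' `styles[1]` for the held-out inter-style distance. Equivalent to
#' [matching_game] + [inter_style_distance] at roughly half the cost.
#'
#' @inheritParams matching_game
#' @param styles Two style tokens: left halves use the first, matching right
#'   halves the second.
#' @param stride Half-tiling stride passed to [half_fingerprint].
#' @return List with `match` (a `match_result`), `inter_style_distance`
#'   (mean squared normalized distance between the two styles' right-half
#'   PATCH fingerprints at matched positions -- the quantity the paired loss
#'   penalises, measured on halves the training never saw),
#'   `between_core_distance` (the same distance between patches of
#'   *different* cores within one style -- the feature spread), and
#'   `style_sensitivity` (their ratio). The ratio is the scale-free
#'   invariance measure: absolute inter-style distance also shrinks when a
#'   model is simply undiscriminating, whereas the ratio only shrinks when
#'   style twins are closer than unrelated tissue.
#' @export
style_matching_eval <- function(model, cohort, styles = c("siteA", "siteB"),
                                grayscale = TRUE, stride = 112L) {
  if (inherits(model, "fp_fit")) model <- model$model
  n <- length(cohort$cores)
  lh <- vector("list", n); rh <- vector("list", n)
  d <- numeric(n)
  tile_patches <- function(half) {
    org <- tile_origins(dim(half)[1], dim(half)[2], 224L, stride)
    lapply(seq_len(nrow(org)), function(i) {
      p <- half[org[i, 1] + 1:224, org[i, 2] + 1:224, , drop = FALSE]
      if (grayscale) gray_to_rgb(luminance(p)) else p
    })
  }
  uA <- matrix(0, n, model$fingerprint_dim)   # one unit patch fp per core/style
  uB <- matrix(0, n, model$fingerprint_dim)
  for (ci in seq_len(n)) {
    imgA <- core_image(cohort, ci, styles[1])
    imgB <- core_image(cohort, ci, styles[2])
    lh[[ci]] <- half_fingerprint(model, imgA, "left", stride = stride,
                                 grayscale = grayscale)
    rA <- extract_fingerprints(model,
                               tile_patches(split_halves(imgA)$right))$fingerprints
    rB <- extract_fingerprints(model,
                               tile_patches(split_halves(imgB)$right))$fingerprints
    # patch-level distance at matched positions: the quantity the paired
    # loss acts on, evaluated on held-out halves
    d[ci] <- mean(vapply(seq_len(nrow(rA)), function(i)
      fingerprint_distance(rA[i, ], rB[i, ]), numeric(1)))
    uA[ci, ] <- unitize(rA[1, ])
    uB[ci, ] <- unitize(rB[1, ])
    agg <- unitize(colMeans(t(apply(rB, 1, unitize))))
    rh[[ci]] <- structure(list(core_index = imgB$core_index,
                               patient_id = imgB$patient_id, side = "right",
                               style_id = imgB$style_id, fp = agg),
                          class = "half_fingerprint")
  }
  # feature spread: mean squared distance between unit patch fingerprints of
  # different cores within one style (averaged over the two styles)
  spread <- function(U) {
    G <- tcrossprod(U)
    mean((2 - 2 * G)[upper.tri(G)])
  }
  between <- (spread(uA) + spread(uB)) / 2
  list(match = score_matching(match_nearest(lh, rh), cohort$layout, lh, rh),
       inter_style_distance = mean(d),
       between_core_distance = between,
       style_sensitivity = mean(d) / (between + 1e-12))
}

#' Mean inter-style patch fingerprint distance on held-out halves
#'
#' For every core, patch fingerprints are computed at matched tiling
#' positions of one half rendered in two styles, and the normalized squared
#' distance between style twins is averaged over positions and cores. This
#' is the same quantity the style-paired loss penalises during training,
#' here measured on the held-out halves; style-paired training should shrink
#' it relative to plain training at matched budget.
#'
#' @inheritParams matching_game
#' @param styles Two style tokens.
#' @param side Which half to use (default the held-out `"right"`).
#' @param stride Tiling stride in px.
#' @return Mean squared normalized patch fingerprint distance.
#' @export
inter_style_distance <- function(model, cohort, styles = c("siteA", "siteB"),
                                 side = "right", grayscale = TRUE,
                                 stride = 112L) {
  if (inherits(model, "fp_fit")) model <- model$model
  prep <- function(half) {
    org <- tile_origins(dim(half)[1], dim(half)[2], 224L, stride)
    lapply(seq_len(nrow(org)), function(i) {
      p <- half[org[i, 1] + 1:224, org[i, 2] + 1:224, , drop = FALSE]
      if (grayscale) gray_to_rgb(luminance(p)) else p
    })
  }
  d <- vapply(seq_along(cohort$cores), function(ci) {
    h1 <- split_halves(core_image(cohort, ci, styles[1]))[[side]]
    h2 <- split_halves(core_image(cohort, ci, styles[2]))[[side]]
    f1 <- extract_fingerprints(model, prep(h1))$fingerprints
    f2 <- extract_fingerprints(model, prep(h2))$fingerprints
    mean(vapply(seq_len(nrow(f1)), function(i)
      fingerprint_distance(f1[i, ], f2[i, ]), numeric(1)))
  }, numeric(1))
  mean(d)
}
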