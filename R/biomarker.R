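# Patient-level marker prediction from fingerprints. Slides are tiled into
# non-overlapping 112 um foreground squares resampled to 224 px; K patches
# per patient form a bag; a small head (D x 8 linear, ReLU, 8 x 1 linear,
# tanh) maps each patch fingerprint to a score in (-1, 1); the bag score is
# the mean patch score (multiple-instance rule) and is regressed onto the
# +-1 patient label with squared error. Early stopping monitors patient-level
# AUC on a held-out "overfitting" group; evaluation is 5-fold CV.

#' Tile a slide into foreground patches
#'
#' The slide is divided into a non-overlapping grid of squares of
#' `patch_um` microns (at the slide's resolution), foreground is detected by
#' Otsu thresholding the saturation channel at 8x downsample, squares with at
#' least `min_fg` foreground are kept and resampled to `patch_px` pixels.
#'
#' @param slide List with `pixels` (`[S, S, 3]`), `mpp`, optionally `mask`
#'   (integer tissue-type map) and `patient_id` (see [render_slide]).
#' @param patch_um Patch side in microns (default 112).
#' @param patch_px Output patch side in pixels (default 224).
#' @param min_fg Minimum foreground fraction to keep a square.
#' @return List of patches: each has `pixels`, `origin` (0-based row/col in
#'   slide pixels), `tissue_class` (majority mask label or `NA`). Empty list
#'   (with a warning) if nothing passes the foreground rule.
#' @export
tile_slide <- function(slide, patch_um = 112, patch_px = 224L, min_fg = 0.5) {
  stop_if_not(!is.null(slide$mpp), "slide has no microns-per-pixel metadata",
              "tissuefp_data_error")
  px <- slide$pixels
  tile_px <- round(patch_um / slide$mpp)
  S1 <- dim(px)[1]; S2 <- dim(px)[2]
  sat <- saturation(px)
  sat8 <- block_downsample(sat, 8L)
  if (max(sat8) < 0.05) {          # nothing but glass
    warning("no foreground patches found in slide")
    return(list())
  }
  # Otsu, capped: on slides with little glass Otsu can split light tissue
  # from dark tissue instead of tissue from glass; any saturation clearly
  # above glass (~0.02) is foreground
  thr <- min(otsu_threshold(sat8), 0.05)
  fg8 <- sat8 > thr
  nr <- S1 %/% tile_px; nc <- S2 %/% tile_px
  out <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * tile_px; c0 <- (j - 1L) * tile_px
      fr <- (r0 %/% 8L) + seq_len(max(1L, tile_px %/% 8L))
      fc <- (c0 %/% 8L) + seq_len(max(1L, tile_px %/% 8L))
      fr <- fr[fr <= nrow(fg8)]; fc <- fc[fc <= ncol(fg8)]
      if (mean(fg8[fr, fc]) < min_fg) next
      tile <- px[r0 + seq_len(tile_px), c0 + seq_len(tile_px), , drop = FALSE]
      if (tile_px != patch_px) tile <- resize_bilinear(tile, patch_px, patch_px)
      tcl <- NA_integer_
      if (!is.null(slide$mask)) {
        sub <- slide$mask[r0 + seq_len(tile_px), c0 + seq_len(tile_px)]
        tcl <- which.max(tabulate(sub + 1L, 4L)) - 1L
      }
      out[[length(out) + 1L]] <- list(pixels = tile,
                                      origin = c(row = r0, col = c0),
                                      tissue_class = tcl)
    }
  }
  if (length(out) == 0L) warning("no foreground patches found in slide")
  out
}

#' Build one patient's fingerprint bag
#'
#' Samples `k` patches uniformly without replacement (with replacement, with
#' a warning, when fewer are available) and extracts their fingerprints.
#'
#' @param patches Patch list from [tile_slide].
#' @param model An [fp_model] or `fp_fit`.
#' @param k Bag size (default 120).
#' @param seed Sampling seed.
#' @param patient_id Carried on the bag.
#' @param grayscale Convert patches to grayscale before the forward pass
#'   (must match fingerprint training).
#' @return A `patch_bag`: `patient_id`, `fingerprints` (`k x D`),
#'   `tissue_class` (length-k vector), `sources`.
#' @export
make_bag <- function(patches, model, k = 120L, seed = 1L,
                     patient_id = NA_integer_, grayscale = TRUE) {
  stop_if_not(length(patches) >= 1L,
              sprintf("no foreground patches for patient %s", patient_id),
              "tissuefp_data_error")
  idx <- with_seed(derive_seed(seed, 43L), {
    if (length(patches) >= k) sample.int(length(patches), k)
    else sample.int(length(patches), k, replace = TRUE)
  })
  if (length(patches) < k) {
    warning(sprintf("patient %s: only %d patches for bag size %d; sampling with replacement",
                    patient_id, length(patches), k))
  }
  uniq <- sort(unique(idx))
  arrays <- lapply(patches[uniq], function(p) {
    if (grayscale) gray_to_rgb(luminance(p$pixels)) else p$pixels
  })
  fps_u <- extract_fingerprints(model, arrays)$fingerprints
  fps <- fps_u[match(idx, uniq), , drop = FALSE]   # duplicates share one forward pass
  structure(list(patient_id = patient_id, fingerprints = fps,
                 tissue_class = vapply(patches[idx],
                                       function(p) p$tissue_class, integer(1)),
                 sources = t(vapply(patches[idx], function(p) p$origin,
                                    numeric(2)))),
            class = "patch_bag")
}

#' Bags for a whole-slide cohort
#'
#' Renders each slide, tiles it, and builds one fingerprint bag per patient.
#'
#' @param cohort An [make_wsi_cohort] result.
#' @param model An [fp_model] or `fp_fit`.
#' @param k Bag size.
#' @param seed Sampling seed.
#' @param style Rendering style token.
#' @param grayscale Passed to [make_bag].
#' @return Named list of `patch_bag`s (names = patient ids).
#' @export
wsi_bags <- function(cohort, model, k = 120L, seed = 1L, style = "siteA",
                     grayscale = TRUE) {
  if (inherits(model, "fp_fit")) model <- model$model
  bags <- lapply(cohort$labels$patient_id, function(pid) {
    s <- render_slide(cohort, pid, style)
    p <- tile_slide(s)
    make_bag(p, model, k = k, seed = derive_seed(seed, 47L, pid),
             patient_id = pid, grayscale = grayscale)
  })
  names(bags) <- cohort$labels$patient_id
  bags
}

# --- marker head -----------------------------------------------------------

new_marker_head <- function(D, seed = 1L) {
  with_seed(derive_seed(seed, 53L), structure(
    list(W1 = matrix(rnorm(D * 8, sd = sqrt(2 / D)), D, 8), b1 = numeric(8),
         w2 = matrix(rnorm(8, sd = sqrt(1 / 8)), 8, 1), b2 = 0,
         mu = numeric(D), sd = rep(1, D)),
    class = "marker_head"))
}

# feature scaling fitted on the training bags and stored with the head
head_scale <- function(head, F) {
  sweep(sweep(F, 2, head$mu), 2, head$sd, "/")
}

head_scores <- function(head, F) {      # F: n x D -> n patch scores in (-1,1)
  if (inherits(head, "marker_head_ens")) {
    S <- sapply(head$members, function(h) head_scores(h, F))
    return(rowMeans(matrix(S, nrow = nrow(F))))
  }
  h <- head_scale(head, F) %*% head$W1
  h <- sweep(h, 2, head$b1, "+")
  h[h < 0] <- 0
  drop(tanh(h %*% head$w2 + head$b2))
}

#' @export
print.marker_head_ens <- function(x, ...) {
  cat(sprintf("<marker_head_ens> %d members; ensemble monitored AUC %.3f\n",
              length(x$members), attr(x, "best_auc") %||% NA_real_))
  invisible(x)
}

#' @export
predict.marker_head_ens <- function(object, bag, tissue_class = NULL, ...) {
  predict_patient(object, bag, tissue_class)
}

#' Patient-level score from a bag
#'
#' The mean of the per-patch tanh outputs, optionally restricted to patches
#' of one tissue class (`NA` if the bag has no such patch).
#'
#' @param head A trained `marker_head`.
#' @param bag A `patch_bag`.
#' @param tissue_class Optional tissue label (e.g. 1 = epithelium) to
#'   restrict the average to.
#' @return Score in `[-1, 1]`, or `NA` if no patch matches the filter.
#' @export
predict_patient <- function(head, bag, tissue_class = NULL) {
  stop_if_not(nrow(bag$fingerprints) >= 1L, "empty bag", "tissuefp_data_error")
  s <- head_scores(head, bag$fingerprints)
  if (!is.null(tissue_class)) {
    keep <- !is.na(bag$tissue_class) & bag$tissue_class == tissue_class
    if (!any(keep)) return(NA_real_)
    s <- s[keep]
  }
  mean(s)
}

#' @export
predict.marker_head <- function(object, bag, tissue_class = NULL, ...) {
  predict_patient(object, bag, tissue_class)
}

#' Marker-head training configuration
#'
#' @param steps Maximum optimisation steps.
#' @param batch_bags Bags per MIL batch.
#' @param lr Adam learning rate.
#' @param eval_interval Steps between overfitting-group AUC evaluations.
#' @param patience Evaluations without AUC improvement before stopping.
#' @param min_delta Minimum AUC improvement that counts.
#' @param restarts Independent initialisations; the head with the best
#'   overfitting-group AUC is kept (restart selection uses only the group
#'   already reserved for early stopping).
#' @param seed Batch-sampling and init seed.
#' @return List of class `head_config`.
#' @export
head_config <- function(steps = 2000L, batch_bags = 8L, lr = 3e-3,
                        eval_interval = 50L, patience = 40L, min_delta = 1e-4,
                        restarts = 3L, seed = 1L) {
  structure(list(steps = as.integer(steps), batch_bags = as.integer(batch_bags),
                 lr = lr, eval_interval = as.integer(eval_interval),
                 patience = as.integer(patience), min_delta = min_delta,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "head_config")
}

#' Train a marker head on fingerprint bags
#'
#' Multiple-instance rule: a batch is `batch_bags` bags; each bag's score is
#' the mean of its per-patch tanh outputs and the loss is the mean squared
#' error between bag scores and the +-1 labels. Every `eval_interval` steps
#' the patient-level AUC on the overfitting group is computed from averaged
#' patch predictions; the best-AUC weights are kept and training stops after
#' `patience` evaluations without improvement.
#'
#' @param train_bags,train_labels Bags and +-1 labels for the training group.
#' @param overfit_bags,overfit_labels Held-out group used only for early
#'   stopping (must contain both classes).
#' @param config A [head_config].
#' @return A `marker_head` with attributes `log` (data frame of step, mse,
#'   overfit_auc) and `best_auc`.
#' @export
train_marker_head <- function(train_bags, train_labels, overfit_bags,
                              overfit_labels, config = head_config()) {
  stopifnot(length(train_bags) == length(train_labels))
  stop_if_not(length(unique(sign(overfit_labels))) == 2L,
              "overfitting group contains a single class; AUC undefined",
              "tissuefp_fold_error")
  if ((config$restarts %||% 1L) > 1L) {
    members <- lapply(seq_len(config$restarts), function(r) {
      cfg <- config
      cfg$restarts <- 1L
      cfg$seed <- derive_seed(config$seed, 71L, r)
      train_marker_head(train_bags, train_labels, overfit_bags,
                        overfit_labels, cfg)
    })
    ens <- structure(list(members = members), class = "marker_head_ens")
    sc <- vapply(overfit_bags, function(b) predict_patient(ens, b), numeric(1))
    attr(ens, "best_auc") <- auc_rank(sc, overfit_labels)
    attr(ens, "member_auc") <- vapply(members, function(h) attr(h, "best_auc"),
                                      numeric(1))
    return(ens)
  }
  D <- ncol(train_bags[[1]]$fingerprints)
  head <- new_marker_head(D, config$seed)
  allF <- do.call(rbind, lapply(train_bags, `[[`, "fingerprints"))
  head$mu <- colMeans(allF)
  head$sd <- pmax(apply(allF, 2, stats::sd), 1e-8)
  rm(allF)
  mm <- lapply(head[c("W1", "b1", "w2", "b2")], function(p) p * 0)
  vv <- mm
  t_adam <- 0L
  best_auc <- -Inf; best_head <- head; since <- 0L
  log_rows <- list()
  eval_auc <- function(h) {
    sc <- vapply(overfit_bags, function(b) predict_patient(h, b), numeric(1))
    auc_rank(sc, overfit_labels)
  }
  for (step in seq_len(config$steps)) {
    ids <- with_seed(derive_seed(config$seed, 59L, step),
                     sample.int(length(train_bags),
                                min(config$batch_bags, length(train_bags))))
    gW1 <- head$W1 * 0; gb1 <- head$b1 * 0; gw2 <- head$w2 * 0; gb2 <- 0
    mse <- 0
    for (bi in ids) {
      F <- head_scale(head, train_bags[[bi]]$fingerprints)
      y <- train_labels[bi]
      h <- sweep(F %*% head$W1, 2, head$b1, "+")
      mask <- h > 0
      hr <- h * mask
      z <- drop(hr %*% head$w2 + head$b2)
      s <- tanh(z)
      sbar <- mean(s)
      mse <- mse + (sbar - y)^2
      dsbar <- 2 * (sbar - y) / length(ids)
      ds <- rep(dsbar / length(s), length(s))
      dz <- ds * (1 - s^2)
      gw2 <- gw2 + t(hr) %*% dz
      gb2 <- gb2 + sum(dz)
      dh <- (dz %*% t(head$w2)) * mask
      gW1 <- gW1 + t(F) %*% dh
      gb1 <- gb1 + colSums(dh)
    }
    mse <- mse / length(ids)
    t_adam <- t_adam + 1L
    upd <- function(p, g, m, v) {
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g * g
      p <- p - config$lr * (m / (1 - 0.9^t_adam)) /
        (sqrt(v / (1 - 0.999^t_adam)) + 1e-8)
      list(p = p, m = m, v = v)
    }
    for (nm in c("W1", "b1", "w2", "b2")) {
      g <- switch(nm, W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2)
      u <- upd(head[[nm]], g, mm[[nm]], vv[[nm]])
      head[[nm]] <- u$p; mm[[nm]] <- u$m; vv[[nm]] <- u$v
    }
    auc <- NA_real_
    if (step %% config$eval_interval == 0L || step == config$steps) {
      auc <- eval_auc(head)
      if (auc > best_auc + config$min_delta) {
        best_auc <- auc; best_head <- head; since <- 0L
      } else since <- since + 1L
      if (best_auc == -Inf) { best_auc <- auc; best_head <- head }
    }
    log_rows[[step]] <- data.frame(step = step, mse = mse, overfit_auc = auc)
    if (!is.na(auc) && since >= config$patience) break
  }
  attr(best_head, "log") <- do.call(rbind, log_rows)
  attr(best_head, "best_auc") <- best_auc
  best_head
}

#' @export
print.marker_head <- function(x, ...) {
  cat(sprintf("<marker_head> %d-d input; best monitored AUC %.3f\n",
              nrow(x$W1), attr(x, "best_auc") %||% NA_real_))
  invisible(x)
}

# --- evaluation ------------------------------------------------------------

# Mann-Whitney rank AUC with tie correction (averaged ranks).
auc_rank <- function(score, label) {
  keep <- !is.na(score)
  score <- score[keep]; label <- label[keep]
  pos <- label > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  stop_if_not(n1 >= 1 && n0 >= 1, "AUC needs both classes",
              "tissuefp_stats_error")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' ROC curve and AUC for patient scores
#'
#' @param scores Numeric vector of patient scores (`NA`s dropped with their
#'   labels).
#' @param labels Vector of +-1 (or 0/1) patient labels aligned with `scores`.
#' @return List of class `roc_eval`: `auc`, `roc` (data frame of fpr, tpr,
#'   threshold), `n_pos`, `n_neg`, `n_excluded` (NA scores dropped).
#' @export
evaluate_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores)
  n_excl <- sum(!keep)
  s <- scores[keep]; y <- labels[keep] > 0
  auc <- auc_rank(s, ifelse(y, 1, -1))
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(y[ord]); fp <- cumsum(!y[ord])
  roc <- data.frame(threshold = c(Inf, s[ord]),
                    tpr = c(0, tp / sum(y)),
                    fpr = c(0, fp / sum(!y)))
  structure(list(auc = auc, roc = roc, n_pos = sum(y), n_neg = sum(!y),
                 n_excluded = n_excl),
            class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("<roc_eval> AUC %.3f  (%d positive, %d negative%s)\n",
              x$auc, x$n_pos, x$n_neg,
              if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Stratified cross-validation groups
#'
#' @param labels +-1 labels (missing allowed as `NA`; NA patients are
#'   assigned groups but should be excluded per marker upstream).
#' @param n_folds Number of groups.
#' @param seed Assignment seed.
#' @return Integer group per patient (1..n_folds).
#' @export
cv_groups <- function(labels, n_folds = 5L, seed = 1L) {
  g <- integer(length(labels))
  with_seed(derive_seed(seed, 61L), {
    for (cl in unique(labels)) {
      idx <- which(if (is.na(cl)) is.na(labels) else !is.na(labels) & labels == cl)
      idx <- idx[sample.int(length(idx))]
      g[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  g
}

#' Five-fold cross-validated marker prediction
#'
#' Patients are split into `n_folds` label-stratified groups. In fold `i` the
#' test group is `i`, the overfitting group is the next group, and the
#' remaining groups train the head. Reports per-fold test AUC, their mean,
#' and out-of-fold patient scores. Folds whose test or overfitting group is
#' single-class are skipped with a warning.
#'
#' @param bags Named list of `patch_bag`s.
#' @param labels +-1 labels aligned with `bags` (NA = missing; those patients
#'   are excluded).
#' @param n_folds Number of folds (default 5).
#' @param seed Grouping seed.
#' @param config A [head_config].
#' @return A `marker_cv`: `fold_auc`, `mean_auc`, `scores` (out-of-fold),
#'   `groups`, `heads`, `labels`.
#' @export
run_cross_validation <- function(bags, labels, n_folds = 5L, seed = 1L,
                                 config = head_config()) {
  stopifnot(length(bags) == length(labels))
  keep <- !is.na(labels)
  bags <- bags[keep]; labels <- labels[keep]
  stop_if_not(length(bags) >= 10L, "need at least 10 labeled patients",
              "tissuefp_data_error")
  groups <- cv_groups(labels, n_folds, seed)
  fold_auc <- rep(NA_real_, n_folds)
  scores <- rep(NA_real_, length(bags))
  heads <- vector("list", n_folds)
  for (i in seq_len(n_folds)) {
    test <- groups == i
    over <- groups == (i %% n_folds) + 1L
    train <- !test & !over
    if (length(unique(labels[test])) < 2L || length(unique(labels[over])) < 2L) {
      warning(sprintf("fold %d skipped: single-class group", i))
      next
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 67L, i)
    h <- train_marker_head(bags[train], labels[train], bags[over],
                           labels[over], cfg)
    sc <- vapply(bags[test], function(b) predict_patient(h, b), numeric(1))
    fold_auc[i] <- auc_rank(sc, labels[test])
    scores[test] <- sc
    heads[[i]] <- h
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc, na.rm = TRUE),
                 scores = scores, groups = groups, heads = heads,
                 labels = labels, patient_id = names(bags)),
            class = "marker_cv")
}

#' @export
print.marker_cv <- function(x, ...) {
  cat(sprintf("<marker_cv> %d folds; per-fold AUC: %s; mean %.3f\n",
              length(x$fold_auc),
              paste(sprintf("%.3f", x$fold_auc), collapse = " "), x$mean_auc))
  invisible(x)
}

#' @export
plot.marker_cv <- function(x, ...) {
  ev <- evaluate_scores(x$scores, x$labels)
  graphics::plot(ev$roc$fpr, ev$roc$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("pooled out-of-fold ROC (AUC %.3f)", ev$auc))
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Tissue-type-restricted out-of-fold AUC
#'
#' Rescored from the cross-validation fit: each test patient's score is the
#' mean patch prediction restricted to the given tissue class (patients with
#' no such patch are excluded and counted).
#'
#' @param cv A `marker_cv` from [run_cross_validation].
#' @param bags The same bag list the CV was run on (named by patient id).
#' @param tissue_class Tissue label to restrict to, or `NULL` for all
#'   patches.
#' @return A `roc_eval` (see [evaluate_scores]).
#' @export
region_restricted_auc <- function(cv, bags, tissue_class = NULL) {
  bags <- bags[cv$patient_id]
  n_folds <- length(cv$fold_auc)
  scores <- rep(NA_real_, length(bags))
  for (i in seq_len(n_folds)) {
    if (is.null(cv$heads[[i]])) next
    test <- cv$groups == i
    scores[test] <- vapply(bags[test],
                           function(b) predict_patient(cv$heads[[i]], b, tissue_class),
                           numeric(1))
  }
  evaluate_scores(scores, cv$labels)
}
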