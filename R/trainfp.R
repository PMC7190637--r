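# Fingerprint-network training. Patches are always drawn from the LEFT half
# of each core; generalisation is monitored as core-index accuracy on patches
# from the unseen RIGHT halves, and training stops when that accuracy
# plateaus. In style_paired mode every optimisation step processes a pair of
# renderings of the same morphology patch in two site styles and adds the
# normalized fingerprint-distance penalty (gamma > 0); plain mode runs the
# identical pipeline with gamma = 0, giving a matched-budget baseline.

#' Training configuration
#'
#' @param experiment_mode `"plain"` (identity cross entropy only, gamma = 0)
#'   or `"style_paired"` (composite loss with the fingerprint-distance term).
#' @param steps Maximum optimisation steps.
#' @param batch_size Core pairs per step.
#' @param lr Adam learning rate (peak rate under the one-cycle schedule).
#' @param lr_schedule `"onecycle"` (default: linear warmup over the first 10%
#'   of steps, cosine decay to `lr/10`) or `"constant"`.
#' @param monitor_interval Steps between right-half accuracy evaluations.
#' @param monitor_patches Patches sampled per right half at evaluation
#'   (default 8).
#' @param patience Evaluations without improvement before stopping.
#' @param min_delta Minimum accuracy improvement that counts.
#' @param swa Average the weights of the last 40% of steps (stochastic
#'   weight averaging); stabilises small-batch training. Default `TRUE`.
#' @param loss A [loss_config]; its gamma applies in `style_paired` mode.
#' @param augment An [augment_config].
#' @param seed Seed driving patch sampling and augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(experiment_mode = c("style_paired", "plain"),
                         steps = 400L, batch_size = 8L, lr = 3e-3,
                         lr_schedule = c("onecycle", "constant"),
                         monitor_interval = 50L, monitor_patches = 8L,
                         patience = 10L, min_delta = 0.002, swa = TRUE,
                         loss = loss_config(), augment = augment_config(),
                         seed = 1L) {
  experiment_mode <- match.arg(experiment_mode)
  lr_schedule <- match.arg(lr_schedule)
  if (patience < 1) invalid_arg("patience must be >= 1")
  structure(list(experiment_mode = experiment_mode, steps = as.integer(steps),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_schedule = lr_schedule,
                 monitor_interval = as.integer(monitor_interval),
                 monitor_patches = as.integer(monitor_patches),
                 patience = as.integer(patience), min_delta = min_delta,
                 swa = isTRUE(swa),
                 loss = loss, augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

# Extract a styled, augmented patch from one core's morphology.
# side: "left"/"right"; origin: 0-based (row, col) within the half, NULL =
# uniform random. Returns the rendered [224,224,3] array.
styled_patch <- function(cohort, core_index, side, style_id, patch_px = 224L,
                         origin = NULL, augment = NULL, rot_k = NULL,
                         do_flip = NULL) {
  core <- cohort$cores[[core_index]]
  H <- cohort$core_px
  half_w <- H %/% 2
  stopifnot(H >= patch_px, half_w >= patch_px)
  if (is.null(origin)) {
    origin <- c(sample.int(H - patch_px + 1L, 1L) - 1L,
                sample.int(half_w - patch_px + 1L, 1L) - 1L)
  }
  col0 <- origin[2] + if (side == "right") half_w else 0L
  rows <- origin[1] + seq_len(patch_px)
  cols <- col0 + seq_len(patch_px)
  morph <- list(nuclear = core$morphology$nuclear[rows, cols],
                cytoplasm = core$morphology$cytoplasm[rows, cols])
  px <- render_style(morph, cohort$styles[[style_id]],
                     seed = derive_seed(cohort$seed, core_index, origin[1], origin[2]))
  if (!is.null(augment)) px <- augment_patch(px, augment, rot_k = rot_k, do_flip = do_flip)
  px
}

#' Train a fingerprint network on a synthetic cohort
#'
#' @param cohort An [make_cohort] result (every core has a left/right split
#'   by construction).
#' @param model An [fp_model] whose `n_identities` equals the number of
#'   cores; `NULL` builds a tiny-profile model automatically.
#' @param config A [train_config].
#' @return An `fp_fit`: `model` (weights at the best monitored accuracy),
#'   `log` (data frame of step, ce1, ce2, d2fp, monitor_acc), `config`,
#'   `best_acc`, `stopped_early`.
#' @export
train_fingerprint_network <- function(cohort, model = NULL,
                                      config = train_config()) {
  stopifnot(inherits(cohort, "fp_cohort"))
  n_cores <- length(cohort$cores)
  if (is.null(model)) {
    model <- fp_model(n_cores, "tiny", seed = config$seed)
  }
  if (model$n_identities != n_cores) {
    stop_if_not(FALSE, "model identity count does not match the cohort",
                "tissuefp_data_error")
  }
  gamma <- if (config$experiment_mode == "style_paired") config$loss$gamma else 0
  style_ids <- names(cohort$styles)
  if (config$experiment_mode == "style_paired" && length(style_ids) < 2) {
    stop_if_not(FALSE, "style_paired mode needs at least two styles",
                "tissuefp_data_error")
  }
  # Pre-render every core's LEFT half in every style once (8-bit cache):
  # training touches left halves thousands of times, and the parametric
  # rendering is deterministic per (core, style).
  half_w <- cohort$core_px %/% 2L
  left_cache <- lapply(seq_len(n_cores), function(ci) {
    core <- cohort$cores[[ci]]
    lapply(cohort$styles[style_ids], function(sty) {
      m <- list(nuclear = core$morphology$nuclear[, seq_len(half_w)],
                cytoplasm = core$morphology$cytoplasm[, seq_len(half_w)])
      px <- render_style(m, sty, seed = derive_seed(cohort$seed, 23L, ci))
      a <- as.integer(round(px * 255))
      dim(a) <- dim(px)
      a
    })
  })
  take_patch <- function(ci, style_id, org) {
    left_cache[[ci]][[style_id]][org[1] + 1:224, org[2] + 1:224, , drop = FALSE] / 255
  }

  st <- adam_init(model)
  log_rows <- vector("list", config$steps)
  best_acc <- -Inf
  best_model <- model
  rounds_since <- 0L
  stopped_early <- FALSE
  n_eval <- 0L
  swa_start <- ceiling(0.6 * config$steps)
  swa_acc <- NULL
  swa_n <- 0L

  for (step in seq_len(config$steps)) {
    batch <- with_seed(derive_seed(config$seed, 31L, step), {
      ids <- sample.int(n_cores, config$batch_size,
                        replace = config$batch_size > n_cores)
      x1 <- vector("list", config$batch_size)
      x2 <- vector("list", config$batch_size)
      for (b in seq_along(ids)) {
        s1 <- style_ids[((step + b) %% length(style_ids)) + 1L]
        s2 <- style_ids[((step + b + 1L) %% length(style_ids)) + 1L]
        rk <- sample.int(4L, 1L) - 1L
        fl <- runif(1) < 0.5
        H <- cohort$core_px
        org <- c(sample.int(H - 223L, 1L) - 1L,
                 sample.int(half_w - 223L, 1L) - 1L)
        x1[[b]] <- augment_patch(take_patch(ids[b], s1, org), config$augment,
                                 rot_k = rk, do_flip = fl)
        x2[[b]] <- augment_patch(take_patch(ids[b], s2, org), config$augment,
                                 rot_k = rk, do_flip = fl)
      }
      list(ids = ids, x1 = x1, x2 = x2)
    })
    # both styles of the pair run through one batched forward/backward
    B <- config$batch_size
    fw <- nn_forward(model, c(batch$x1, batch$x2), keep_cache = TRUE,
                     training = TRUE)
    i1 <- seq_len(B); i2 <- B + i1
    g1 <- ce_grad(fw$logits[, i1, drop = FALSE], batch$ids)
    g2 <- ce_grad(fw$logits[, i2, drop = FALSE], batch$ids)
    fd <- fpdist_grad(fw$fingerprint[, i1, drop = FALSE],
                      fw$fingerprint[, i2, drop = FALSE], config$loss$epsilon)
    d2 <- mean(fd$d2)
    dlogits <- cbind(g1$dlogits, g2$dlogits)
    dfp <- if (gamma > 0) gamma * cbind(fd$df1, fd$df2) else NULL
    gr <- nn_backward(model, fw, dlogits, dfp)
    lr_t <- if (identical(config$lr_schedule, "constant")) config$lr else {
      warm <- max(1L, round(0.1 * config$steps))
      if (step <= warm) config$lr * step / warm
      else {
        frac <- (step - warm) / max(1L, config$steps - warm)
        0.1 * config$lr + 0.9 * config$lr * (1 + cos(pi * frac)) / 2
      }
    }
    up <- adam_step(model, gr, st, lr = lr_t)
    model <- up$model; st <- up$state
    if (config$swa && step >= swa_start) {
      swa_acc <- if (is.null(swa_acc)) model else add_params(swa_acc, model)
      swa_n <- swa_n + 1L
    }

    acc <- NA_real_
    if (step %% config$monitor_interval == 0L || step == config$steps) {
      acc <- monitor_right_half_accuracy(model, cohort,
                                         k_patches = config$monitor_patches,
                                         seed = derive_seed(config$seed, 37L, step),
                                         grayscale = config$augment$grayscale)
      n_eval <- n_eval + 1L
      if (acc > best_acc + config$min_delta) {
        best_acc <- acc
        best_model <- model
        rounds_since <- 0L
      } else {
        rounds_since <- rounds_since + 1L
      }
      if (best_acc == -Inf) { best_acc <- acc; best_model <- model }
    }
    log_rows[[step]] <- data.frame(step = step, ce1 = g1$loss, ce2 = g2$loss,
                                   d2fp = d2, monitor_acc = acc)
    if (!is.na(acc) && rounds_since >= config$patience) {
      stopped_early <- TRUE
      break
    }
  }
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  out_model <- if (config$swa && swa_n > 0L) scale_params(swa_acc, 1 / swa_n)
               else best_model
  structure(list(model = out_model, best_model = best_model,
                 final_model = model, log = log,
                 config = config, best_acc = max(best_acc, 0),
                 stopped_early = stopped_early, n_evaluations = n_eval),
            class = "fp_fit")
}

# elementwise weight arithmetic over the trainable parameters (batch-norm
# running statistics are averaged along with the weights)
add_params <- function(a, b) {
  for (i in seq_along(a$layers)) {
    ty <- a$layers[[i]]$type
    if (!ty %in% c("conv", "bnorm_t")) next
    a$layers[[i]]$W <- a$layers[[i]]$W + b$layers[[i]]$W
    a$layers[[i]]$b <- a$layers[[i]]$b + b$layers[[i]]$b
    if (ty == "bnorm_t") {
      a$layers[[i]]$rmean <- a$layers[[i]]$rmean + b$layers[[i]]$rmean
      a$layers[[i]]$rvar <- a$layers[[i]]$rvar + b$layers[[i]]$rvar
    }
  }
  a$head$W <- a$head$W + b$head$W
  a$head$b <- a$head$b + b$head$b
  a
}

scale_params <- function(a, s) {
  for (i in seq_along(a$layers)) {
    ty <- a$layers[[i]]$type
    if (!ty %in% c("conv", "bnorm_t")) next
    a$layers[[i]]$W <- a$layers[[i]]$W * s
    a$layers[[i]]$b <- a$layers[[i]]$b * s
    if (ty == "bnorm_t") {
      a$layers[[i]]$rmean <- a$layers[[i]]$rmean * s
      a$layers[[i]]$rvar <- a$layers[[i]]$rvar * s
    }
  }
  a$head$W <- a$head$W * s
  a$head$b <- a$head$b * s
  a
}

add_grads <- function(a, b) {
  for (i in seq_along(a$layers)) {
    if (is.null(a$layers[[i]])) next
    a$layers[[i]]$dW <- a$layers[[i]]$dW + b$layers[[i]]$dW
    a$layers[[i]]$db <- a$layers[[i]]$db + b$layers[[i]]$db
  }
  a$head$dW <- a$head$dW + b$head$dW
  a$head$db <- a$head$db + b$head$db
  a
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf("<fp_fit> mode=%s  steps=%d  best right-half accuracy=%.3f%s\n",
              x$config$experiment_mode, nrow(x$log), x$best_acc,
              if (x$stopped_early) " (early stop)" else ""))
  invisible(x)
}

#' @export
plot.fp_fit <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$log$step, x$log$ce1 + x$log$ce2, type = "l",
                 xlab = "step", ylab = "cross entropy (pair)", main = "identity loss")
  ok <- !is.na(x$log$monitor_acc)
  graphics::plot(x$log$step[ok], x$log$monitor_acc[ok], type = "b",
                 xlab = "step", ylab = "right-half accuracy", main = "monitor")
  invisible(x)
}

#' Right-half core-index accuracy
#'
#' Samples `k_patches` patches from the right half of every core (cycling
#' through the cohort's styles), averages the softmax identity distributions
#' per core, and reports the fraction of cores whose aggregated argmax equals
#' their own index. This is the held-out signal used for early stopping:
#' the network never trains on right halves.
#'
#' @param model An [fp_model].
#' @param cohort An [make_cohort] result.
#' @param k_patches Patches per right half (default 8).
#' @param seed Patch-sampling seed.
#' @param grayscale Convert patches to grayscale; must match how the model
#'   was trained (see [augment_config]).
#' @return Accuracy in `[0, 1]`.
#' @export
monitor_right_half_accuracy <- function(model, cohort, k_patches = 8L, seed = 1L,
                                        grayscale = TRUE) {
  n_cores <- length(cohort$cores)
  style_ids <- names(cohort$styles)
  aug <- augment_config(rotate = FALSE, flip = FALSE, mult_jitter = 0,
                        add_jitter = 0,
                        grayscale = grayscale)
  correct <- 0L
  with_seed(derive_seed(seed, 41L), {
    for (ci in seq_len(n_cores)) {
      patches <- lapply(seq_len(k_patches), function(j) {
        styled_patch(cohort, ci, "right", style_ids[(j %% length(style_ids)) + 1L],
                     augment = aug)
      })
      p <- predict(model, patches, type = "prob")
      agg <- rowMeans(p)
      if (which.max(agg) == ci) correct <- correct + 1L
    }
  })
  correct / n_cores
}

#' Extract fingerprints for a set of patches
#'
#' @param model An [fp_model] (or an `fp_fit`, whose best model is used).
#' @param patches List of `[224, 224, 3]` arrays or `patch_sample` objects;
#'   an empty list yields a `0 x D` matrix.
#' @param chunk Patches per forward batch.
#' @return List with `fingerprints` (`n x D` matrix) and `sources` (data
#'   frame of core index, origin and side where available).
#' @export
extract_fingerprints <- function(model, patches, chunk = 32L) {
  if (inherits(model, "fp_fit")) model <- model$model
  n <- length(patches)
  D <- model$fingerprint_dim
  if (n == 0L) {
    return(list(fingerprints = matrix(numeric(0), 0, D),
                sources = data.frame(core_index = integer(0),
                                     row = integer(0), col = integer(0),
                                     side = character(0))))
  }
  src <- do.call(rbind, lapply(patches, function(p) {
    if (inherits(p, "patch_sample")) {
      data.frame(core_index = p$core_index %||% NA_integer_,
                 row = unname(p$origin[1]), col = unname(p$origin[2]),
                 side = p$side %||% NA_character_)
    } else {
      data.frame(core_index = NA_integer_, row = NA_integer_,
                 col = NA_integer_, side = NA_character_)
    }
  }))
  arrays <- lapply(patches, function(p) if (inherits(p, "patch_sample")) p$pixels else p)
  out <- matrix(0, n, D)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    fp <- nn_forward(model, arrays[i:j])$fingerprint
    out[i:j, ] <- t(fp)
    i <- j + 1L
  }
  list(fingerprints = out, sources = src)
}
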