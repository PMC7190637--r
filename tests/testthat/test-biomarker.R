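# Slide tiling, bags, the MIL head, AUC machinery and cross-validation.

solid_slide <- function(S, mpp = 0.5, color = c(0.8, 0.3, 0.5)) {
  list(slide_id = 1L, patient_id = 1L,
       pixels = array(rep(color, each = S * S), c(S, S, 3)),
       mask = NULL, mpp = mpp)
}

test_that("slide tiling follows the 112-um grid and resamples to 224 px", {
  # saturated slide: everything is foreground; 2048 px at 0.5 um/px -> 9x9
  s <- solid_slide(2048)
  # inject a low-saturation (background) band so Otsu has two classes
  s$pixels[1:640, , 1] <- 0.95; s$pixels[1:640, , 2] <- 0.95; s$pixels[1:640, , 3] <- 0.95
  p <- tile_slide(s)
  expect_lte(length(p), 81)
  expect_true(all(vapply(p, function(q) all(dim(q$pixels) == c(224, 224, 3)),
                         logical(1))))
  # rows overlapping the background band are dropped
  expect_true(all(vapply(p, function(q) q$origin[1] >= 560, logical(1))))
  # at 0.25 um/px the grid squares are 448 px, still resampled to 224
  s2 <- solid_slide(1024, mpp = 0.25)
  s2$pixels[1:256, , ] <- 0.95
  p2 <- tile_slide(s2)
  expect_true(all(vapply(p2, function(q) all(dim(q$pixels) == c(224, 224, 3)),
                         logical(1))))
  expect_true(all(vapply(p2, function(q) q$origin[1] %% 448 == 0, logical(1))))
  expect_warning(tile_slide(solid_slide(1024, color = c(0.95, 0.95, 0.95))),
                 "no foreground")
  expect_error(tile_slide(list(pixels = solid_slide(1024)$pixels, mpp = NULL)),
               class = "tissuefp_data_error")
})

test_that("tissue classes are attached from the mask majority", {
  s <- solid_slide(1024)
  s$pixels[1:224, , ] <- 0.95
  s$mask <- matrix(2L, 1024, 1024)
  s$mask[, 1:512] <- 1L
  p <- tile_slide(s)
  cl <- vapply(p, `[[`, integer(1), "tissue_class")
  expect_setequal(unique(cl), c(1L, 2L))
  left <- vapply(p, function(q) q$origin[2] + 224 <= 512, logical(1))
  expect_true(all(cl[left] == 1L))
})

test_that("bags sample without replacement when possible, with when not", {
  m <- tiny_model(8)
  mk_patch <- function(i) list(pixels = rand_patch(i), origin = c(row = i, col = 0),
                               tissue_class = 1L)
  many <- lapply(1:150, mk_patch)
  b <- make_bag(many, m, k = 120, seed = 3, patient_id = 7)
  expect_equal(nrow(b$fingerprints), 120)
  expect_equal(ncol(b$fingerprints), 32)
  expect_equal(nrow(unique(b$sources)), 120)   # distinct patches
  few <- lapply(1:10, mk_patch)
  expect_warning(b2 <- make_bag(few, m, k = 30, seed = 3), "replacement")
  expect_equal(nrow(b2$fingerprints), 30)
  expect_lte(nrow(unique(b2$sources)), 10)
  b3 <- suppressWarnings(make_bag(few, m, k = 30, seed = 3))
  expect_identical(b2, b3)                      # fixed seed, identical bag
  expect_error(make_bag(list(), m, k = 10), class = "tissuefp_data_error")
})

test_that("patient scores average patch outputs and stay in [-1, 1]", {
  head <- tissuefp:::new_marker_head(8, seed = 2)
  set.seed(4)
  F <- matrix(rnorm(40 * 8), 40, 8)
  bag <- structure(list(patient_id = 1, fingerprints = F,
                        tissue_class = rep(c(1L, 3L), 20)),
                   class = "patch_bag")
  s <- predict_patient(head, bag)
  expect_gte(s, -1); expect_lte(s, 1)
  # compositional oracle: mean of individually scored patches
  singles <- vapply(seq_len(40), function(i)
    tissuefp:::head_scores(head, F[i, , drop = FALSE]), numeric(1))
  expect_equal(s, mean(singles), tolerance = 1e-7)
  # tissue filter averages the matching patches only
  s_epi <- predict_patient(head, bag, tissue_class = 1L)
  expect_equal(s_epi, mean(singles[seq(1, 39, 2)]), tolerance = 1e-7)
  expect_true(is.na(predict_patient(head, bag, tissue_class = 2L)))
  empty <- structure(list(fingerprints = matrix(0, 0, 8),
                          tissue_class = integer(0)), class = "patch_bag")
  expect_error(predict_patient(head, empty), class = "tissuefp_data_error")
})

test_that("rank AUC matches exhaustive pair counting and pROC", {
  score <- c(0.9, 0.2, 0.6, 0.1, 0.5, 0.3)
  label <- c(1, -1, 1, -1, 1, -1)
  pairs <- expand.grid(p = which(label > 0), n = which(label < 0))
  oracle <- mean(ifelse(score[pairs$p] > score[pairs$n], 1,
                        ifelse(score[pairs$p] == score[pairs$n], 0.5, 0)))
  expect_equal(tissuefp:::auc_rank(score, label), oracle)
  ev <- evaluate_scores(score, label)
  expect_equal(ev$auc, oracle)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
  expect_equal(ev$roc$fpr[nrow(ev$roc)], 1)
  skip_if_not_installed("pROC")
  set.seed(5)
  s2 <- rnorm(80); l2 <- rep(c(1, -1), 40)
  expect_equal(tissuefp:::auc_rank(s2, l2),
               as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
  # perfect separation and null behaviour
  expect_equal(tissuefp:::auc_rank(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 1)
  set.seed(6)
  expect_equal(tissuefp:::auc_rank(rnorm(200), rep(c(1, -1), 100)), 0.5,
               tolerance = 0.12)
  expect_error(tissuefp:::auc_rank(1:3, c(1, 1, 1)), class = "tissuefp_stats_error")
})

test_that("the MIL head learns separable bags and respects early stopping", {
  gb <- gaussian_bags(40, seed = 7)
  tr <- 1:24; ov <- 25:32
  h <- train_marker_head(gb$bags[tr], gb$labels[tr], gb$bags[ov], gb$labels[ov],
                         head_config(steps = 300, eval_interval = 20,
                                     patience = 5, restarts = 1, seed = 1))
  expect_gte(attr(h, "best_auc"), 0.9)
  te <- 33:40
  sc <- vapply(gb$bags[te], function(b) predict_patient(h, b), numeric(1))
  expect_gte(tissuefp:::auc_rank(sc, gb$labels[te]), 0.9)
  # shuffled labels -> chance-level monitored AUC
  set.seed(8)
  sh <- sample(gb$labels[tr])
  h0 <- train_marker_head(gb$bags[tr], sh, gb$bags[ov], gb$labels[ov],
                          head_config(steps = 120, eval_interval = 20,
                                      patience = 3, restarts = 1, seed = 1))
  expect_lte(attr(h0, "best_auc"), 0.85)
  # the kept weights are the best ones, not the last evaluated
  log <- attr(h, "log")
  evals <- log$overfit_auc[!is.na(log$overfit_auc)]
  expect_equal(attr(h, "best_auc"), max(evals))
  # single-class overfitting group is a fold error
  expect_error(train_marker_head(gb$bags[tr], gb$labels[tr], gb$bags[1:3],
                                 c(1, 1, 1), head_config(steps = 10)),
               class = "tissuefp_fold_error")
  # restart ensembling: members average into one patient score
  ens <- train_marker_head(gb$bags[tr], gb$labels[tr], gb$bags[ov],
                           gb$labels[ov],
                           head_config(steps = 150, eval_interval = 30,
                                       patience = 3, restarts = 2, seed = 1))
  expect_s3_class(ens, "marker_head_ens")
  expect_length(ens$members, 2)
  b1 <- gb$bags[[te[1]]]
  expect_equal(predict_patient(ens, b1),
               mean(vapply(ens$members, function(h) predict_patient(h, b1),
                           numeric(1))), tolerance = 1e-10)
})

test_that("cross-validation partitions patients and recovers strong signal", {
  gb <- gaussian_bags(60, seed = 9)
  cv <- run_cross_validation(gb$bags, gb$labels, n_folds = 5, seed = 2,
                             config = head_config(steps = 200,
                                                  eval_interval = 20,
                                                  patience = 4, restarts = 1))
  expect_length(cv$fold_auc, 5)
  expect_equal(sort(unique(cv$groups)), 1:5)
  expect_equal(as.vector(table(cv$groups)), rep(12, 5))   # stratified, balanced
  expect_gte(cv$mean_auc, 0.85)
  expect_false(any(is.na(cv$scores)))                     # out-of-fold score per patient
  # same seed reproduces the grouping
  cv2_groups <- cv_groups(gb$labels, 5, seed = 2)
  expect_identical(cv$groups, cv2_groups)
})
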