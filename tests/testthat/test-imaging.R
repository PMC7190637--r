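# Core preparation geometry, half-open splitting, patch sampling and
# augmentation, and the restyle contract.

test_that("prepare_core rescales and center-crops to the working geometry", {
  set.seed(1)
  raw <- array(runif(400 * 400 * 3), c(400, 400, 3))
  # 400 px at 0.25 um/px covers 100 um -> 200 px at 0.5; pad up to target
  out <- prepare_core(raw, mpp_in = 0.25, target_px = 256)
  expect_equal(dim(out$pixels), c(256, 256, 3))
  expect_equal(out$mpp, 0.5)
  # identity: already at target size and resolution
  raw2 <- array(runif(256 * 256 * 3), c(256, 256, 3))
  out2 <- prepare_core(raw2, mpp_in = 0.5, target_px = 256)
  expect_identical(out2$pixels, raw2)
  # oversize input is center-cropped after rescaling
  raw3 <- array(runif(600 * 600 * 3), c(600, 600, 3))
  out3 <- prepare_core(raw3, mpp_in = 0.5, target_px = 256)
  expect_identical(out3$pixels, raw3[172 + 1:256, 172 + 1:256, ])
})

test_that("prepare_core pads short axes symmetrically with the border color", {
  fill <- c(0.9, 0.8, 0.7)
  raw <- array(rep(fill, each = 300 * 200), c(300, 200, 3))
  out <- prepare_core(raw, mpp_in = 0.5, target_px = 300)
  expect_equal(dim(out$pixels), c(300, 300, 3))
  expect_equal(out$pad_color, fill, tolerance = 0.01)
  # 50-px pad bands on both column sides
  expect_equal(out$pixels[150, 25, ], fill, tolerance = 0.01)
  expect_equal(out$pixels[150, 290, ], fill, tolerance = 0.01)
  expect_error(prepare_core(raw, mpp_in = 0.5, target_px = 300, pad = FALSE),
               class = "tissuefp_size_error")
})

test_that("halves split half-open with no shared columns and exact recomposition", {
  set.seed(2)
  px <- array(runif(64 * 64 * 3), c(64, 64, 3))
  core <- structure(list(pixels = px, prepared = TRUE), class = "core_image")
  h <- split_halves(core)
  expect_equal(dim(h$left), c(64, 32, 3))
  expect_equal(dim(h$right), c(64, 32, 3))
  recomposed <- array(0, dim(px))
  recomposed[, 1:32, ] <- h$left
  recomposed[, 33:64, ] <- h$right
  expect_identical(recomposed, px)
  # column 32 (0-based) = column 33 (1-based) lives in the right half only
  expect_identical(h$right[, 1, ], px[, 33, ])
  expect_equal(attr(h$right, "col_offset"), 32L)
  expect_error(split_halves(structure(list(pixels = px, prepared = FALSE),
                                      class = "core_image")),
               class = "tissuefp_state_error")
})

test_that("patch origins are uniform over the valid grid and reproducible", {
  set.seed(3)
  half <- array(runif(300 * 240 * 3), c(300, 240, 3))
  orgs <- t(replicate(300, sample_patch(half)$origin))
  expect_true(all(orgs[, 1] >= 0 & orgs[, 1] <= 300 - 224))
  expect_true(all(orgs[, 2] >= 0 & orgs[, 2] <= 240 - 224))
  # both extremes get visited on a small grid
  expect_gt(length(unique(orgs[, 2])), 10)
  # single valid origin
  small <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_identical(unname(sample_patch(small)$origin), c(0L, 0L))
  expect_error(sample_patch(array(0, c(200, 224, 3))), class = "tissuefp_size_error")
  set.seed(42); a <- replicate(5, sample_patch(half)$origin)
  set.seed(42); b <- replicate(5, sample_patch(half)$origin)
  expect_identical(a, b)
})

test_that("augmentation honors identity, involution and grayscale contracts", {
  x <- rand_patch(4)
  off <- augment_config(rotate = FALSE, flip = FALSE, mult_jitter = 0,
                        add_jitter = 0, grayscale = FALSE)
  expect_identical(augment_patch(x, off), x)
  r180 <- augment_patch(x, off, rot_k = 2)
  expect_identical(augment_patch(r180, off, rot_k = 2), x)
  r90 <- augment_patch(x, off, rot_k = 1)
  expect_equal(dim(r90), dim(x))
  expect_false(identical(r90, x))
  gray <- augment_patch(x, augment_config(rotate = FALSE, flip = FALSE,
                                          mult_jitter = 0, add_jitter = 0,
                                          grayscale = TRUE))
  expect_identical(gray[, , 1], gray[, , 2])
  expect_identical(gray[, , 1], gray[, , 3])
  set.seed(5)
  jit <- augment_patch(x, augment_config(mult_jitter = 0.2, add_jitter = 0.2,
                                         grayscale = FALSE))
  expect_true(all(jit >= 0 & jit <= 1))
})

test_that("restyle preserves morphology and matches the direct render", {
  coh <- small_cohort()
  a <- core_image(coh, 2, "siteA")$pixels
  b <- core_image(coh, 2, "siteB")$pixels
  expect_identical(restyle(a, "siteA", "siteA"), a)
  r <- restyle(a, "siteA", "siteB")
  expect_equal(r, b, tolerance = 1e-10)
  expect_error(restyle(a, "siteA", "nosuch"), class = "tissuefp_config_error")
  # luminance-gradient structure survives restyling
  gl <- function(img) { y <- tissuefp:::luminance(img); abs(diff(y)) }
  expect_gt(cor(as.vector(gl(a)), as.vector(gl(r))), 0.9)
})

test_that("file-backed restyle returns stored twins bit-exactly", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort_images(coh, dir, styles = c("siteA", "siteB"))
  b_stored <- png_to_rgb_fixture(file.path(dir, "core_0003_siteB.png"))
  got <- restyle(core_image(coh, 3, "siteA")$pixels, "siteA", "siteB",
                 dir = dir, core_index = 3)
  expect_identical(got, b_stored)
  # manifest round trip
  img <- read_core_image(dir, 3, "siteB")
  expect_identical(img$pixels, b_stored)
  expect_equal(img$patient_id, coh$cores[[3]]$patient_id)
})
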