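# Heatmaps and embeddings: probability aggregation and conservation, value
# ranges, grid geometry, grayscale mapping and cluster retrieval.

test_that("core-to-patient aggregation conserves probability mass", {
  layout <- make_layout(207, 104)
  expect_length(layout, 207)
  expect_equal(length(unique(layout)), 104)
  expect_true(all(table(layout) %in% c(1, 2)))
  set.seed(1)
  z <- rnorm(207)
  p <- exp(z) / sum(exp(z))
  agg <- aggregate_to_patients(p, layout)
  expect_length(agg, 104)
  expect_equal(sum(agg), 1, tolerance = 1e-9)
  expect_true(all(agg >= 0))
  # uniform softmax: a 2-core patient receives 2/207
  u <- rep(1 / 207, 207)
  aggu <- aggregate_to_patients(u, layout)
  two_core <- names(which(table(layout) == 2))[1]
  expect_equal(aggu[[two_core]], 2 / 207, tolerance = 1e-12)
  one_core <- names(which(table(layout) == 1))[1]
  expect_equal(aggu[[one_core]], 1 / 207, tolerance = 1e-12)
})

test_that("identity heatmaps have probability values on the tiling grid", {
  coh <- small_cohort()
  m <- tiny_model(8)
  core <- core_image(coh, 1, "siteA")
  hm <- identity_heatmap(m, core, coh$layout, stride = 112)
  nr <- (448 - 224) %/% 112 + 1
  expect_equal(dim(hm$values), c(nr, nr))
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  expect_equal(hm$kind, "identity_prob")
  # default stride is 45 px (80% linear overlap of 224)
  hm2 <- identity_heatmap(m, core, coh$layout)
  expect_equal(hm2$stride, 45L)
  expect_equal(nrow(hm2$values), (448 - 224) %/% 45 + 1)
  expect_error(identity_heatmap(m, core, make_layout(20, 10)),
               class = "tissuefp_config_error")
})

test_that("similarity heatmaps are 1 on matching constant halves and reproducible", {
  m <- tiny_model(8)
  half <- array(0.4, c(448, 224, 3))
  hm <- similarity_heatmap(m, half, half)
  # constant input standardizes to (numerically) zero, so fingerprints are
  # float noise; similarity still collapses to 1 up to that noise
  expect_true(all(abs(hm$values - 1) < 1e-3))
  set.seed(2)
  q <- array(runif(448 * 224 * 3), c(448, 224, 3))
  h1 <- similarity_heatmap(m, q, half)
  h2 <- similarity_heatmap(m, q, half)
  expect_identical(h1$values, h2$values)
  expect_true(all(h1$values >= 0 & h1$values <= 1))
})

test_that("marker heatmaps map scores to grayscale with background mid-gray", {
  coh <- memo("wsi_small", make_wsi_cohort(2, slide_px = 1024, seed = 8))
  s <- render_slide(coh, 1)
  m <- tiny_model(8)
  # zero head: all foreground predictions exactly 0 -> mid-gray 0.5
  head0 <- tissuefp:::new_marker_head(32, seed = 1)
  head0$W1[] <- 0; head0$b1[] <- 0; head0$w2[] <- 0; head0$b2 <- 0
  hm <- marker_heatmap(head0, m, s)
  expect_equal(dim(hm$values), c(4, 4))
  fg <- !is.na(hm$values)
  expect_true(any(fg))
  expect_true(all(hm$values[fg] == 0))
  raster <- hm$provenance$raster
  expect_true(all(raster == 0.5))
  expect_identical(attr(raster, "foreground"), fg)
  # endpoint mapping: score -1 -> 0 (black), +1 -> 255/255 (white)
  v <- matrix(c(-1, 0, 1, NA), 2, 2)
  expect_equal(((v + 1) / 2)[1, 1], 0)
  expect_equal(((v + 1) / 2)[1, 2], 1)
  # heat values agree with the bag-level patient score on the same patches
  head1 <- tissuefp:::new_marker_head(32, seed = 2)
  hm1 <- marker_heatmap(head1, m, s)
  patches <- tile_slide(s)
  bag <- make_bag(patches, m, k = length(patches), seed = 1, patient_id = 1)
  # bag sampling permutes but covers every patch exactly once
  expect_equal(mean(hm1$values, na.rm = TRUE),
               predict_patient(head1, bag), tolerance = 1e-7)
})

test_that("embedding places duplicates together and retrieves nearest patches", {
  set.seed(3)
  X <- matrix(rnorm(60 * 8), 60, 8)
  X[31:60, ] <- X[1:30, ]          # exact duplicates
  sc <- runif(60, -1, 1)
  emb <- embed_and_cluster(X, sc, seed = 4, perplexity = 8, n_iter = 250)
  expect_equal(dim(emb$coords), c(60, 2))
  span <- max(dist(emb$coords))
  dup_d <- sqrt(rowSums((emb$coords[1:30, ] - emb$coords[31:60, ])^2))
  # duplicates land together: typically well under 1% of the span, always
  # within a few percent (they are exchangeable, not glued)
  expect_lt(median(dup_d), 0.01 * span)
  expect_lt(max(dup_d), 0.05 * span)
  # retrieval agrees with an exhaustive scan
  centers <- emb$coords[c(5, 40), ]
  emb2 <- embed_and_cluster(X, sc, seed = 4, centers = centers, k_patches = 5,
                            perplexity = 8, n_iter = 250)
  expect_length(emb2$clusters, 2)
  for (i in 1:2) {
    d <- sqrt(colSums((t(emb2$coords) - centers[i, ])^2))
    expect_identical(emb2$clusters[[i]]$index, order(d)[1:5])
    expect_length(emb2$clusters[[i]]$index, 5)
  }
  expect_error(embed_and_cluster(X[1:12, ], sc[1:12], perplexity = 30),
               class = "tissuefp_config_error")
})

test_that("heatmaps serialise to PNG plus TSV", {
  dir <- withr::local_tempdir()
  hm <- tissuefp:::new_heatmap(matrix(runif(12), 3, 4), "identity_prob", 224L, 45L)
  p <- write_heatmap(hm, file.path(dir, "hm"))
  expect_true(file.exists(p))
  vals <- as.matrix(read.table(file.path(dir, "hm.tsv"), sep = "\t"))
  expect_equal(unname(vals), unname(hm$values), tolerance = 1e-7)
})
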