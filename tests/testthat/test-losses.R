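# Identity loss family: closed-form cases, brute-force compositional oracle,
# analytic distance limits and gradient correctness.

brute_ce <- function(c, y) -log(exp(c[y]) / sum(exp(c)))   # naive oracle

brute_d2 <- function(f1, f2, eps = 1e-6) {
  u <- f1 / (sqrt(sum(f1^2)) + eps)
  v <- f2 / (sqrt(sum(f2^2)) + eps)
  sum((u - v)^2)
}

test_that("cross entropy matches direct evaluation and is shift invariant", {
  expect_equal(cross_entropy(c(0, 0), 1), log(2))
  expect_equal(cross_entropy(c(10, 0, 0), 1), brute_ce(c(10, 0, 0), 1),
               tolerance = 1e-9)
  expect_equal(cross_entropy(c(10, 0, 0), 1), 9.079574e-05, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:20) {
    c <- rnorm(7, sd = 3)
    y <- sample(7, 1)
    expect_equal(cross_entropy(c, y), brute_ce(c, y), tolerance = 1e-10)
    expect_equal(cross_entropy(c + 123.4, y), cross_entropy(c, y),
                 tolerance = 1e-9)
  }
  # log-sum-exp stability where the naive form overflows
  expect_equal(cross_entropy(c(1000, 0), 2), 1000)
  expect_error(cross_entropy(c(0, 0), 3), class = "tissuefp_invalid_argument")
})

test_that("fingerprint distance hits the analytic limits", {
  expect_lt(fingerprint_distance(c(1, 2, 3), c(1, 2, 3)), 1e-10)
  expect_equal(fingerprint_distance(c(1, 0), c(0, 1)), 2, tolerance = 1e-5)
  expect_equal(fingerprint_distance(c(1, 2), c(-1, -2)), 4, tolerance = 1e-5)
  expect_error(fingerprint_distance(1:3, 1:4), class = "tissuefp_invalid_argument")
})

test_that("fingerprint distance is symmetric, nonnegative and bounded", {
  set.seed(2)
  for (i in 1:50) {
    a <- rnorm(16); b <- rnorm(16)
    d1 <- fingerprint_distance(a, b)
    expect_identical(d1, fingerprint_distance(b, a))
    expect_gte(d1, 0)
    expect_lte(d1, 4 + 1e-9)
  }
})

test_that("composite loss equals the recomposition of independent oracles", {
  set.seed(3)
  for (i in 1:100) {
    n_id <- sample(3:10, 1)
    D <- sample(4:16, 1)
    o1 <- list(logits = rnorm(n_id, sd = 2), fingerprint = rnorm(D))
    o2 <- list(logits = rnorm(n_id, sd = 2), fingerprint = rnorm(D))
    y <- sample(n_id, 1)
    gamma <- runif(1, 0, 1)
    got <- composite_loss(o1, o2, y, loss_config(gamma = gamma))
    want <- brute_ce(o1$logits, y) + brute_ce(o2$logits, y) +
      gamma * brute_d2(o1$fingerprint, o2$fingerprint)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("gamma = 0 reduces to the two cross entropies; loss is monotone in gamma", {
  set.seed(4)
  o1 <- list(logits = rnorm(5), fingerprint = rnorm(8))
  o2 <- list(logits = rnorm(5), fingerprint = rnorm(8))
  expect_equal(composite_loss(o1, o2, 2, loss_config(gamma = 0)),
               cross_entropy(o1$logits, 2) + cross_entropy(o2$logits, 2),
               tolerance = 1e-12)
  ls <- vapply(c(0, 0.25, 0.5, 1, 2),
               function(g) composite_loss(o1, o2, 2, loss_config(gamma = g)),
               numeric(1))
  expect_true(all(diff(ls) >= 0))
  # identical outputs: distance term vanishes
  expect_equal(composite_loss(o1, o1, 2, loss_config(gamma = 0.5)),
               2 * cross_entropy(o1$logits, 2), tolerance = 1e-9)
})

test_that("analytic loss gradients match numerical differentiation", {
  set.seed(5)
  logits <- matrix(rnorm(5 * 3, sd = 2), 5, 3)
  y <- c(2, 4, 1)
  g <- tissuefp:::ce_grad(logits, y)
  eps <- 1e-6
  for (i in c(1, 7, 12)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (tissuefp:::ce_grad(lp, y)$loss - tissuefp:::ce_grad(lm, y)$loss) / (2 * eps)
    expect_equal(g$dlogits[i], num, tolerance = 1e-4)
  }
  f1 <- matrix(rnorm(8 * 2), 8, 2)
  f2 <- matrix(rnorm(8 * 2), 8, 2)
  fg <- tissuefp:::fpdist_grad(f1, f2, 1e-6)
  mean_d2 <- function(a, b) mean(tissuefp:::fpdist_grad(a, b, 1e-6)$d2)
  for (i in c(1, 5, 13)) {
    fp <- f1; fp[i] <- fp[i] + eps
    fm <- f1; fm[i] <- fm[i] - eps
    num <- (mean_d2(fp, f2) - mean_d2(fm, f2)) / (2 * eps)
    expect_equal(fg$df1[i], num, tolerance = 1e-4)
  }
})

test_that("network gradients agree with numerical differentiation end to end", {
  m <- fp_model(4, "tiny", fingerprint_dim = 8, seed = 3)
  set.seed(6)
  x <- array(runif(224 * 224 * 3 * 2), c(224, 224, 3, 2))
  y <- c(2, 3)
  fwd <- tissuefp:::nn_forward(m, x, keep_cache = TRUE, training = TRUE)
  g <- tissuefp:::ce_grad(fwd$logits, y)
  gr <- tissuefp:::nn_backward(m, fwd, g$dlogits)
  lossfn <- function(mm) {
    tissuefp:::ce_grad(tissuefp:::nn_forward(mm, x, training = TRUE)$logits,
                       y)$loss
  }
  eps <- 1e-5
  conv2 <- which(vapply(m$layers, `[[`, character(1), "type") == "conv")[2]
  bn2 <- which(vapply(m$layers, `[[`, character(1), "type") == "bnorm_t")[2]
  # head weight, a mid-network conv weight, and a batch-norm scale
  for (spec in list(list(where = "head", i = 5), list(where = "conv", i = 40),
                    list(where = "bn", i = 3))) {
    m2 <- m; m3 <- m
    if (spec$where == "head") {
      m2$head$W[spec$i] <- m2$head$W[spec$i] + eps
      m3$head$W[spec$i] <- m3$head$W[spec$i] - eps
      ana <- gr$head$dW[spec$i]
    } else if (spec$where == "conv") {
      m2$layers[[conv2]]$W[spec$i] <- m2$layers[[conv2]]$W[spec$i] + eps
      m3$layers[[conv2]]$W[spec$i] <- m3$layers[[conv2]]$W[spec$i] - eps
      ana <- gr$layers[[conv2]]$dW[spec$i]
    } else {
      m2$layers[[bn2]]$W[spec$i] <- m2$layers[[bn2]]$W[spec$i] + eps
      m3$layers[[bn2]]$W[spec$i] <- m3$layers[[bn2]]$W[spec$i] - eps
      ana <- gr$layers[[bn2]]$dW[spec$i]
    }
    num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
    expect_equal(ana, num, tolerance = 1e-4)
  }
})
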