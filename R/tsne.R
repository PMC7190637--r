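# Exact (dense) tSNE, adequate for the desk-scale embeddings this package
# produces (up to a few thousand fingerprints). Standard formulation:
# per-point precisions tuned by bisection to a target perplexity, symmetrized
# input affinities, Student-t low-dimensional kernel, gradient descent with
# momentum and early exaggeration.

tsne_embed <- function(X, perplexity = 30, n_iter = 500L, seed = 1L,
                       lr = NULL, momentum = c(0.5, 0.8), exaggeration = 4,
                       exaggeration_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  # the usual heuristic: learning rate ~ n / early exaggeration, floored
  if (is.null(lr)) lr <- max(10, n / exaggeration)
  if (n - 1 < 3 * perplexity) {
    stop_if_not(FALSE, sprintf(
      "tSNE needs > 3*perplexity + 1 rows (n = %d, perplexity = %g); lower the perplexity",
      n, perplexity), "tissuefp_config_error")
  }
  D2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- Inf
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    di <- D2[i, ]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { H <- 0 } else {
        pr <- w / sw
        nz <- pr > 0
        H <- -sum(pr[nz] * log(pr[nz]))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { beta_lo <- beta; beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2 }
      else { beta_hi <- beta; beta <- (beta + beta_lo) / 2 }
    }
    P[i, ] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  Y <- with_seed(derive_seed(seed, 71L), matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  V <- Y * 0
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= exaggeration_iter) P * exaggeration else P
    num <- 1 / (1 + outer(rowSums(Y^2), rowSums(Y^2), "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    M <- (Pe - Q) * num
    G <- 4 * (diag(rowSums(M)) - M) %*% Y
    mom <- if (iter <= 250) momentum[1] else momentum[2]
    V <- mom * V - lr * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
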