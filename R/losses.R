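# The identity loss family. Training minimises, for a same-core image pair
# rendered in two staining styles,
#   loss = CE(c1, y) + CE(c2, y) + gamma * d2_FP(fp1, fp2)
# where CE is softmax cross entropy over core indices and d2_FP is the squared
# Euclidean distance between the L2-normalized fingerprints. The distance term
# pulls fingerprints of the two styles of one core together, which is what
# makes the learned features stain-invariant.

#' Loss configuration
#'
#' @param gamma Weight of the fingerprint-distance term (default 0.5; 0
#'   disables it, recovering plain identity training).
#' @param epsilon Stabiliser added to each fingerprint norm before dividing.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(gamma = 0.5, epsilon = 1e-6) {
  if (gamma < 0) invalid_arg("gamma must be >= 0")
  if (epsilon <= 0) invalid_arg("epsilon must be > 0")
  structure(list(gamma = gamma, epsilon = epsilon), class = "loss_config")
}

#' Softmax cross entropy for an identity classification vector
#'
#' Computes `-log(exp(c[y]) / sum(exp(c)))` in a log-sum-exp stable way.
#'
#' @param c Numeric classification vector (unnormalised logits), one entry per
#'   identity.
#' @param y Integer identity label in `1..length(c)`.
#' @return The cross-entropy loss (scalar).
#' @examples
#' cross_entropy(c(0, 0), 1)   # log(2)
#' @export
cross_entropy <- function(c, y) {
  c <- as.numeric(c)
  if (length(y) != 1L || y < 1 || y > length(c) || y != round(y)) {
    invalid_arg("y must be a single integer in 1..length(c)")
  }
  m <- max(c)
  lse <- m + log(sum(exp(c - m)))
  lse - c[y]
}

#' Squared distance between L2-normalized fingerprints
#'
#' `d2 = || fp1 / (||fp1|| + eps) - fp2 / (||fp2|| + eps) ||^2`, which lies in
#' `[0, 4]` (0 for identical directions, 2 for orthogonal, 4 for antipodal)
#' up to epsilon effects.
#'
#' @param fp1,fp2 Numeric fingerprint vectors of equal length.
#' @param epsilon Norm stabiliser (default `1e-6`).
#' @return The squared normalized Euclidean distance (scalar).
#' @export
fingerprint_distance <- function(fp1, fp2, epsilon = 1e-6) {
  fp1 <- as.numeric(fp1); fp2 <- as.numeric(fp2)
  if (length(fp1) != length(fp2)) invalid_arg("fingerprints must have equal length")
  u <- fp1 / (sqrt(sum(fp1^2)) + epsilon)
  v <- fp2 / (sqrt(sum(fp2^2)) + epsilon)
  sum((u - v)^2)
}

#' Composite style-invariance loss for a same-core image pair
#'
#' @param out1,out2 Network outputs for the two styled renderings of one core:
#'   lists with elements `logits` (classification vector) and `fingerprint`.
#' @param y Shared identity label (core index).
#' @param config A [loss_config].
#' @return Scalar loss `CE(c1, y) + CE(c2, y) + gamma * d2_FP(fp1, fp2)`.
#' @export
composite_loss <- function(out1, out2, y, config = loss_config()) {
  cross_entropy(out1$logits, y) + cross_entropy(out2$logits, y) +
    config$gamma * fingerprint_distance(out1$fingerprint, out2$fingerprint,
                                        config$epsilon)
}

# --- gradients (internal, used by the trainer) -----------------------------

softmax_cols <- function(z) {
  apply(z, 2, function(col) { col <- col - max(col); e <- exp(col); e / sum(e) })
}

# d/dlogits of mean-over-batch CE: (softmax - onehot) / B. Returns loss too.
ce_grad <- function(logits, y) {
  B <- ncol(logits)
  p <- softmax_cols(logits)
  if (!is.matrix(p)) p <- matrix(p, ncol = B)
  li <- cbind(y, seq_len(B))
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-300)))
  d <- p
  d[li] <- d[li] - 1
  list(loss = loss, dlogits = d / B)
}

# Gradient of d2_FP wrt both raw fingerprints (columnwise over a batch).
# Returns per-pair distances and gradient matrices of the batch MEAN distance.
fpdist_grad <- function(f1, f2, epsilon) {
  B <- ncol(f1)
  n1 <- sqrt(colSums(f1^2)); n2 <- sqrt(colSums(f2^2))
  u <- sweep(f1, 2, n1 + epsilon, "/")
  v <- sweep(f2, 2, n2 + epsilon, "/")
  diff <- u - v
  d2 <- colSums(diff^2)
  # du/df = I/(n+eps) - f f^T / (n (n+eps)^2); applied to 2*diff
  g1 <- sweep(2 * diff, 2, n1 + epsilon, "/") -
    sweep(f1, 2, 2 * colSums(diff * f1) / (pmax(n1, 1e-12) * (n1 + epsilon)^2), "*")
  g2 <- sweep(-2 * diff, 2, n2 + epsilon, "/") -
    sweep(f2, 2, -2 * colSums(diff * f2) / (pmax(n2, 1e-12) * (n2 + epsilon)^2), "*")
  list(d2 = d2, df1 = g1 / B, df2 = g2 / B)
}
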