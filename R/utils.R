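# Internal helpers: seeded substreams, value clipping, small assertions.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm fft quantile rbinom plogis setNames aggregate
#' @importFrom utils head write.csv read.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps every stochastic entry point independently
# reproducible without clobbering user RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a substream seed from a base seed plus integer tags. Mixing uses
# MINSTD-style multipliers small enough that every intermediate product is an
# exact double (< 2^53); result lies in [0, 2^31 - 2], a valid set.seed()
# argument on 32-bit R integers.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 17
  for (t in tags) {
    h <- (h * 48271 + as.numeric(t) + 11) %% 2147483647
    h <- (h * 16807 + 1) %% 2147483647
  }
  as.integer(h %% 2147483646)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stop_if_not <- function(cond, msg, class = "tissuefp_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

invalid_arg <- function(msg) stop_if_not(FALSE, msg, class = "tissuefp_invalid_argument")

# Luminance (Rec. 601) of an [H, W, 3] array.
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Replicate a matrix into an [H, W, 3] gray RGB array.
gray_to_rgb <- function(m) {
  array(rep(m, 3L), dim = c(dim(m), 3L))
}

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
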