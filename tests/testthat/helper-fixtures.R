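# Shared fixtures, built once per test run and memoised. Cores are kept at
# the smallest geometry at which a 224-px patch still fits in a half
# (448 px -> 448 x 224 halves), which keeps rendering cheap.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

small_cohort <- function() memo("small_cohort",
                                make_cohort(4, 2, core_px = 448, seed = 11))

tiny_model <- function(n_identities = 8, D = 32)
  memo(paste0("m", n_identities, "_", D),
       fp_model(n_identities, "tiny", fingerprint_dim = D, seed = 5))

png_to_rgb_fixture <- function(path) tissuefp:::png_to_array(png::readPNG(path))

# A flat random patch batch
rand_patch <- function(seed = 1) {
  set.seed(seed)
  array(runif(224 * 224 * 3), c(224, 224, 3))
}

# Gaussian-feature bags for head/CV tests: class +1 bags have mean mu along
# the first feature, class -1 bags -mu; no imaging involved.
gaussian_bags <- function(n_patients, k = 20, D = 16, mu = 1.5, noise = 1,
                          seed = 1) {
  set.seed(seed)
  labels <- rep(c(1, -1), length.out = n_patients)
  bags <- lapply(seq_len(n_patients), function(i) {
    F <- matrix(rnorm(k * D, sd = noise), k, D)
    F[, 1] <- F[, 1] + labels[i] * mu
    structure(list(patient_id = i, fingerprints = F,
                   tissue_class = rep(NA_integer_, k),
                   sources = NULL),
              class = "patch_bag")
  })
  names(bags) <- seq_len(n_patients)
  list(bags = bags, labels = labels)
}
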