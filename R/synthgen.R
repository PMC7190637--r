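# Synthetic H&E-like cohort generator. Each patient has a latent phenotype
# (gland fraction, nuclear density and radius, stromal texture wavelength and
# anisotropy); each of their cores is an independent render from that
# phenotype, so cores of one patient share texture statistics but not pixels.
# Morphology is a two-channel raster (nuclear, cytoplasm) in [0, 1]; color is
# applied separately by a parametric "site style", so the same morphology can
# be rendered in several staining styles -- the synthetic stand-in for
# restained/restyled serial sections.

#' Site style parameters
#'
#' @param style_id Token naming the style.
#' @param hematoxylin,eosin,background RGB triplets in `[0, 1]` for the
#'   nuclear stain, cytoplasm stain and glass background.
#' @param gamma Display gamma in `[0.5, 2]`.
#' @param hue_jitter_deg Random hue rotation amplitude (degrees; 0 = none).
#' @param brightness Additive brightness offset.
#' @return A list of class `style_params`.
#' @export
style_params <- function(style_id, hematoxylin, eosin, background,
                         gamma = 1, hue_jitter_deg = 0, brightness = 0) {
  ok_rgb <- function(v) length(v) == 3 && all(v >= 0) && all(v <= 1)
  if (!ok_rgb(hematoxylin) || !ok_rgb(eosin) || !ok_rgb(background)) {
    invalid_arg("stain colors must be RGB triplets in [0, 1]")
  }
  if (gamma < 0.5 || gamma > 2) invalid_arg("gamma must lie in [0.5, 2]")
  structure(list(style_id = style_id, hematoxylin = hematoxylin, eosin = eosin,
                 background = background, gamma = gamma,
                 hue_jitter_deg = hue_jitter_deg, brightness = brightness),
            class = "style_params")
}

#' The two built-in site styles
#'
#' `siteA` mimics a bright, neutral scanner profile; `siteB` a warmer, darker
#' one (different stain colors, background, gamma and brightness). Their mean
#' RGB renderings of the same morphology differ by well over 10 gray levels,
#' which is what the style-invariance machinery has to overcome.
#'
#' @return Named list of [style_params].
#' @export
builtin_styles <- function() {
  list(
    siteA = style_params("siteA",
                         hematoxylin = c(0.32, 0.22, 0.58),
                         eosin = c(0.90, 0.60, 0.75),
                         background = c(0.96, 0.95, 0.97),
                         gamma = 1.0, brightness = 0),
    siteB = style_params("siteB",
                         hematoxylin = c(0.18, 0.28, 0.48),
                         eosin = c(0.82, 0.66, 0.58),
                         background = c(0.91, 0.87, 0.84),
                         gamma = 1.3, brightness = -0.03)
  )
}

#' Cohort generator configuration
#'
#' @param marker_k Logistic coupling strength between gland fraction and the
#'   marker label: `P(m = +1 | g) = plogis(marker_k * (g - 0.5))`. The default
#'   16 leaves ~10% intrinsic label noise relative to the threshold rule.
#' @param nuclei_gland_frac Fraction of nuclei seeded inside glands.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(marker_k = 16, nuclei_gland_frac = 0.7) {
  structure(list(marker_k = marker_k, nuclei_gland_frac = nuclei_gland_frac),
            class = "cohort_config")
}

# Patient phenotypes: one row per patient, all parameters from the patient's
# RNG substream so the draw is independent of cohort size ordering.
sample_phenotypes <- function(n_patients, seed, config) {
  rows <- lapply(seq_len(n_patients), function(pid) {
    with_seed(derive_seed(seed, 3L, pid), {
      g <- runif(1, 0.05, 0.95)
      d <- runif(1, 0.3, 0.9)
      r <- runif(1, 3, 7)
      w <- runif(1, 8, 32)
      a <- runif(1)
      u <- runif(1)
      m <- if (plogis(config$marker_k * (g - 0.5)) > u) 1L else -1L
      data.frame(patient_id = pid, gland_fraction = g, nuclear_density = d,
                 nucleus_radius = r, stroma_wavelength = w, anisotropy = a,
                 marker = m)
    })
  })
  do.call(rbind, rows)
}

# Gaussian random field of size n x n via FFT filtering of white noise;
# `scale` is the correlation length in pixels. Returned standardized.
smooth_field <- function(n, scale) {
  w <- matrix(rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n      # cycles per pixel
  H <- exp(-0.5 * (outer(f^2, f^2, "+")) * (scale * pi)^2)
  x <- Re(fft(fft(w) * H, inverse = TRUE)) / (n * n)
  (x - mean(x)) / (stats::sd(x) + 1e-12)
}

# Oriented band-pass texture: energy concentrated on the frequency annulus at
# wavelength `w` px; `aniso` in [0,1] interpolates isotropic -> strongly
# oriented at angle `theta0`.
bandpass_texture <- function(n, wavelength, aniso, theta0) {
  z <- matrix(rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n)
  rho <- sqrt(fx^2 + fy^2)
  rho0 <- 1 / wavelength
  radial <- exp(-0.5 * ((rho - rho0) / (rho0 / 3 + 1e-9))^2)
  theta <- atan2(fy, fx)
  kappa <- 8 * aniso
  angular <- exp(kappa * (cos(2 * (theta - theta0)) - 1))
  x <- Re(fft(fft(z) * radial * angular, inverse = TRUE)) / (n * n)
  x <- (x - mean(x)) / (stats::sd(x) + 1e-12)
  clip01(0.5 + 0.25 * x)
}

# Stamp soft elliptical nuclei into a channel matrix (in place semantics via
# return). positions: matrix [n, 2] of (row, col) centers.
stamp_nuclei <- function(ch, positions, radius) {
  n <- nrow(positions)
  if (n == 0L) return(ch)
  H <- nrow(ch); W <- ncol(ch)
  a_all <- radius * runif(n, 0.75, 1.25)
  b_all <- a_all * runif(n, 0.5, 0.85)
  phi_all <- runif(n, 0, pi)
  int_all <- runif(n, 0.7, 0.95)
  for (i in seq_len(n)) {
    a <- a_all[i]; b <- b_all[i]; phi <- phi_all[i]
    e <- ceiling(a) + 1L
    r0 <- positions[i, 1]; c0 <- positions[i, 2]
    rs <- max(1L, r0 - e):min(H, r0 + e)
    cs <- max(1L, c0 - e):min(W, c0 + e)
    dy <- rs - r0
    dx <- cs - c0
    xr <- outer(dy, dx, function(y, x)  x * cos(phi) + y * sin(phi))
    yr <- outer(dy, dx, function(y, x) -x * sin(phi) + y * cos(phi))
    q <- (xr / a)^2 + (yr / b)^2
    m <- pmax(0, 1 - q)
    patch <- int_all[i] * sqrt(m)
    ch[rs, cs] <- pmax(ch[rs, cs], patch)
  }
  ch
}

# Render one core's morphology (nuclear + cytoplasm channels) from a patient
# phenotype. All randomness comes from the current RNG stream.
render_core_morphology <- function(phen, core_px, config) {
  n <- core_px
  gland_field <- smooth_field(n, n / 8)
  thr <- quantile(gland_field, 1 - phen$gland_fraction)
  gland <- gland_field > thr
  theta0 <- runif(1, 0, pi)
  stroma <- bandpass_texture(n, phen$stroma_wavelength, phen$anisotropy, theta0)
  cyt <- matrix(0, n, n)
  gland_tone <- clip01(0.5 + 0.12 * smooth_field(n, 8))
  cyt[gland] <- gland_tone[gland]
  cyt[!gland] <- 0.2 + 0.5 * stroma[!gland]
  n_nuclei <- round(phen$nuclear_density * n * n / 100)
  n_in <- round(config$nuclei_gland_frac * n_nuclei)
  gi <- which(gland)
  si <- which(!gland)
  pick <- function(pool, k) {
    if (length(pool) == 0L || k == 0L) return(integer(0))
    pool[sample.int(length(pool), k, replace = length(pool) < k)]
  }
  sel <- c(pick(gi, n_in), pick(si, n_nuclei - n_in))
  pos <- cbind((sel - 1L) %% n + 1L, (sel - 1L) %/% n + 1L)
  nuc <- stamp_nuclei(matrix(0, n, n), pos, phen$nucleus_radius)
  cyt <- pmin(cyt, 1 - nuc)   # keep the linear stain composition in range
  list(nuclear = nuc, cytoplasm = cyt, gland = gland)
}

#' Generate a synthetic multi-core TMA cohort
#'
#' Draws one phenotype per patient and renders `cores_per_patient` independent
#' morphology rasters from each, mirroring a tissue microarray in which every
#' patient contributes one or more ~1 mm cores. Marker labels are coupled to
#' the gland fraction through a logistic rule (see [cohort_config]). The
#' rasters are morphology only; color is applied per style with
#' [render_style] or [core_image].
#'
#' @param n_patients Number of patients (>= 2).
#' @param cores_per_patient Cores rendered per patient.
#' @param core_px Core raster side in pixels (>= 256) at a nominal 0.5 um/px.
#' @param seed Integer seed; the same call with the same seed is bit-identical.
#' @param config A [cohort_config].
#' @return An object of class `fp_cohort` with elements `phenotypes`
#'   (data frame), `cores` (list of `core_index`, `patient_id`, `morphology`),
#'   `styles`, `layout` (named vector core index -> patient id), `core_px`,
#'   `mpp` and `seed`.
#' @export
make_cohort <- function(n_patients, cores_per_patient = 2L, core_px = 512L,
                        seed = 1L, config = cohort_config()) {
  if (n_patients < 2) invalid_arg("n_patients must be >= 2")
  if (cores_per_patient < 1) invalid_arg("cores_per_patient must be >= 1")
  if (core_px < 256) invalid_arg("core_px must be >= 256")
  phen <- sample_phenotypes(n_patients, seed, config)
  n_cores <- n_patients * cores_per_patient
  layout <- rep(seq_len(n_patients), each = cores_per_patient)
  names(layout) <- seq_len(n_cores)
  cores <- lapply(seq_len(n_cores), function(ci) {
    pid <- layout[[ci]]
    morph <- with_seed(derive_seed(seed, 7L, ci),
                       render_core_morphology(phen[pid, ], core_px, config))
    list(core_index = ci, patient_id = pid,
         morphology = morph[c("nuclear", "cytoplasm")])
  })
  structure(list(phenotypes = phen, cores = cores, styles = builtin_styles(),
                 layout = layout, core_px = as.integer(core_px), mpp = 0.5,
                 seed = as.integer(seed), config = config),
            class = "fp_cohort")
}

#' @export
print.fp_cohort <- function(x, ...) {
  cat(sprintf("<fp_cohort> %d patients, %d cores (%d px at %.1f um/px), styles: %s\n",
              nrow(x$phenotypes), length(x$cores), x$core_px, x$mpp,
              paste(names(x$styles), collapse = ", ")))
  invisible(x)
}

#' Render a morphology raster in a site style
#'
#' Composites the two morphology channels with the style's stain colors:
#' `pixel = (1 - n - c) * background + n * hematoxylin + c * eosin`, followed
#' by gamma, brightness and (optional) hue jitter. Channel supports -- hence
#' morphology -- are unchanged; only color statistics differ between styles.
#'
#' @param morphology List with matrices `nuclear` and `cytoplasm` (same
#'   shape, values in `[0, 1]`).
#' @param style A [style_params].
#' @param seed Seed for the hue jitter draw (unused when `hue_jitter_deg = 0`).
#' @return An `[H, W, 3]` RGB array in `[0, 1]`.
#' @export
render_style <- function(morphology, style, seed = 1L) {
  nuc <- morphology$nuclear; cyt <- morphology$cytoplasm
  if (!is.matrix(nuc) || !is.matrix(cyt) || !all(dim(nuc) == dim(cyt))) {
    invalid_arg("morphology channels must be matrices of identical shape")
  }
  h <- nrow(nuc); w <- ncol(nuc)
  rgb <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    rgb[, , ch] <- (1 - nuc - cyt) * style$background[ch] +
      nuc * style$hematoxylin[ch] + cyt * style$eosin[ch]
  }
  # the convex composition already lies in [0, 1]; clipping is only needed
  # after a brightness shift
  if (style$gamma != 1) rgb <- rgb^style$gamma
  if (style$brightness != 0) rgb <- clip01(rgb + style$brightness)
  if (style$hue_jitter_deg != 0) {
    deg <- with_seed(derive_seed(seed, 11L),
                     runif(1, -style$hue_jitter_deg, style$hue_jitter_deg))
    rgb <- rotate_hue(rgb, deg)
  }
  rgb
}

# Rotate hue of an RGB array by `deg` degrees (through HSV).
rotate_hue <- function(rgb, deg) {
  d <- dim(rgb)
  m <- matrix(aperm(rgb, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + deg / 360) %% 1
  col <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
  out <- grDevices::col2rgb(col) / 255
  aperm(array(out, c(3, d[1], d[2])), c(2, 3, 1))
}

#' Styled image of one cohort core
#'
#' @param cohort An [make_cohort] result.
#' @param core_index Core to render.
#' @param style Style token (must exist in `cohort$styles`) or a
#'   [style_params].
#' @param seed Seed passed to [render_style].
#' @return A `core_image` object: list with `pixels` (`[H, W, 3]`),
#'   `core_index`, `patient_id`, `style_id`, `mpp`, `prepared`.
#' @export
core_image <- function(cohort, core_index, style = "siteA", seed = 1L) {
  stopifnot(inherits(cohort, "fp_cohort"))
  core <- cohort$cores[[core_index]]
  if (is.character(style)) {
    if (is.null(cohort$styles[[style]])) {
      stop_if_not(FALSE, paste0("unknown style: ", style), "tissuefp_config_error")
    }
    style <- cohort$styles[[style]]
  }
  px <- render_style(core$morphology, style, seed = derive_seed(seed, core$core_index))
  structure(list(pixels = px, core_index = core$core_index,
                 patient_id = core$patient_id, style_id = style$style_id,
                 mpp = cohort$mpp, prepared = TRUE),
            class = "core_image")
}
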