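# Whole-slide-like mosaics: per patient, one flat raster composed of
# epithelium (rendered from the patient's phenotype -- this is the only
# compartment that carries patient/marker signal), generic stroma, fat
# vacuoles and glass background, plus a tissue-type label map
# {0 background, 1 epithelium, 2 stroma, 3 fat} and patient-level marker
# labels. Slides are rendered lazily (render_slide) so large cohorts never
# hold all pixels at once.

#' Generate a synthetic whole-slide cohort
#'
#' Phenotypes and the marker coupling are shared with [make_cohort]; `ER` and
#' `PR` couple to the gland fraction, `Her2` to the nuclear density. The
#' epithelial compartment is rendered with the same gland-blob recipe as the
#' cores (gland fraction g of the epithelial area), so only epithelial
#' patches are informative about ER/PR status -- stroma and fat are rendered
#' with patient-independent parameters.
#'
#' @param n_patients Number of patients.
#' @param slide_px Slide side in pixels (>= 1024) at 0.5 um/px.
#' @param seed Integer seed.
#' @param config A [cohort_config].
#' @return An `fp_wsi_cohort`: `phenotypes`, `labels` (data frame with
#'   `patient_id`, `ER`, `PR`, `Her2` in {1, -1}), `slide_px`, `mpp`, `seed`.
#'   Pixels are produced on demand by [render_slide].
#' @export
make_wsi_cohort <- function(n_patients, slide_px = 1536L, seed = 1L,
                            config = cohort_config()) {
  if (n_patients < 1) invalid_arg("n_patients must be >= 1")
  if (slide_px < 1024) invalid_arg("slide_px must be >= 1024")
  phen <- sample_phenotypes(n_patients, seed, config)
  k <- config$marker_k
  labels <- do.call(rbind, lapply(seq_len(n_patients), function(pid) {
    p <- phen[pid, ]
    with_seed(derive_seed(seed, 13L, pid), {
      u <- runif(3)
      er <- if (plogis(k * (p$gland_fraction - 0.5)) > u[1]) 1L else -1L
      pr <- if (plogis(k * (p$gland_fraction - 0.5)) > u[2]) 1L else -1L
      # map d in [0.3, 0.9] onto the same +-0.45 logistic scale as g
      her2 <- if (plogis(k * 1.5 * (p$nuclear_density - 0.6)) > u[3]) 1L else -1L
      data.frame(patient_id = pid, ER = er, PR = pr, Her2 = her2)
    })
  }))
  structure(list(phenotypes = phen, labels = labels,
                 slide_px = as.integer(slide_px), mpp = 0.5,
                 seed = as.integer(seed), config = config),
            class = "fp_wsi_cohort")
}

#' @export
print.fp_wsi_cohort <- function(x, ...) {
  cat(sprintf("<fp_wsi_cohort> %d patients, %d px slides @ %.1f um/px, markers: ER PR Her2\n",
              nrow(x$phenotypes), x$slide_px, x$mpp))
  invisible(x)
}

#' Render one slide of a whole-slide cohort
#'
#' @param cohort An [make_wsi_cohort] result.
#' @param patient_id Patient to render.
#' @param style Style token in [builtin_styles] (default `"siteA"`).
#' @return List with `slide_id`, `patient_id`, `pixels` (`[S, S, 3]`), `mask`
#'   (`[S, S]` integer label map), `mpp`, `epithelium_fraction`.
#' @export
render_slide <- function(cohort, patient_id, style = "siteA") {
  stopifnot(inherits(cohort, "fp_wsi_cohort"))
  phen <- cohort$phenotypes[patient_id, ]
  sty <- builtin_styles()[[style]]
  stop_if_not(!is.null(sty), paste0("unknown style: ", style), "tissuefp_config_error")
  with_seed(derive_seed(cohort$seed, 17L, patient_id), {
    n <- cohort$slide_px
    # random fields are generated at half resolution and upsampled: every
    # field here has a correlation length of several pixels or more, so the
    # half-grid realisation is statistically equivalent at a quarter of the
    # FFT cost
    half_field <- function(scale) {
      f <- smooth_field(n %/% 2L, scale / 2)
      f <- resize_bilinear(f, n, n)
      (f - mean(f)) / (stats::sd(f) + 1e-12)
    }
    # tissue blob: smooth field plus a radial bias so background hugs edges
    fld <- half_field(n / 5)
    cx <- (seq_len(n) - (n + 1) / 2) / (n / 2)
    rad <- sqrt(outer(cx^2, cx^2, "+"))
    score <- fld - 2.2 * pmax(rad - 0.75, 0) * 4
    tissue <- score > quantile(score, 0.15)           # ~85% tissue
    # epithelium: target fraction of the WHOLE slide in [0.25, 0.5]
    f_epi <- runif(1, 0.25, 0.5)
    efld <- half_field(n / 7)
    efld[!tissue] <- -Inf
    k_needed <- round(f_epi * n * n)
    thr <- sort(efld[tissue], decreasing = TRUE)[min(k_needed, sum(tissue))]
    epi <- efld >= thr
    # fat: a few large adipose lobules (big enough that whole 224-px tiles
    # are fat-majority), rendered later as pale vacuoles with a stained web
    fat <- matrix(FALSE, n, n)
    n_lob <- max(3L, round(n / 300))
    cand <- which(tissue & !epi)
    if (length(cand) > 0) {
      centers <- cand[sample.int(length(cand), min(n_lob, length(cand)))]
      rr <- (centers - 1L) %% n + 1L
      cc <- (centers - 1L) %/% n + 1L
      radii <- runif(length(centers), 0.12 * n, 0.18 * n)
      for (i in seq_along(centers)) {
        e <- ceiling(radii[i])
        rs <- max(1L, rr[i] - e):min(n, rr[i] + e)
        cs <- max(1L, cc[i] - e):min(n, cc[i] + e)
        disc <- outer((rs - rr[i])^2, (cs - cc[i])^2, "+") <= radii[i]^2
        blk <- fat[rs, cs]
        blk[disc] <- TRUE
        fat[rs, cs] <- blk
      }
      fat <- fat & tissue & !epi
    }
    stroma <- tissue & !epi & !fat
    mask <- matrix(0L, n, n)
    mask[epi] <- 1L; mask[stroma] <- 2L; mask[fat] <- 3L

    nuc <- matrix(0, n, n)
    cyt <- matrix(0, n, n)
    # epithelium: rendered with the SAME recipe as the patient's TMA cores
    # -- gland blobs occupying fraction g of the epithelial area (eosin-rich
    # tone, nuclei-dense) in a lightly-stained epithelial matrix -- so the
    # phenotype expresses identically in cores and slides and core-trained
    # fingerprints transfer
    gl_fld <- half_field(48)
    ne <- sum(epi)
    if (ne > 0) {
      gq <- quantile(gl_fld[epi], 1 - phen$gland_fraction)
      gland <- epi & (gl_fld > gq)
      mtx <- epi & !gland
      gland_tone <- clip01(0.55 + 0.12 * half_field(8))
      cyt[gland] <- gland_tone[gland]
      cyt[mtx] <- 0.16
      n_nuc <- round(phen$nuclear_density * ne / 100)
      n_in <- round(cohort$config$nuclei_gland_frac * n_nuc)
      pick <- function(pool, k) {
        if (length(pool) == 0L || k <= 0L) return(integer(0))
        pool[sample.int(length(pool), min(k, length(pool)))]
      }
      sel <- c(pick(which(gland), n_in), pick(which(mtx), n_nuc - n_in))
      if (length(sel) > 0) {
        pos <- cbind((sel - 1L) %% n + 1L, (sel - 1L) %/% n + 1L)
        nuc <- stamp_nuclei(nuc, pos, phen$nucleus_radius)
      }
    }
    # stroma: wavy collagen whose texture parameters vary from slide to
    # slide but are drawn independently of the marker-linked phenotype --
    # non-epithelial tissue is uninformative yet not constant, so averaging
    # it into a patient score dilutes the epithelial signal (as in real
    # slides) without ever carrying label information
    if (any(stroma)) {
      st <- bandpass_texture(n %/% 2L, runif(1, 6, 11), runif(1, 0.15, 0.5),
                             runif(1, 0, pi))
      st <- clip01(resize_bilinear(st, n, n))
      cyt[stroma] <- runif(1, 0.17, 0.26) + runif(1, 0.38, 0.5) * st[stroma]
      n_snuc <- round(runif(1, 0.04, 0.09) * sum(stroma) / 100)
      pool <- which(stroma)
      if (n_snuc > 0) {
        sel <- pool[sample.int(length(pool), min(n_snuc, length(pool)))]
        pos <- cbind((sel - 1L) %% n + 1L, (sel - 1L) %/% n + 1L)
        nuc <- stamp_nuclei(nuc, pos, 4)
      }
    }
    # fat: pale vacuoles separated by a stained interstitial web (the web
    # keeps adipose tiles above the foreground threshold)
    if (any(fat)) {
      webf <- half_field(9)
      web <- abs(webf) < quantile(abs(webf), 0.4)
      cyt[fat] <- 0.10
      cyt[fat & web] <- 0.55
    }
    nuc[!tissue] <- 0
    cyt[!tissue] <- 0
    cyt <- pmin(cyt, 1 - nuc)
    px <- render_style(list(nuclear = nuc, cytoplasm = cyt), sty,
                       seed = derive_seed(cohort$seed, 19L, patient_id))
    list(slide_id = patient_id, patient_id = patient_id, pixels = px,
         mask = mask, mpp = cohort$mpp,
         epithelium_fraction = mean(epi))
  })
}

#' Write a whole-slide cohort to disk
#'
#' Renders every slide and writes `slide_<id>.png`, `mask_<id>.png`
#' (labels scaled to {0, 85, 170, 255} gray), `labels.csv`
#' (`patient_id, ER, PR, Her2`) and `manifest.json` (slide px, um/px, seed).
#'
#' @param cohort An [make_wsi_cohort] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_wsi_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in cohort$labels$patient_id) {
    s <- render_slide(cohort, pid)
    png::writePNG(s$pixels, file.path(dir, sprintf("slide_%04d.png", pid)))
    png::writePNG(s$mask / 3, file.path(dir, sprintf("mask_%04d.png", pid)))
  }
  write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(n_patients = nrow(cohort$labels), slide_px = cohort$slide_px,
                   mpp = cohort$mpp, seed = cohort$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
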