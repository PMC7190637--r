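# Disk interchange. Cohorts round-trip as PNG rasters plus a JSON manifest
# (file -> core_index, patient_id, style_id, microns per pixel), the labels
# as CSV; fingerprints as TSV with a sources CSV. Everything is plain text
# or PNG so fixtures stay portable.

#' Write a TMA cohort's styled renderings and manifest
#'
#' Renders every core in the requested styles and writes
#' `core_<index>_<style>.png`, a `manifest.json` (one record per file with
#' `file`, `core_index`, `patient_id`, `style_id`, `mpp`), a `layout.json`
#' and `labels.csv` (patient_id, marker).
#'
#' @param cohort An [make_cohort] result.
#' @param dir Output directory.
#' @param styles Style tokens to render (default all built in).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort_images <- function(cohort, dir, styles = names(cohort$styles)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ci in seq_along(cohort$cores)) {
    for (s in styles) {
      img <- core_image(cohort, ci, s)
      fn <- sprintf("core_%04d_%s.png", ci, s)
      png::writePNG(img$pixels, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        file = fn, core_index = ci, patient_id = img$patient_id,
        style_id = s, mpp = cohort$mpp)
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows")
  jsonlite::write_json(as.list(cohort$layout), file.path(dir, "layout.json"),
                       auto_unbox = TRUE)
  write.csv(cohort$phenotypes[, c("patient_id", "marker")],
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a core image listed in a cohort manifest
#'
#' @param dir Directory written by [write_cohort_images] (or arranged
#'   identically for external data).
#' @param core_index,style_id Which record to read.
#' @param prepare Run [prepare_core] (rescale/crop to the working geometry)?
#'   Default `FALSE`: returns the raster at its stored size.
#' @param target_px Passed to [prepare_core] when `prepare = TRUE`.
#' @return A `core_image`.
#' @export
read_core_image <- function(dir, core_index, style_id, prepare = FALSE,
                            target_px = 1600L) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  row <- manifest[manifest$core_index == core_index &
                    manifest$style_id == style_id, , drop = FALSE]
  stop_if_not(nrow(row) == 1L,
              sprintf("no manifest record for core %s style %s", core_index, style_id),
              "tissuefp_data_error")
  px <- png_to_array(png::readPNG(file.path(dir, row$file)))
  if (prepare) {
    return(prepare_core(px, mpp_in = row$mpp, target_px = target_px,
                        core_index = row$core_index,
                        patient_id = row$patient_id, style_id = row$style_id))
  }
  structure(list(pixels = px, core_index = row$core_index,
                 patient_id = row$patient_id, style_id = row$style_id,
                 mpp = row$mpp, prepared = TRUE),
            class = "core_image")
}

#' Write a fingerprint matrix with its source table
#'
#' @param fp Result of [extract_fingerprints].
#' @param path Path prefix; writes `<path>.tsv` (matrix) and
#'   `<path>_sources.csv`.
#' @return Invisibly, the TSV path.
#' @export
write_fingerprints <- function(fp, path) {
  utils::write.table(fp$fingerprints, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  write.csv(fp$sources, paste0(path, "_sources.csv"), row.names = FALSE)
  invisible(paste0(path, ".tsv"))
}
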