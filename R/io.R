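## Plain-file export: NIfTI images (float32) with JSON sidecars.

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

nifti_write <- function(mat, path, pixdim_mm) {
  img <- RNifti::asNifti(array(mat, dim = c(dim(mat), 1L)),
                         pixdim = c(pixdim_mm, pixdim_mm, 1),
                         datatype = "float")
  RNifti::writeNifti(img, path)
}

#' Save a phantom's ground-truth maps as NIfTI plus a JSON sidecar
#'
#' Writes `S0_map.nii.gz`, `ADC_map.nii.gz`, `label_map.nii.gz` (float32)
#' and `phantom.json` (units, pixel size, seed, lesion registry) into `dir`.
#'
#' @param truth a `phantom_truth`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
save_phantom <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- truth$spec$pixel_size_mm
  nifti_write(truth$S0_map, file.path(dir, "S0_map.nii.gz"), px)
  nifti_write(truth$ADC_map, file.path(dir, "ADC_map.nii.gz"), px)
  nifti_write(truth$label_map, file.path(dir, "label_map.nii.gz"), px)
  sidecar <- list(
    units = list(S0 = "arbitrary", ADC = "1e-3 mm^2/s", pixel_size = "mm"),
    grid_size = truth$spec$grid_size,
    pixel_size_mm = px,
    seed = truth$spec$seed,
    label_codes = list(background = 0, parenchyma = 1, vessel = 2,
                       lesion_base = 2),
    lesion_registry = lapply(truth$lesion_registry, function(l) {
      list(center = l$center, diameter_mm = l$diameter_mm,
           S0_contrast = l$S0_contrast, lesion_ADC = l$lesion_ADC)
    })
  )
  write_json_sidecar(sidecar, file.path(dir, "phantom.json"))
  invisible(dir)
}

#' Save a multi-b-value series as one NIfTI per b-value plus a sidecar
#'
#' @param series a `bvalue_series` (magnitudes are written) or
#'   `recon_series`
#' @param dir output directory
#' @param pixel_size_mm pixel size for the NIfTI header
#' @return `dir`, invisibly
#' @export
save_series <- function(series, dir, pixel_size_mm = 2.38) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mags <- if (inherits(series, "recon_series")) series$magnitude
          else abs(series$images)
  for (bi in seq_along(series$b_values)) {
    nifti_write(mags[, , bi],
                file.path(dir, sprintf("b%04d.nii.gz", series$b_values[bi])),
                pixel_size_mm)
  }
  sidecar <- list(b_values = series$b_values,
                  units = list(b = "s/mm^2", signal = "arbitrary"))
  if (inherits(series, "recon_series")) sidecar$provenance <- series$provenance
  write_json_sidecar(sidecar, file.path(dir, "series.json"))
  invisible(dir)
}

#' Save a reconstructed image as NIfTI with its provenance JSON
#'
#' @param recon a `recon_image`
#' @param path output NIfTI path (`.nii.gz`); provenance goes to
#'   `<path>.json`
#' @param pixel_size_mm pixel size for the header
#' @return `path`, invisibly
#' @export
save_recon <- function(recon, path, pixel_size_mm = 2.38) {
  stopifnot(inherits(recon, "recon_image"))
  nifti_write(recon$magnitude, path, pixel_size_mm)
  write_json_sidecar(recon$provenance, paste0(path, ".json"))
  invisible(path)
}
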