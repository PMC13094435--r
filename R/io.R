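# Volume and manifest I/O. Snapshots are stored as one NIfTI stopping-power
# volume plus one NIfTI label volume per snapshot; because structures may
# legitimately overlap (CTV_pri is inside CTV_pro, OARs may overlap the
# prophylactic target), the label volume is a bit mask: bit i set means
# voxel belongs to structure i of the order recorded in the JSON sidecar.

.mask_order <- function(masks) names(masks)

#' Write a phantom snapshot to NIfTI files
#'
#' Creates `<prefix>_spr.nii.gz`, `<prefix>_labels.nii.gz` and
#' `<prefix>_meta.json` (spacing, origin, week, structure bit order).
#'
#' @param snapshot a `phantom_snapshot`.
#' @param prefix file path prefix.
#' @return invisibly, the three file paths.
#' @export
write_snapshot <- function(snapshot, prefix) {
  spr_file <- paste0(prefix, "_spr.nii.gz")
  lab_file <- paste0(prefix, "_labels.nii.gz")
  meta_file <- paste0(prefix, "_meta.json")
  RNifti::writeNifti(RNifti::asNifti(snapshot$spr_grid,
                                     pixdim = snapshot$spacing), spr_file)
  order <- .mask_order(snapshot$masks)
  lab <- array(0, dim(snapshot$spr_grid))
  for (i in seq_along(order)) {
    lab <- lab + snapshot$masks[[order[i]]] * 2^(i - 1)
  }
  RNifti::writeNifti(RNifti::asNifti(lab, pixdim = snapshot$spacing),
                     lab_file)
  jsonlite::write_json(
    list(spacing = snapshot$spacing, origin = snapshot$origin,
         timepoint_week = snapshot$timepoint_week, structures = order),
    meta_file, auto_unbox = TRUE, digits = NA
  )
  invisible(c(spr_file, lab_file, meta_file))
}

#' Read a phantom snapshot written by [write_snapshot()]
#'
#' @param prefix file path prefix used at write time.
#' @return a `phantom_snapshot` (without the generator geometry record).
#' @export
read_snapshot <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"))
  spr <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_spr.nii.gz"))),
               dim = dim(RNifti::readNifti(paste0(prefix, "_spr.nii.gz"))))
  lab <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  lab <- array(as.numeric(lab), dim = dim(lab))
  masks <- list()
  for (i in seq_along(meta$structures)) {
    masks[[meta$structures[i]]] <- (lab %/% 2^(i - 1)) %% 2 == 1
  }
  structure(
    list(spr_grid = spr, masks = masks, spacing = as.numeric(meta$spacing),
         origin = as.numeric(meta$origin),
         timepoint_week = as.integer(meta$timepoint_week)),
    class = "phantom_snapshot"
  )
}

#' Write a dose grid as NIfTI
#' @param dose 3-D dose array.
#' @param spacing voxel spacing in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_dose <- function(dose, spacing, path) {
  RNifti::writeNifti(RNifti::asNifti(dose, pixdim = spacing), path)
  invisible(path)
}

#' Write a cohort to disk (volumes plus JSON manifest)
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(p) {
    paths <- vapply(seq_along(p$snapshots), function(k) {
      prefix <- file.path(dir, sprintf("pat%03d_wk%02d", p$id,
                                       p$snapshots[[k]]$timepoint_week))
      write_snapshot(p$snapshots[[k]], prefix)
      prefix
    }, character(1))
    list(id = p$id, seed = p$seed, drift_rate = p$drift_rate,
         factors = p$factors, snapshot_prefixes = paths,
         fraction_days = p$schedule$fraction_days,
         rct_days = p$schedule$rct_days, pattern = p$schedule$pattern)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
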