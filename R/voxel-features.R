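# Voxel-domain feature extraction on pre-registered label volumes:
# superficial-white-matter mean diffusivity under the 5-mm boundary rule,
# gray-matter ROI volume, and resection-overlap fractions.
#
# Grids are dense 3-D arrays on a common space; no resampling or
# registration is performed here. Distance searches are exact
# (vectorized brute force over GM voxels), intended for the desk-scale
# grids this package analyses.

#' Construct a label volume
#'
#' @param labels integer 3-D array of ROI labels (0 = background).
#' @param voxel_mm numeric length-3: voxel size in mm per axis.
#' @param label_table optional data.frame `label`, `roi_id`; by default
#'   labels map to themselves.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, voxel_mm = c(1, 1, 1), label_table = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) stop_shape("labels must be a 3-D array")
  if (any(voxel_mm <= 0)) stop_config("voxel sizes must be positive")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  if (is.null(label_table)) {
    label_table <- data.frame(label = present,
                              roi_id = as.character(present),
                              stringsAsFactors = FALSE)
  }
  if (!all(present %in% label_table$label)) {
    stop_config("labels present in the volume are missing from label_table")
  }
  structure(list(labels = labels, voxel_mm = as.numeric(voxel_mm),
                 label_table = label_table),
            class = "label_volume")
}

#' Read a volume from a plain-text array + JSON sidecar
#'
#' The array is stored as whitespace-delimited values in Fortran order
#' with a JSON sidecar giving `dim` and `voxel_mm`; an imaging-free
#' interchange format for testing. NIfTI input is supported through
#' [RNifti::readNifti()] when that package is available.
#'
#' @param path path to the `.txt` array (sidecar at `paste0(path, ".json")`)
#'   or to a `.nii`/`.nii.gz` file.
#' @return list with `array` and `voxel_mm`.
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop_config("RNifti is required to read NIfTI volumes")
    }
    img <- RNifti::readNifti(path)
    return(list(array = as.array(img),
                voxel_mm = RNifti::pixdim(img)[1:3]))
  }
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  vals <- scan(path, quiet = TRUE)
  list(array = array(vals, dim = meta$dim), voxel_mm = meta$voxel_mm)
}

#' Write a volume as plain-text array + JSON sidecar
#' @param arr 3-D array.
#' @param voxel_mm voxel size (mm per axis).
#' @param path output path (`.txt`).
#' @export
write_volume <- function(arr, voxel_mm, path) {
  write(as.vector(arr), path, ncolumns = 8)
  jsonlite::write_json(list(dim = dim(arr), voxel_mm = voxel_mm),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

.voxel_coords_mm <- function(idx, dims, voxel_mm) {
  # idx: linear indices; returns n x 3 coordinates of voxel centers in mm
  i <- arrayInd(idx, dims)
  sweep(i - 1, 2, voxel_mm, `*`)
}

.check_grids <- function(a, b, what) {
  if (!identical(dim(a), dim(b))) {
    stop_shape(what, ": grids have different shapes (",
               paste(dim(a), collapse = "x"), " vs ",
               paste(dim(b), collapse = "x"), ")")
  }
}

#' Superficial-white-matter mean diffusivity per region
#'
#' For each parcellation region, averages the mean-diffusivity values of
#' white-matter voxels lying within `distance_mm` of that region's gray
#' matter. Each WM voxel contributes to the single region whose GM it is
#' nearest to (Euclidean distance between voxel centers, voxel-size
#' aware); voxels farther than `distance_mm` from all GM are dropped.
#' Regions with no qualifying WM voxels get a missing value.
#'
#' @param md_volume numeric 3-D array of mean diffusivity.
#' @param parcellation a [label_volume()] whose labels are GM regions.
#' @param wm_mask binary/logical 3-D array of white matter.
#' @param distance_mm inclusion radius (default 5 mm).
#' @return data.frame `roi_id`, `mean_md`, `n_voxels`.
#' @export
swm_mean_md <- function(md_volume, parcellation, wm_mask, distance_mm = 5) {
  stopifnot(inherits(parcellation, "label_volume"))
  if (distance_mm <= 0) stop_config("distance_mm must be positive")
  lab <- parcellation$labels
  .check_grids(md_volume, lab, "MD vs parcellation")
  .check_grids(wm_mask, lab, "WM mask vs parcellation")
  dims <- dim(lab); vx <- parcellation$voxel_mm

  gm_idx <- which(lab != 0)
  wm_idx <- which(wm_mask != 0)
  tbl <- parcellation$label_table
  out <- data.frame(roi_id = tbl$roi_id, mean_md = NA_real_,
                    n_voxels = 0L, stringsAsFactors = FALSE)
  if (!length(gm_idx) || !length(wm_idx)) return(out)

  gm_xyz <- .voxel_coords_mm(gm_idx, dims, vx)
  wm_xyz <- .voxel_coords_mm(wm_idx, dims, vx)
  gm_lab <- lab[gm_idx]

  # nearest GM voxel for every WM voxel, blocked to bound memory
  nearest_lab <- integer(length(wm_idx))
  nearest_d <- numeric(length(wm_idx))
  gm_sq <- rowSums(gm_xyz^2)
  block <- max(1L, floor(2e7 / length(gm_idx)))
  for (s in seq(1L, length(wm_idx), by = block)) {
    e <- min(s + block - 1L, length(wm_idx))
    w <- wm_xyz[s:e, , drop = FALSE]
    d2 <- outer(rowSums(w^2), gm_sq, `+`) - 2 * w %*% t(gm_xyz)
    j <- max.col(-d2, ties.method = "first")
    nearest_lab[s:e] <- gm_lab[j]
    nearest_d[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(w)), j)], 0))
  }
  keep <- nearest_d <= distance_mm
  if (any(keep)) {
    md <- md_volume[wm_idx[keep]]
    grp <- nearest_lab[keep]
    means <- tapply(md, grp, mean)
    counts <- tapply(md, grp, length)
    roi_of_label <- tbl$roi_id[match(as.numeric(names(means)), tbl$label)]
    i <- match(roi_of_label, out$roi_id)
    out$mean_md[i] <- as.numeric(means)
    out$n_voxels[i] <- as.integer(counts)
  }
  out
}

#' Gray-matter region volumes
#'
#' Volume of each labelled region: voxel count times voxel volume.
#' Regions listed in the label table but absent from the volume get
#' volume 0 with a warning.
#'
#' @param parcellation a [label_volume()].
#' @return data.frame `roi_id`, `volume_mm3`, `n_voxels`.
#' @export
gm_roi_volume <- function(parcellation) {
  stopifnot(inherits(parcellation, "label_volume"))
  vox_vol <- prod(parcellation$voxel_mm)
  tbl <- parcellation$label_table
  counts <- table(parcellation$labels[parcellation$labels != 0])
  n <- counts[as.character(tbl$label)]
  n[is.na(n)] <- 0L
  if (any(n == 0)) warning(sum(n == 0), " region(s) empty: volume 0")
  data.frame(roi_id = tbl$roi_id, volume_mm3 = as.numeric(n) * vox_vol,
             n_voxels = as.integer(n), stringsAsFactors = FALSE)
}

#' Resection overlap fraction per region
#'
#' Fraction of each region's voxels covered by a binary resection mask.
#' Empty regions get a missing fraction. Downstream, a region counts as
#' resected only when its fraction strictly exceeds 0.10.
#'
#' @param parcellation a [label_volume()].
#' @param resection_mask binary/logical 3-D array on the same grid.
#' @return data.frame `roi_id`, `overlap_fraction`.
#' @export
resection_overlap_fractions <- function(parcellation, resection_mask) {
  stopifnot(inherits(parcellation, "label_volume"))
  lab <- parcellation$labels
  .check_grids(resection_mask, lab, "resection mask vs parcellation")
  if (!all(resection_mask %in% c(0, 1, FALSE, TRUE))) {
    stop_config("resection mask must be binary")
  }
  tbl <- parcellation$label_table
  tot <- table(lab[lab != 0])
  hit <- table(lab[lab != 0 & resection_mask != 0])
  n_tot <- as.numeric(tot[as.character(tbl$label)])
  n_hit <- as.numeric(hit[as.character(tbl$label)])
  n_hit[is.na(n_hit)] <- 0
  data.frame(roi_id = tbl$roi_id,
             overlap_fraction = ifelse(is.na(n_tot) | n_tot == 0,
                                       NA_real_, n_hit / n_tot),
             stringsAsFactors = FALSE)
}
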