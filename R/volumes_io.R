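# Volumes, masks, VOIs and grey-level quantization.
#
# A "volume" is a 3D array of scalar intensities plus voxel spacing and a
# modality tag; a "mask" is a logical array on the same grid flagging the
# lesion. All texture statistics downstream read in-mask voxels only.

#' Construct a volume
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing Voxel size `(dx, dy, dz)` in mm; all components positive.
#' @param modality `"T2W"` or `"ADC"`.
#' @param case_id Case identifier string.
#' @return An object of class `rad_volume`.
#' @export
new_volume <- function(voxels, spacing = c(1, 1, 1), modality = c("T2W", "ADC"),
                       case_id = "case") {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) abort("all three dimensions must be >= 1")
  if (!all(is.finite(voxels))) abort("volume contains non-finite intensities")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three positive numbers")
  structure(
    list(voxels = voxels, spacing = spacing, modality = modality,
         case_id = as.character(case_id)),
    class = "rad_volume"
  )
}

#' Construct a binary mask
#'
#' @param flags 3D logical (or 0/1 numeric) array; `TRUE`/nonzero = lesion.
#' @param case_id Case identifier string.
#' @return An object of class `rad_mask`.
#' @export
new_mask <- function(flags, case_id = "case") {
  if (!is.array(flags) || length(dim(flags)) != 3L)
    abort("`flags` must be a 3D array")
  if (!is.logical(flags)) {
    if (!all(is.finite(flags))) abort("mask contains non-finite values")
    flags <- flags != 0
  }
  structure(list(flags = flags, case_id = as.character(case_id)),
            class = "rad_mask")
}

#' @export
print.rad_volume <- function(x, ...) {
  cat(sprintf("<rad_volume %s> %s, %s voxels, spacing %s mm\n",
              x$case_id, x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.rad_mask <- function(x, ...) {
  cat(sprintf("<rad_mask %s> %s grid, %d in-mask voxels\n", x$case_id,
              paste(dim(x$flags), collapse = "x"), sum(x$flags)))
  invisible(x)
}

#' Read a 3D volume from a NIfTI file
#'
#' Intensities are read unchanged; the voxel spacing comes from the file
#' header. Trailing singleton dimensions (e.g. a 4th dimension of size 1)
#' are dropped.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param modality `"T2W"` or `"ADC"`.
#' @param case_id Case identifier; default the file name without extension.
#' @return An [`rad_volume`][new_volume].
#' @export
load_volume <- function(path, modality = c("T2W", "ADC"), case_id = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L)
    abort(sprintf("not a 3D volume: %s has %d dimension(s)", path, length(d)))
  if (!all(is.finite(arr)))
    abort(sprintf("volume %s contains NaN/Inf voxels", path))
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  new_volume(arr, spacing = sp, modality = modality, case_id = case_id)
}

#' Read a binary lesion mask from a NIfTI file
#'
#' Nonzero voxels are treated as lesion. The mask must live on the same
#' grid as its reference volume.
#'
#' @param path Path to a `.nii`/`.nii.gz` mask file.
#' @param reference The [`rad_volume`][new_volume] the mask belongs to.
#' @return An [`rad_mask`][new_mask].
#' @export
load_mask <- function(path, reference) {
  stopifnot(inherits(reference, "rad_volume"))
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L || !identical(as.integer(d), as.integer(dim(reference$voxels))))
    abort(sprintf(
      "mask grid (%s) does not match volume grid (%s)",
      paste(d, collapse = "x"), paste(dim(reference$voxels), collapse = "x")))
  new_mask(arr != 0, case_id = reference$case_id)
}

#' Write a volume or mask to a NIfTI file
#'
#' @param x An `rad_volume` or `rad_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "rad_mask")) {
    arr <- array(as.integer(x$flags), dim(x$flags))
    sp <- c(1, 1, 1)
  } else if (inherits(x, "rad_volume")) {
    arr <- x$voxels
    sp <- x$spacing
  } else abort("`x` must be an rad_volume or rad_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract the volume of interest (VOI)
#'
#' Pairs a volume with its lesion mask and computes the tight bounding box
#' of the in-mask voxels (1-based inclusive index ranges per axis). All
#' feature extraction reads only in-mask voxels.
#'
#' @param volume An [`rad_volume`][new_volume].
#' @param mask An [`rad_mask`][new_mask] on the same grid.
#' @return An object of class `rad_voi` with elements `volume`, `mask`,
#'   `bbox` (3x2 matrix of inclusive index ranges), cropped `vox`/`flags`
#'   arrays and the in-mask intensity vector `values`.
#' @export
extract_voi <- function(volume, mask) {
  stopifnot(inherits(volume, "rad_volume"), inherits(mask, "rad_mask"))
  if (!identical(dim(volume$voxels), dim(mask$flags)))
    abort(sprintf("mask grid (%s) does not match volume grid (%s)",
                  paste(dim(mask$flags), collapse = "x"),
                  paste(dim(volume$voxels), collapse = "x")))
  idx <- which(mask$flags)
  if (length(idx) == 0L) abort("empty mask: no in-mask voxels")
  co <- arrayInd(idx, dim(mask$flags))
  bbox <- rbind(x = range(co[, 1]), y = range(co[, 2]), z = range(co[, 3]))
  colnames(bbox) <- c("lo", "hi")
  vox <- volume$voxels[bbox[1, 1]:bbox[1, 2],
                       bbox[2, 1]:bbox[2, 2],
                       bbox[3, 1]:bbox[3, 2], drop = FALSE]
  flags <- mask$flags[bbox[1, 1]:bbox[1, 2],
                      bbox[2, 1]:bbox[2, 2],
                      bbox[3, 1]:bbox[3, 2], drop = FALSE]
  structure(
    list(volume = volume, mask = mask, bbox = bbox,
         vox = vox, flags = flags, values = vox[flags]),
    class = "rad_voi"
  )
}

#' @export
print.rad_voi <- function(x, ...) {
  cat(sprintf("<rad_voi %s> %s, bbox %s, %d in-mask voxels\n",
              x$volume$case_id, x$volume$modality,
              paste(sprintf("[%d,%d]", x$bbox[, 1], x$bbox[, 2]), collapse = ""),
              length(x$values)))
  invisible(x)
}

#' Quantize VOI intensities to N = 2^bits grey levels
#'
#' In-mask intensities are min-max binned to integer levels `0..N-1`:
#' `level = floor(N * (x - min) / (max - min))`, clipped to `[0, N-1]`,
#' with min/max taken over in-mask voxels only. A constant VOI maps to
#' level 0. The mapping is monotone in the intensity.
#'
#' @param voi An [`rad_voi`][extract_voi].
#' @param bits Bit depth `m`, 1..8; the level count is `N = 2^m`.
#'   Default 5 (32 levels), a standard co-occurrence requantization.
#' @return An object of class `rad_qvoi` with integer `levels` on the
#'   cropped grid (out-of-mask voxels are `NA`), `flags`, `n_levels`, `bits`.
#' @export
quantize <- function(voi, bits = 5L) {
  stopifnot(inherits(voi, "rad_voi"))
  bits <- as.integer(bits)
  if (length(bits) != 1L || is.na(bits) || bits < 1L || bits > 8L)
    abort("`bits` must be an integer in [1, 8]")
  n <- 2L^bits
  v <- voi$values
  lo <- min(v); hi <- max(v)
  lv <- array(NA_integer_, dim(voi$vox))
  if (hi > lo) {
    lev <- floor(n * (voi$vox[voi$flags] - lo) / (hi - lo))
    lv[voi$flags] <- as.integer(pmin(pmax(lev, 0), n - 1L))
  } else {
    lv[voi$flags] <- 0L
  }
  structure(
    list(levels = lv, flags = voi$flags, n_levels = n, bits = bits,
         source = voi),
    class = "rad_qvoi"
  )
}
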