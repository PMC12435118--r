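#' 4D diffusion-weighted volume
#'
#' Bundles a 4D magnitude image (x, y, z, b-index) with its per-volume
#' b-values, an optional brain mask, and an optional reference NIfTI image
#' whose header (spatial transform) is propagated to output maps.  At least
#' one b = 0 volume is required; magnitudes must be non-negative.
#'
#' @param data 4D numeric array.
#' @param b_values Numeric vector, one b per 4th-dimension index (s/mm^2).
#' @param mask Optional 3D logical (or 0/1) array on the same grid.
#' @param reference Optional `niftiImage` (or anything [RNifti::asNifti()]
#'   accepts) carrying the spatial metadata.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, b_values, mask = NULL, reference = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4, is.numeric(b_values))
  if (dim(data)[4] != length(b_values))
    stop("4th-dimension length (", dim(data)[4],
         ") must equal length(b_values) (", length(b_values), ")")
  if (!any(b_values == 0))
    stop("no b = 0 volume present; normalization requires one")
  if (any(data < 0, na.rm = TRUE))
    stop("negative intensities found; magnitude data must be >= 0")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)[1:3]))
      stop("mask grid does not match the image grid")
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  structure(list(data = data, b_values = as.numeric(b_values),
                 mask = mask, reference = reference),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume %dx%dx%d, %d b-values (%s s/mm^2)%s\n",
              d[1], d[2], d[3], d[4],
              paste(x$b_values, collapse = ", "),
              if (is.null(x$mask)) "" else
                sprintf(", mask with %d voxels", sum(x$mask))))
  invisible(x)
}

#' Read a DWI series from NIfTI + FSL-style b-value file
#'
#' @param nifti_path 4D NIfTI file (gzip accepted).
#' @param bval_path Whitespace-separated text file of b-values.
#' @param mask_path Optional NIfTI mask (non-zero = inside).
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(nifti_path, bval_path, mask_path = NULL) {
  img <- RNifti::readNifti(nifti_path)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  mask <- if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    array(as.array(m) != 0, dim = dim(m))
  }
  dwi_volume(as.array(img), bvals, mask = mask, reference = img)
}

#' Average repeated b-value volumes across gradient directions
#'
#' Diffusion series acquired with motion-probing gradients along several
#' directions carry one volume per (b, direction).  This collapses volumes
#' sharing a b-value into a single trace-weighted volume, by geometric mean
#' (default; the trace-weighted convention for exponential decays) or
#' arithmetic mean.  A series with unique b-values passes through unchanged.
#'
#' @param dwi A [dwi_volume()].
#' @param method `"geometric"` or `"arithmetic"`.
#' @return A [dwi_volume()] with one volume per distinct b-value.
#' @export
average_directions <- function(dwi, method = c("geometric", "arithmetic")) {
  stopifnot(inherits(dwi, "dwi_volume"))
  method <- match.arg(method)
  ub <- sort(unique(dwi$b_values))
  if (length(ub) == length(dwi$b_values)) return(dwi)
  d3 <- dim(dwi$data)[1:3]
  out <- array(0, dim = c(d3, length(ub)))
  for (k in seq_along(ub)) {
    idx <- which(dwi$b_values == ub[k])
    sub <- dwi$data[, , , idx, drop = FALSE]
    out[, , , k] <- if (method == "geometric") {
      exp(apply(log(pmax(sub, .Machine$double.xmin)), 1:3, mean))
    } else {
      apply(sub, 1:3, mean)
    }
  }
  dwi_volume(out, ub, mask = dwi$mask, reference = dwi$reference)
}

#' Normalize a DWI volume to per-voxel decay signals
#'
#' Divides each masked voxel's b > 0 signals by the mean of its b = 0
#' signals.  Voxels whose b = 0 intensity is not positive are marked invalid
#' and excluded from fitting.
#'
#' @param dwi A [dwi_volume()].
#' @return A list: `b_values` (the b > 0 values), `signals` (matrix, one row
#'   per valid masked voxel), `voxels` (their linear indices into the 3D
#'   grid), `dim` (3D grid), `n_invalid_b0` (masked voxels dropped for
#'   non-positive b0).
#' @export
normalize_volume <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d3 <- dim(dwi$data)[1:3]
  nvox <- prod(d3)
  mat <- matrix(dwi$data, nrow = nvox)
  is_b0 <- dwi$b_values == 0
  b0 <- rowMeans(mat[, is_b0, drop = FALSE])
  inside <- if (is.null(dwi$mask)) rep(TRUE, nvox) else as.vector(dwi$mask)
  ok <- inside & b0 > 0
  voxels <- which(ok)
  signals <- mat[voxels, !is_b0, drop = FALSE] / b0[voxels]
  list(b_values = dwi$b_values[!is_b0], signals = signals, voxels = voxels,
       dim = d3, n_invalid_b0 = sum(inside & !(b0 > 0)))
}

#' Voxelwise F_int and D_int maps
#'
#' Runs the NNLS spectral fit and component extraction in every masked voxel.
#' F_int is stored in percent (0-100), D_int in 1e-3 mm^2/s; voxels outside
#' the mask, with non-positive b0, or where the solver fails are `NaN` in the
#' floating-point maps and 0 in the validity map.  The validity map marks
#' voxels with a defined D_int (non-zero intermediate amplitude).
#'
#' @param dwi A [dwi_volume()].
#' @param dictionary An `sda_dictionary`; defaults to Lin200.
#' @param normalize_fractions Passed to [extract_sda()].
#' @param progress Report progress every `progress` voxels (0 = silent).
#' @return An object of class `sda_maps`: 3D arrays `f_int` (percent),
#'   `d_int` (1e-3 mm^2/s), `valid` (0/1), plus `n_fitted`, `n_failed`,
#'   `n_invalid_b0` and the input's `reference`.
#' @export
fit_volume <- function(dwi, dictionary = build_component_linear_dictionary(),
                       normalize_fractions = TRUE, progress = 0) {
  norm <- normalize_volume(dwi)
  design <- exp(-outer(norm$b_values, dictionary$atoms))
  f_map <- array(NaN, dim = norm$dim)
  d_map <- array(NaN, dim = norm$dim)
  v_map <- array(0, dim = norm$dim)
  n_failed <- 0L
  labels_int <- dictionary$labels == "intermediate"
  atoms_int <- dictionary$atoms[labels_int]
  for (i in seq_along(norm$voxels)) {
    if (progress > 0 && i %% progress == 0)
      message(sprintf("voxel %d / %d", i, length(norm$voxels)))
    vox <- norm$voxels[i]
    fit <- tryCatch(nnls_lawson_hanson(design, norm$signals[i, ]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    amps <- fit$x
    total <- sum(amps)
    s_int <- sum(amps[labels_int])
    f <- if (!normalize_fractions) s_int
         else if (total > 0) s_int / total else 0
    f_map[vox] <- 100 * f
    if (s_int > 0) {
      d_map[vox] <- atoms_int[which.max(amps[labels_int])] * 1e3
      v_map[vox] <- 1
    }
  }
  if (n_failed > 0)
    warning(n_failed, " voxel(s) failed to fit and were marked invalid")
  structure(list(f_int = f_map, d_int = d_map, valid = v_map,
                 n_fitted = length(norm$voxels) - n_failed,
                 n_failed = n_failed, n_invalid_b0 = norm$n_invalid_b0,
                 reference = dwi$reference),
            class = "sda_maps")
}

#' @export
print.sda_maps <- function(x, ...) {
  cat(sprintf("SDA maps %s: %d voxels fitted (%d solver failures, %d bad b0); F_int in %%, D_int in 1e-3 mm^2/s\n",
              paste(dim(x$f_int), collapse = "x"),
              x$n_fitted, x$n_failed, x$n_invalid_b0))
  invisible(x)
}

map_to_nifti <- function(arr, reference) {
  if (is.null(reference)) RNifti::asNifti(arr)
  else RNifti::asNifti(arr, reference = reference)
}

#' @rdname maps_io
#' @export
write_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "sda_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  RNifti::writeNifti(map_to_nifti(maps$f_int, maps$reference),
                     file.path(dir, "f_int.nii.gz"), datatype = "float")
  RNifti::writeNifti(map_to_nifti(maps$d_int, maps$reference),
                     file.path(dir, "d_int.nii.gz"), datatype = "float")
  RNifti::writeNifti(map_to_nifti(maps$valid, maps$reference),
                     file.path(dir, "valid.nii.gz"), datatype = "uint8")
  invisible(dir)
}

#' Parameter-map NIfTI output and input
#'
#' Writes `f_int.nii.gz` (percent, float32), `d_int.nii.gz` (1e-3 mm^2/s,
#' float32; `NaN` where undefined) and `valid.nii.gz` (uint8) into `dir`,
#' preserving the reference spatial transform; `read_maps` reconstructs an
#' `sda_maps` object from such a directory.
#'
#' @param maps An `sda_maps` object.
#' @param dir Output directory.
#' @name maps_io
#' @export
read_maps <- function(dir) {
  f <- RNifti::readNifti(file.path(dir, "f_int.nii.gz"))
  d <- RNifti::readNifti(file.path(dir, "d_int.nii.gz"))
  v <- RNifti::readNifti(file.path(dir, "valid.nii.gz"))
  structure(list(f_int = as.array(f), d_int = as.array(d),
                 valid = as.array(v),
                 n_fitted = sum(!is.nan(as.array(f))), n_failed = NA_integer_,
                 n_invalid_b0 = NA_integer_, reference = f),
            class = "sda_maps")
}
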