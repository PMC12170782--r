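# Shared machinery for 4D series (DSC time series, CEST z-spectra, SAGE
# echoes). A series stores its per-frame data either as a dense (x,y,z,frame)
# array or as a masked voxel-by-frame matrix plus the linear indices of the
# voxels it covers. The masked form lets whole-cohort simulations keep only
# brain voxels in memory; both forms flow through the same code paths.

# Normalize series data to a voxel x frame matrix.
# Returns list(mat, voxels (NULL = all voxels of dim3), dim3).
series_matrix <- function(signal, voxels = NULL, dim3 = NULL) {
  if (is.matrix(signal)) {
    if (is.null(dim3)) stop("masked series data needs `dim3`")
    if (!is.null(voxels) && length(voxels) != nrow(signal)) {
      stop("`voxels` length must match the number of matrix rows")
    }
    list(mat = signal, voxels = voxels, dim3 = as.integer(dim3))
  } else {
    d <- dim(signal)
    if (length(d) != 4L) stop("series data must be a 4D array or a matrix")
    list(mat = matrix(signal, prod(d[1:3]), d[4]),
         voxels = NULL, dim3 = as.integer(d[1:3]))
  }
}

# Rebuild an image_volume from per-voxel values on a (possibly masked) grid.
values_to_volume <- function(values, voxels, dim3, spacing,
                             frame_id = "common", fill = NA_real_) {
  arr <- array(fill, dim3)
  if (is.null(voxels)) arr[] <- values else arr[voxels] <- values
  image_volume(arr, spacing = spacing, frame_id = frame_id)
}

# Restrict a series matrix to the voxels of a binary mask; returns row indices
# into `mat` and the corresponding linear voxel indices.
mask_rows <- function(sm, mask) {
  idx <- which(mask$data)
  if (is.null(sm$voxels)) {
    list(rows = idx, voxels = idx)
  } else {
    pos <- match(idx, sm$voxels)
    if (anyNA(pos)) stop("mask covers voxels absent from the masked series")
    list(rows = pos, voxels = idx)
  }
}
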