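#' Volumetric image container
#'
#' `image_volume()` wraps a 3D scalar array together with its voxel spacing
#' and a frame identifier. All per-voxel maps produced by the package (ADC,
#' rCBV, MTR_asym, qT2, qT2*, deltaT1) live in this container. Two volumes are
#' combinable only when their shapes, spacings and frame identifiers match
#' exactly; the package performs no resampling, so all inputs are assumed to
#' be registered to one common grid.
#'
#' @param data 3D numeric array. Non-finite voxels are permitted and are
#'   treated as invalid by downstream ROI statistics.
#' @param spacing Numeric length-3, voxel size in mm along each axis; all > 0.
#' @param frame_id Character tag naming the common grid.
#' @return An object of class `image_volume`.
#' @seealso [binary_mask()], [masked_values()], [read_volume()]
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), frame_id = "common") {
  data <- as.array(data)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) {
    data <- array(data, dim(data)[1:3])
  }
  if (length(dim(data)) != 3L) {
    stop("image_volume: `data` must be a 3D array (got ",
         length(dim(data)), " dims)")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("image_volume: `spacing` must be three positive voxel sizes in mm")
  }
  structure(list(data = data, spacing = spacing, frame_id = frame_id),
            class = "image_volume")
}

#' Binary region mask
#'
#' A 3D logical mask on the same grid contract as [image_volume()]. The two
#' kinds used by the pipeline are the contrast-enhancing tumor segmentation
#' (`"tumor_ce"`) and the whole-brain mask (`"brain"`); a tumor mask must be
#' a subset of the brain mask it is analyzed against.
#'
#' @param data 3D logical (or coercible) array.
#' @inheritParams image_volume
#' @param kind One of `"tumor_ce"`, `"brain"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1),
                        kind = c("tumor_ce", "brain"), frame_id = "common") {
  kind <- match.arg(kind)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("binary_mask: `data` must be a 3D array")
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  vol <- image_volume(data * 1L, spacing = spacing, frame_id = frame_id)
  structure(list(data = data, spacing = vol$spacing, kind = kind,
                 frame_id = frame_id),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, frame '", x$frame_id, "'\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask:", x$kind, "> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " true\n", sep = "")
  invisible(x)
}

# Grid contract: identical shape, spacing (to 1e-6 mm) and frame id.
same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < 1e-6) &&
    identical(a$frame_id, b$frame_id)
}

assert_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop("grid contract violated: ", what,
         " differ in shape, spacing or frame_id")
  }
  invisible(TRUE)
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads a `.nii`/`.nii.gz` file into an [image_volume()], applying the
#' container's scaling and byte order. 4D files with a single frame are
#' accepted and squeezed to 3D.
#'
#' @param path Path to a NIfTI-1 file.
#' @param frame_id Frame identifier to assign; defaults to `"common"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, frame_id = "common") {
  if (!file.exists(path)) stop("read_volume: file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("read_volume: not a readable NIfTI image: ", path,
                         " (", conditionMessage(e), ")", call. = FALSE)
                  })
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))  # strip container attributes
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L) {
    stop("read_volume: expected a 3D (or single-frame 4D) image: ", path)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  image_volume(arr, spacing = spacing, frame_id = frame_id)
}

#' Write a volume to a NIfTI-1 file
#'
#' Writes float32 data so that [read_volume()] inverts it bit-faithfully;
#' NaN voxels survive the roundtrip as NaN.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) {
    stop("write_volume: directory does not exist: ", dirname(path))
  }
  dat <- vol$data
  if (inherits(vol, "binary_mask")) {
    storage.mode(dat) <- "integer"
    dt <- "uint8"
  } else {
    storage.mode(dat) <- "double"
    dt <- "float"
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Extract map values under a mask
#'
#' Returns the finite map values at the true voxels of `mask`. Non-finite
#' voxels inside the mask are dropped; their count is attached as the
#' `n_dropped` attribute (and reported when `options(gbmphen.verbose = TRUE)`).
#'
#' @param vol An [image_volume()].
#' @param mask A [binary_mask()] on the same grid.
#' @return Numeric vector of finite values with attribute `n_dropped`.
#' @export
masked_values <- function(vol, mask) {
  assert_same_grid(vol, mask, "volume and mask")
  if (!any(mask$data)) {
    warning("masked_values: mask is empty")
    return(structure(numeric(0), n_dropped = 0L))
  }
  v <- vol$data[mask$data]
  keep <- is.finite(v)
  n_drop <- sum(!keep)
  if (n_drop > 0) vlog("masked_values: dropped ", n_drop, " non-finite voxels")
  structure(v[keep], n_dropped = n_drop)
}
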