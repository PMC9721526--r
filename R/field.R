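#' Scalar fields
#'
#' A scalar field is a plain numeric 2D matrix or 3D array whose entries are
#' probabilities (or normalised intensities) in \[0, 1\]. It represents either
#' an input image/volume or a segmentation probability map. All topofit
#' functions accept and return base R arrays; `as_scalar_field()` validates
#' and (optionally) normalises an array into this form.
#'
#' @param x a numeric matrix (2D) or 3D array.
#' @param normalise if `TRUE`, min-max rescale `x` to \[0, 1\] (a constant
#'   array maps to all zeros).
#' @return the validated array.
#' @examples
#' f <- as_scalar_field(matrix(runif(16), 4, 4))
#' @export
as_scalar_field <- function(x, normalise = FALSE) {
  if (is.null(dim(x))) stop("a scalar field must be a matrix or 3D array")
  nd <- length(dim(x))
  if (nd < 2L || nd > 3L) stop("field dimension must be 2 or 3, got ", nd)
  if (!is.numeric(x)) stop("field values must be numeric")
  if (any(!is.finite(x))) stop("field values must be finite")
  x <- x * 1.0
  if (normalise) x <- normalise_field(x)
  if (any(x < 0 | x > 1))
    stop("field values must lie in [0, 1]; use normalise = TRUE to rescale")
  x
}

#' Min-max normalise an array to \[0, 1\]
#'
#' @param x numeric array.
#' @return array of the same shape with range \[0, 1\]; a constant array maps
#'   to all zeros.
#' @export
normalise_field <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

#' Read an image or volume as a scalar field
#'
#' Reads a 2D greyscale image (PNG or TIFF; colour images are averaged over
#' channels) or a 3D NIfTI volume and min-max normalises it to \[0, 1\].
#'
#' @param path file path; format chosen from the extension
#'   (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @return a scalar field (2D matrix or 3D array).
#' @export
read_field <- function(path) {
  ext <- tolower(sub(".*\\.(?=[^.]+$)", "", basename(path), perl = TRUE))
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) {
    requireNamespace_or_stop("RNifti")
    x <- as.array(RNifti::readNifti(path))
  } else if (ext == "png") {
    requireNamespace_or_stop("png")
    x <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    requireNamespace_or_stop("tiff")
    x <- tiff::readTIFF(path)
  } else stop("unsupported field format: .", ext)
  if (length(dim(x)) > 3L) stop("field must be 2D or 3D")
  if (length(dim(x)) == 3L && dim(x)[3] %in% c(2L, 3L, 4L) && ext %in% c("png", "tif", "tiff"))
    x <- apply(x[, , seq_len(min(3L, dim(x)[3])), drop = FALSE], c(1, 2), mean)
  x <- array(as.numeric(x), dim(x))  # drop format-specific attributes
  as_scalar_field(x, normalise = TRUE)
}

#' Write a scalar field to disk
#'
#' @param x a scalar field.
#' @param path output path; `.png`/`.tif`/`.tiff` for 2D, `.nii`/`.nii.gz`
#'   for 3D.
#' @return `path`, invisibly.
#' @export
write_field <- function(x, path) {
  x <- as_scalar_field(x)
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) {
    requireNamespace_or_stop("RNifti")
    RNifti::writeNifti(RNifti::asNifti(x), path)
  } else if (grepl("\\.png$", tolower(path))) {
    requireNamespace_or_stop("png")
    if (length(dim(x)) != 2L) stop("PNG output requires a 2D field")
    png::writePNG(x, path)
  } else if (grepl("\\.tiff?$", tolower(path))) {
    requireNamespace_or_stop("tiff")
    if (length(dim(x)) != 2L) stop("TIFF output requires a 2D field")
    tiff::writeTIFF(x, path)
  } else stop("unsupported output format for ", path)
  invisible(path)
}

requireNamespace_or_stop <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this file format", call. = FALSE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
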