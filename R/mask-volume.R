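#' Construct a 3-D binary structure mask
#'
#' A `mask_volume` carries a rectilinear 3-D binary grid together with its
#' physical voxel spacing and origin, all in centimetres. It is the container
#' for delineated structures (GTVs, PTVs, reference contours) throughout the
#' package: the standard volume, the reference volume, and every region
#' derived from them by Boolean operations are `mask_volume` objects.
#'
#' Masks are interpreted as sets of voxel *centers*: the physical position of
#' voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`. All
#' distances in the package are Euclidean distances between voxel centers.
#'
#' @param grid a 3-D `logical` (or coercible numeric) array; any nonzero
#'   value counts as inside the structure.
#' @param spacing numeric vector of length 3, physical voxel edge lengths in
#'   cm along each array axis; all strictly positive.
#' @param origin numeric vector of length 3, physical coordinate in cm of the
#'   center of voxel `(1, 1, 1)`. Defaults to `c(0, 0, 0)`.
#' @return An object of class `mask_volume` with elements `grid`, `spacing`,
#'   `origin`.
#' @examples
#' g <- array(FALSE, c(5, 5, 5)); g[3, 3, 3] <- TRUE
#' m <- mask_volume(g, spacing = c(0.1, 0.1, 0.1))
#' mask_volume_cc(m)  # 0.001 cm^3
#' @seealso [mask_volume_cc()], [read_mask()], [distance_field()]
#' @export
mask_volume <- function(grid, spacing, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-D array", call. = FALSE)
  if (!is.logical(grid)) {
    storage.mode(grid) <- "double"
    grid <- grid != 0
  }
  if (anyNA(grid))
    stop("`grid` must not contain missing values", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (cm)", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite values (cm)", call. = FALSE)
  structure(list(grid = grid, spacing = spacing, origin = origin),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("mask_volume:", paste(dim(x$grid), collapse = " x "), "voxels,",
      "spacing", paste(format(x$spacing), collapse = " x "), "cm\n")
  cat("  in-voxels:", sum(x$grid), " volume:",
      format(mask_volume_cc(x), digits = 6), "cm^3\n")
  invisible(x)
}

#' Physical volume of a mask in cubic centimetres
#'
#' @param mask a [mask_volume()].
#' @return Volume in cm^3: the number of in-voxels times the voxel volume.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$grid) * prod(mask$spacing)
}

#' @rdname mask_volume_cc
#' @export
voxel_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  prod(mask$spacing)
}

# Check that two masks live on the identical grid; error names the first
# mismatched attribute. Registration/resampling between grids is deliberately
# out of scope: contours compared here come from one planning CT.
check_same_grid <- function(a, b, tol = 1e-8) {
  stopifnot(inherits(a, "mask_volume"), inherits(b, "mask_volume"))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("grid mismatch: shape differs (", paste(dim(a$grid), collapse = "x"),
         " vs ", paste(dim(b$grid), collapse = "x"), ")", call. = FALSE)
  if (any(abs(a$spacing - b$spacing) > tol))
    stop("grid mismatch: spacing differs", call. = FALSE)
  if (any(abs(a$origin - b$origin) > tol))
    stop("grid mismatch: origin differs", call. = FALSE)
  invisible(TRUE)
}

check_nonempty <- function(mask, label = "mask") {
  if (!any(mask$grid))
    stop("degenerate input: ", label, " contains no voxels", call. = FALSE)
  invisible(TRUE)
}

# Boolean combinations on a shared grid.
mask_and <- function(a, b) {
  check_same_grid(a, b)
  mask_volume(a$grid & b$grid, a$spacing, a$origin)
}

mask_minus <- function(a, b) {
  check_same_grid(a, b)
  mask_volume(a$grid & !b$grid, a$spacing, a$origin)
}

#' Overlap volumes of a standard/reference structure pair
#'
#' Computes the basic volumetric decomposition used by every concordance
#' coefficient: the two structure volumes, their intersection `V_I`, and the
#' two one-sided non-overlap volumes (`V_Std - V_I` and `V_Ref - V_I`).
#'
#' @param std,ref [mask_volume()] objects on the identical grid (same shape,
#'   spacing, and origin); both non-empty.
#' @return A list with elements `V_Std`, `V_Ref`, `V_I`, `V_Std_minus_I`,
#'   `V_Ref_minus_I`, all in cm^3.
#' @examples
#' g <- array(FALSE, c(12, 12, 12))
#' a <- g; a[3:8, 3:8, 3:8] <- TRUE
#' b <- g; b[5:10, 5:10, 5:10] <- TRUE
#' s <- c(0.1, 0.1, 0.1)
#' overlap_volumes(mask_volume(a, s), mask_volume(b, s))
#' @export
overlap_volumes <- function(std, ref) {
  check_same_grid(std, ref)
  check_nonempty(std, "standard mask")
  check_nonempty(ref, "reference mask")
  vv <- prod(std$spacing)
  v_std <- sum(std$grid) * vv
  v_ref <- sum(ref$grid) * vv
  v_i <- sum(std$grid & ref$grid) * vv
  list(V_Std = v_std, V_Ref = v_ref, V_I = v_i,
       V_Std_minus_I = v_std - v_i, V_Ref_minus_I = v_ref - v_i)
}

#' Read a binary structure mask from a NIfTI or NRRD volume
#'
#' Any nonzero voxel is taken to be inside the structure. Spacing and origin
#' are read from the header and converted to centimetres; headers whose
#' spatial unit is millimetres (the usual case for CT-based structures, and
#' the assumed default when the unit is unspecified) are divided by 10.
#'
#' @param path path to a `.nii`, `.nii.gz`, or `.nrrd` file containing a 3-D
#'   scalar volume.
#' @return A [mask_volume()].
#' @seealso [write_mask()]
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("mask file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    read_mask_nifti(path)
  } else if (grepl("\\.nrrd$", lower)) {
    read_mask_nrrd(path)
  } else {
    stop("unsupported mask format (expect .nii, .nii.gz, or .nrrd): ",
         path, call. = FALSE)
  }
}

read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("NIfTI volume is not 3-D: ", path, call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  unit <- tryCatch(RNifti::pixunits(img)[1], error = function(e) "Unknown")
  scale <- if (identical(unit, "cm")) 1 else 0.1  # mm (or unknown) -> cm
  mask_volume(arr != 0, spacing = abs(pd) * scale,
              origin = nifti_origin_cm(img, scale))
}

nifti_origin_cm <- function(img, scale) {
  off <- tryCatch({
    xf <- RNifti::xform(img)
    as.numeric(xf[1:3, 4])
  }, error = function(e) c(0, 0, 0))
  if (!all(is.finite(off))) off <- c(0, 0, 0)
  off * scale
}

#' Write a binary mask to NIfTI or NRRD
#'
#' The inverse of [read_mask()]: in-voxels are written as 1, spacing is
#' written in millimetres (cm x 10), the convention of CT-derived structure
#' files. The format is chosen from the file extension.
#'
#' @param mask a [mask_volume()].
#' @param path destination path ending in `.nii`, `.nii.gz`, or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- array(as.integer(mask$grid), dim(mask$grid))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- mask$spacing * 10
    RNifti::pixunits(img) <- c("mm")
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (grepl("\\.nrrd$", lower)) {
    write_mask_nrrd(mask, path)
  } else {
    stop("unsupported mask format (expect .nii, .nii.gz, or .nrrd): ",
         path, call. = FALSE)
  }
  invisible(path)
}
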