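#' Construct a volume
#'
#' A volume is a rank-3 scalar grid with per-axis voxel spacing in
#' millimetres and a 4x4 affine locating the grid in world space. The third
#' array axis is the axial (slice) direction.
#'
#' @param grid Numeric rank-3 array of voxel values.
#' @param spacing Numeric length-3 vector of voxel edge lengths (mm), all
#'   strictly positive.
#' @param affine Optional 4x4 world transform; defaults to a diagonal scaling
#'   by `spacing` (RAS-aligned, origin at the first voxel).
#' @return An object of class `volume` with elements `grid`, `spacing`,
#'   `affine`.
#' @export
as_volume <- function(grid, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a rank-3 array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(list(grid = grid, spacing = spacing, affine = affine),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels, spacing [%s] mm, range [%.4g, %.4g]\n",
              paste(dim(x$grid), collapse = " x "),
              paste(format(x$spacing, digits = 4), collapse = ", "),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$grid)

#' Read a volume from a (gzipped) NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [as_volume()] object. Integer-valued files keep integer storage.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  grid <- as.array(img)
  grid <- structure(as.vector(grid), dim = dim(grid))  # drop NIfTI attributes
  if (length(dim(grid)) != 3L)
    stop("expected a rank-3 volume in ", path, " (field: dim)")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("malformed voxel spacing in ", path, " (field: pixdim)")
  aff <- tryCatch(unclass(RNifti::xform(img))[1:4, 1:4],
                  error = function(e) diag(c(sp, 1)))
  as_volume(grid, sp, aff)
}

#' Write a volume to a gzipped NIfTI file
#'
#' @param v A [as_volume()] object (or a bare rank-3 array).
#' @param path Output path ending in `.nii.gz` (or `.nii`).
#' @param datatype NIfTI on-disk datatype; `"auto"` stores integer grids as
#'   `int16` and floating grids as `double`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "auto") {
  if (!inherits(v, "volume")) v <- as_volume(v)
  img <- RNifti::asNifti(v$grid)
  RNifti::pixdim(img) <- v$spacing
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  if (identical(datatype, "auto"))
    datatype <- if (is.integer(v$grid)) "int16" else "double"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Separable 1D interpolation along one axis of a 3D array.
# method "cubic" uses an interpolating natural cubic spline, "nearest" picks
# the closest sample. `at` are fractional input indices (1-based).
interp_axis <- function(arr, axis, at, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  n <- d[axis]
  at <- pmin(pmax(at, 1), n)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  if (method == "nearest") {
    out <- m[pmin(pmax(round(at), 1L), n), , drop = FALSE]
  } else if (n < 4 || length(at) == n && max(abs(at - seq_len(n))) == 0) {
    # degenerate or identity resampling: linear/exact lookup is sufficient
    if (all(at == round(at))) {
      out <- m[as.integer(at), , drop = FALSE]
    } else {
      lo <- pmin(floor(at), n - 1); w <- at - lo
      out <- m[lo, , drop = FALSE] * (1 - w) + m[lo + 1, , drop = FALSE] * w
    }
  } else {
    out <- apply(m, 2, function(col)
      stats::spline(seq_len(n), col, xout = at, method = "natural")$y)
    out <- matrix(out, nrow = length(at))
  }
  dim(out) <- c(length(at), d[perm[2]], d[perm[3]])
  aperm(out, order(perm))
}

#' Resample a volume to a target voxel spacing
#'
#' The output grid has `round(dim * spacing / target)` voxels per axis, with
#' voxel centres aligned at the first voxel. Images are interpolated with a
#' third-order (natural cubic spline) kernel in-plane and nearest-neighbour
#' between slices, reflecting the strong through-plane anisotropy of prostate
#' T2W data; masks are always resampled nearest-neighbour.
#'
#' @param v A [as_volume()] object.
#' @param target_spacing Numeric length-3 target spacing in mm.
#' @param mask Logical; if `TRUE`, use nearest-neighbour on every axis and
#'   keep integer storage.
#' @return A resampled `volume` with `spacing == target_spacing`.
#' @export
resample <- function(v, target_spacing = c(0.66, 0.66, 5), mask = FALSE) {
  if (!inherits(v, "volume")) stop("`v` must be a volume")
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0) ||
      any(!is.finite(target_spacing)))
    stop("`target_spacing` must be 3 strictly positive numbers")
  d_in <- dim(v$grid)
  d_out <- pmax(1L, as.integer(round(d_in * v$spacing / target_spacing)))
  grid <- v$grid
  storage <- is.integer(grid)
  if (!mask) grid <- grid * 1.0
  for (ax in 1:3) {
    if (d_out[ax] == d_in[ax] && target_spacing[ax] == v$spacing[ax]) next
    # physical position of output voxel i: (i-1)*target; input index at that
    # position: pos/spacing_in + 1
    at <- (seq_len(d_out[ax]) - 1) * target_spacing[ax] / v$spacing[ax] + 1
    meth <- if (mask || ax == 3L) "nearest" else "cubic"
    grid <- interp_axis(grid, ax, at, meth)
  }
  if (mask && storage) storage.mode(grid) <- "integer"
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] %*% diag(target_spacing / v$spacing)
  as_volume(grid, target_spacing, aff)
}

#' Z-score normalize a volume
#'
#' Centres and scales intensities to zero mean and unit variance, computed
#' over the whole volume.
#'
#' @param v A [as_volume()] object or rank-3 array.
#' @return A `volume` with standardized intensities.
#' @export
znorm <- function(v) {
  bare <- !inherits(v, "volume")
  g <- if (bare) v else v$grid
  s <- stats::sd(g)
  if (!is.finite(s) || s == 0)
    stop("cannot Z-score normalize a volume with zero intensity variance")
  g <- (g - mean(g)) / s
  if (bare) return(g)
  as_volume(g, v$spacing, v$affine)
}

# Pad or crop a 2D matrix symmetrically to `size[1]` x `size[2]`; `fill` pads.
pad_crop_2d <- function(m, size, fill = 0) {
  size <- rep(size, length.out = 2L)
  for (ax in 1:2) {
    n <- dim(m)[ax]
    size_ax <- size[ax]
    if (n < size_ax) {
      lo <- (size_ax - n) %/% 2
      blk_dim <- dim(m); blk_dim[ax] <- size_ax
      out <- array(fill, blk_dim)
      idx <- lo + seq_len(n)
      if (ax == 1) out[idx, ] <- m else out[, idx] <- m
      m <- out
    } else if (n > size_ax) {
      lo <- (n - size_ax) %/% 2
      idx <- lo + seq_len(size_ax)
      m <- if (ax == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
    }
  }
  m
}

#' Extract axial 2D slices padded/cropped to a fixed size
#'
#' @param v A [as_volume()] object (typically resampled and normalized).
#' @param mask A rank-3 integer mask array or `volume` aligned with `v`.
#' @param size Target in-plane size (pixels); slices are symmetrically
#'   zero-padded or centre-cropped.
#' @return A list with one element per axial slice: `list(image, mask, index)`.
#' @export
make_slices_2d <- function(v, mask, size = 512) {
  g <- if (inherits(v, "volume")) v$grid else v
  mk <- if (inherits(mask, "volume")) mask$grid else mask
  if (!all(dim(g) == dim(mk)))
    stop("volume and mask shapes differ")
  lapply(seq_len(dim(g)[3]), function(k) {
    list(image = pad_crop_2d(g[, , k], size, fill = 0),
         mask = pad_crop_2d(mk[, , k], size, fill = 0L),
         index = k)
  })
}

#' Crop a 3D patch centred on the mask centroid
#'
#' @param v A [as_volume()] object.
#' @param mask Aligned rank-3 mask (array or `volume`) with nonempty
#'   foreground, used for centring.
#' @param size Integer length-3 patch size; borders are zero-padded.
#' @return `list(image, mask)` arrays of dimension `size`.
#' @export
crop_patch_3d <- function(v, mask, size = c(320, 320, 16)) {
  g <- if (inherits(v, "volume")) v$grid else v
  mk <- if (inherits(mask, "volume")) mask$grid else mask
  if (!all(dim(g) == dim(mk))) stop("volume and mask shapes differ")
  idx <- which(mk > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask has no foreground; cannot centre the patch")
  ctr <- ceiling(colMeans(idx) - 0.5)  # nearest voxel, ties toward the origin
  img <- array(0, size)
  out_mk <- array(0L, size)
  lo_src <- hi_src <- lo_dst <- integer(3)
  src_idx <- dst_idx <- vector("list", 3)
  for (ax in 1:3) {
    start <- ctr[ax] - size[ax] %/% 2  # 0-based start in source
    src <- pmax(1L, start + 1L):pmin(dim(g)[ax], start + size[ax])
    if (length(src) == 0 || src[1] > src[length(src)])
      stop("patch does not intersect the volume along axis ", ax)
    dst <- src - start
    src_idx[[ax]] <- src
    dst_idx[[ax]] <- dst
  }
  img[dst_idx[[1]], dst_idx[[2]], dst_idx[[3]]] <-
    g[src_idx[[1]], src_idx[[2]], src_idx[[3]]]
  out_mk[dst_idx[[1]], dst_idx[[2]], dst_idx[[3]]] <-
    mk[src_idx[[1]], src_idx[[2]], src_idx[[3]]]
  list(image = img, mask = out_mk)
}
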