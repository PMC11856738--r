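#' Specification for a synthetic prostate phantom
#'
#' Describes a T2W-like test volume: a bright ellipsoidal organ on a darker
#' background inside an organ-centred field of view, with in-plane boundary
#' blur that is strongest on the first and last slices the organ occupies
#' (the apex/base analogue, where real prostate boundaries are blurriest) and
#' additive Gaussian noise. The mask is the clean, unblurred ellipsoid.
#'
#' Defaults emulate an organ-centred crop of a clinical T2W scan: in-plane
#' spacing 0.66 mm, 5 mm slices, organ semi-axes of 12 x 10 x 18 mm
#' (left-right, anterior-posterior, cranio-caudal), organ intensity 1 against
#' a 0.3 background, mid-gland blur of 0.6 px rising to 2.5 px at apex/base,
#' and noise with standard deviation 0.05.
#'
#' @param grid_size Integer length-3 grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param semi_axes Organ semi-axes in mm (before per-seed jitter).
#' @param axis_jitter Relative uniform jitter applied to each semi-axis.
#' @param centre_jitter_mm Maximum uniform offset of the organ centre (mm).
#' @param blur_mid In-plane Gaussian blur sigma (pixels) at mid-gland.
#' @param blur_apex_base Blur sigma (pixels) on the first/last organ slices.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param organ_intensity,background_intensity Clean tissue intensities.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(64, 64, 12),
                         spacing = c(0.66, 0.66, 5),
                         semi_axes = c(12, 10, 18),
                         axis_jitter = 0.15,
                         centre_jitter_mm = c(2, 2, 4),
                         blur_mid = 0.6,
                         blur_apex_base = 2.5,
                         noise_sd = 0.05,
                         organ_intensity = 1,
                         background_intensity = 0.3,
                         seed = 1L) {
  spec <- list(grid_size = as.integer(grid_size), spacing = as.numeric(spacing),
               semi_axes = as.numeric(semi_axes), axis_jitter = axis_jitter,
               centre_jitter_mm = as.numeric(centre_jitter_mm),
               blur_mid = blur_mid, blur_apex_base = blur_apex_base,
               noise_sd = noise_sd, organ_intensity = organ_intensity,
               background_intensity = background_intensity,
               seed = as.integer(seed))
  if (any(spec$blur_mid < 0) || any(spec$blur_apex_base < 0))
    stop("blur strengths must be nonnegative")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  fov <- spec$grid_size * spec$spacing
  if (any(2 * spec$semi_axes * (1 + spec$axis_jitter) >= fov))
    stop("organ does not fit inside the grid")
  class(spec) <- "phantom_spec"
  spec
}

#' Generate a synthetic prostate phantom
#'
#' @param spec A [phantom_spec()].
#' @return `list(volume, mask)`: the noisy, blurred image as a
#'   [as_volume()] object and the clean binary organ mask as an integer
#'   `volume` with the same geometry.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  with_seed(spec$seed, {
    d <- spec$grid_size
    sp <- spec$spacing
    ax <- spec$semi_axes *
      stats::runif(3, 1 - spec$axis_jitter, 1 + spec$axis_jitter)
    fov <- d * sp
    if (any(2 * ax >= fov)) stop("organ does not fit inside the grid")
    ctr <- fov / 2 + stats::runif(3, -1, 1) * spec$centre_jitter_mm
    # world coordinates of voxel centres
    xs <- (seq_len(d[1]) - 0.5) * sp[1]
    ys <- (seq_len(d[2]) - 0.5) * sp[2]
    zs <- (seq_len(d[3]) - 0.5) * sp[3]
    q <- outer(((xs - ctr[1]) / ax[1])^2, ((ys - ctr[2]) / ax[2])^2, "+")
    mask <- array(0L, d)
    for (k in seq_len(d[3]))
      mask[, , k] <- (q + ((zs[k] - ctr[3]) / ax[3])^2 <= 1) * 1L
    img <- array(spec$background_intensity, d)
    img[mask == 1L] <- spec$organ_intensity

    occ <- which(apply(mask, 3, sum) > 0)
    if (length(occ) > 0) {
      # blur strongest at the first/last occupied slice, weakest mid-gland
      mid <- (min(occ) + max(occ)) / 2
      half <- max((max(occ) - min(occ)) / 2, 0.5)
      for (k in seq_len(d[3])) {
        w <- if (k %in% occ) min(abs(k - mid) / half, 1) else 1
        sig <- spec$blur_mid + (spec$blur_apex_base - spec$blur_mid) * w
        if (sig > 0)
          img[, , k] <- EBImage::gblur(img[, , k], sigma = sig)
      }
    }
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
    list(volume = as_volume(img, sp),
         mask = as_volume(mask, sp))
  })
}

#' Write a synthetic phantom dataset with train/val/test splits
#'
#' Generates `n_cases` phantoms (seeds `seed`, `seed + 1`, ...) and writes
#' paired gzipped NIfTI image/mask files plus a `manifest.csv` with columns
#' `case_id`, `image`, `mask`, `split`, `seed`.
#'
#' @param n_cases Number of phantoms.
#' @param dir Output directory (created if missing).
#' @param seed Base seed.
#' @param split Named numeric fractions for `train`/`val`/`test`; must sum
#'   to 1. Cases are assigned in order.
#' @param spec Template [phantom_spec()]; its seed is overridden per case.
#' @return The manifest as a data.frame, invisibly.
#' @export
write_phantom_dataset <- function(n_cases, dir, seed = 1L,
                                  split = c(train = 0.8, val = 0.2, test = 0),
                                  spec = phantom_spec()) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_split <- diff(round(cumsum(c(0, split)) * n_cases))
  labels <- rep(names(split), n_split)
  rows <- lapply(seq_len(n_cases), function(i) {
    sp <- spec
    sp$seed <- as.integer(seed + i - 1L)
    ph <- generate_phantom(sp)
    cid <- sprintf("case_%03d", i)
    img_path <- file.path(dir, paste0(cid, "_image.nii.gz"))
    msk_path <- file.path(dir, paste0(cid, "_mask.nii.gz"))
    write_volume(ph$volume, img_path)
    write_volume(ph$mask, msk_path)
    data.frame(case_id = cid, image = img_path, mask = msk_path,
               split = labels[i], seed = sp$seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
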