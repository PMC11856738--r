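# Evaluation layer: boundary extraction, surface distances (ASSD, HD95),
# overlap metrics (Jaccard, DSC), inter-annotator correlation, and per-case
# reporting. Distances are computed from an exact Euclidean distance
# transform of each boundary set (separable parabola algorithm in src/),
# read off at the other mask's boundary voxels.

mask_grid <- function(m) {
  g <- if (inherits(m, "volume")) m$grid else m
  if (length(dim(g)) == 2L) dim(g) <- c(dim(g), 1L)
  if (length(dim(g)) != 3L) stop("mask must be a rank-2 or rank-3 array")
  if (!all(g %in% c(0, 1))) stop("mask values must be exactly {0, 1}")
  g != 0
}

#' Extract the boundary voxels of a binary mask
#'
#' A boundary voxel is a foreground voxel with at least one face-adjacent
#' (6-connectivity) neighbour that is background or outside the grid.
#'
#' @param mask Binary rank-3 array (or `volume`) with values in \{0, 1\}.
#' @return Integer matrix with one row per boundary voxel and columns
#'   `x`, `y`, `z` (0-based coordinates), plus attribute `"grid"`: the logical
#'   boundary array.
#' @export
extract_boundary <- function(mask) {
  fg <- mask_grid(mask)
  if (!any(fg)) stop("no surface: mask has empty foreground")
  d <- dim(fg)
  # pad with background so out-of-grid neighbours read as background
  pad <- array(FALSE, d + 2L)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- fg
  i <- 1L + seq_len(d[1]); j <- 1L + seq_len(d[2]); k <- 1L + seq_len(d[3])
  interior <- pad[i - 1L, j, k] & pad[i + 1L, j, k] &
    pad[i, j - 1L, k] & pad[i, j + 1L, k] &
    pad[i, j, k - 1L] & pad[i, j, k + 1L]
  on_bd <- fg & !interior
  coords <- which(on_bd, arr.ind = TRUE) - 1L
  colnames(coords) <- c("x", "y", "z")
  structure(coords, grid = on_bd)
}

# Directed nearest-boundary distances between two masks: for every boundary
# voxel of `a`, the Euclidean distance to the nearest boundary voxel of `b`,
# and vice versa. Spacing weights the per-axis steps (all-ones = voxel units).
surface_distances <- function(a, b, spacing = c(1, 1, 1)) {
  ga <- mask_grid(a); gb <- mask_grid(b)
  if (!all(dim(ga) == dim(gb))) stop("mask shapes differ")
  if (!any(ga) || !any(gb)) stop("no surface: mask has empty foreground")
  sa <- attr(extract_boundary(ga * 1L), "grid")
  sb <- attr(extract_boundary(gb * 1L), "grid")
  dta <- edt3d_cpp(as.logical(sa), dim(ga), as.numeric(spacing))
  dtb <- edt3d_cpp(as.logical(sb), dim(gb), as.numeric(spacing))
  dim(dta) <- dim(ga); dim(dtb) <- dim(gb)
  list(a_to_b = as.numeric(dtb[sa]), b_to_a = as.numeric(dta[sb]))
}

#' Average symmetric surface distance
#'
#' Sums, over each boundary voxel of each mask, the Euclidean distance to the
#' nearest boundary voxel of the other mask, and divides by the total number
#' of boundary voxels. Symmetric in its arguments.
#'
#' @param a,b Binary rank-3 arrays (or `volume`s) of identical shape.
#' @param spacing Per-axis step lengths; the default of all ones yields voxel
#'   units (as reported for this metric); pass the voxel spacing for mm.
#' @return Nonnegative scalar.
#' @export
assd <- function(a, b, spacing = c(1, 1, 1)) {
  d <- surface_distances(a, b, spacing)
  (sum(d$a_to_b) + sum(d$b_to_a)) / (length(d$a_to_b) + length(d$b_to_a))
}

#' 95th-percentile Hausdorff distance
#'
#' The larger of the two directed 95th percentiles of nearest-boundary
#' distances, using the linear-interpolation percentile rule
#' (`quantile(type = 7)`).
#'
#' @inheritParams assd
#' @return Nonnegative scalar.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  d <- surface_distances(a, b, spacing)
  max(stats::quantile(d$a_to_b, 0.95, type = 7, names = FALSE),
      stats::quantile(d$b_to_a, 0.95, type = 7, names = FALSE))
}

#' Jaccard index (intersection over union), as a percentage
#'
#' @inheritParams assd
#' @return Scalar in `[0, 100]`.
#' @export
jaccard <- function(a, b) {
  ga <- mask_grid(a); gb <- mask_grid(b)
  if (!all(dim(ga) == dim(gb))) stop("mask shapes differ")
  u <- sum(ga | gb)
  if (u == 0) stop("Jaccard undefined: both masks are empty")
  100 * sum(ga & gb) / u
}

#' Dice similarity coefficient, as a percentage
#'
#' `100 * 2*TP / (FP + FN + 2*TP)`, from 0 (no overlap) to 100 (identical).
#'
#' @inheritParams assd
#' @return Scalar in `[0, 100]`.
#' @export
dsc <- function(a, b) {
  ga <- mask_grid(a); gb <- mask_grid(b)
  if (!all(dim(ga) == dim(gb))) stop("mask shapes differ")
  tp <- sum(ga & gb); fp <- sum(!ga & gb); fn <- sum(ga & !gb)
  if (tp + fp + fn == 0) stop("DSC undefined: both masks are empty")
  100 * 2 * tp / (fp + fn + 2 * tp)
}

#' Inter-annotator correlation coefficient
#'
#' Pearson-form correlation between two paired per-slice annotation series
#' (e.g. annotated areas per slice from two readers).
#'
#' @param x,y Numeric vectors of equal length (at least 2) with nonzero
#'   variance.
#' @return Scalar in `[-1, 1]`.
#' @export
annotation_cc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("`x` and `y` must be paired series of equal length >= 2")
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) stop("degenerate input: zero variance in an annotation series")
  sum(dx * dy) / den
}

#' Evaluate predicted masks against ground truth, case by case
#'
#' Matches files named `<case_id>.nii.gz` (or `<case_id>.nii`) across the two
#' directories and computes ASSD, HD95 (voxel units), Jaccard and DSC (%) per
#' case, plus a final row of arithmetic means across cases. An empty
#' prediction scores 0% on the overlap metrics while its surface distances
#' are recorded as `NA`, excluded from the aggregate means, and flagged with
#' a warning.
#'
#' @param pred_dir,gt_dir Directories of predicted and ground-truth masks.
#' @param out Optional path for a CSV copy of the report.
#' @param aggregate `"per_case"` (mean of per-case overlap percentages,
#'   the default) or `"pooled"` (overlap percentages recomputed from voxel
#'   counts pooled over all cases; distances remain per-case means).
#' @return A `metric_report` data.frame with columns `case_id`, `assd_voxel`,
#'   `hd95_voxel`, `jaccard_pct`, `dsc_pct`; the last row (`aggregate`) holds
#'   the column means.
#' @export
evaluate_cases <- function(pred_dir, gt_dir, out = NULL,
                           aggregate = c("per_case", "pooled")) {
  aggregate <- match.arg(aggregate)
  list_cases <- function(d) {
    f <- list.files(d, pattern = "\\.nii(\\.gz)?$")
    stats::setNames(file.path(d, f), sub("\\.nii(\\.gz)?$", "", f))
  }
  preds <- list_cases(pred_dir)
  gts <- list_cases(gt_dir)
  missing_gt <- setdiff(names(preds), names(gts))
  missing_pred <- setdiff(names(gts), names(preds))
  if (length(missing_gt) || length(missing_pred))
    stop("unmatched case ids; missing ground truth: [",
         paste(missing_gt, collapse = ", "), "]; missing predictions: [",
         paste(missing_pred, collapse = ", "), "]")
  ids <- sort(names(gts))
  pool <- c(tp = 0, fp = 0, fn = 0, un = 0)
  rows <- lapply(ids, function(id) {
    p <- read_volume(preds[[id]])$grid
    g <- read_volume(gts[[id]])$grid
    gp <- mask_grid(p); gg <- mask_grid(g)
    pool <<- pool + c(tp = sum(gp & gg), fp = sum(gp & !gg),
                      fn = sum(!gp & gg), un = sum(gp | gg))
    if (!any(gp)) {
      warning("empty prediction for case '", id,
              "': surface distances excluded from aggregates")
      data.frame(case_id = id, assd_voxel = NA_real_, hd95_voxel = NA_real_,
                 jaccard_pct = 0, dsc_pct = 0)
    } else {
      data.frame(case_id = id, assd_voxel = assd(gg, gp),
                 hd95_voxel = hd95(gg, gp), jaccard_pct = jaccard(gg, gp),
                 dsc_pct = dsc(gg, gp))
    }
  })
  rep <- do.call(rbind, rows)
  agg <- data.frame(case_id = "aggregate",
                    assd_voxel = mean(rep$assd_voxel, na.rm = TRUE),
                    hd95_voxel = mean(rep$hd95_voxel, na.rm = TRUE),
                    jaccard_pct = if (aggregate == "pooled")
                      100 * pool[["tp"]] / pool[["un"]] else
                        mean(rep$jaccard_pct),
                    dsc_pct = if (aggregate == "pooled")
                      100 * 2 * pool[["tp"]] /
                        (pool[["fp"]] + pool[["fn"]] + 2 * pool[["tp"]]) else
                        mean(rep$dsc_pct))
  rep <- rbind(rep, agg)
  class(rep) <- c("metric_report", "data.frame")
  if (!is.null(out)) write.csv(rep, out, row.names = FALSE)
  rep
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("Segmentation metric report (distances in voxels, overlap in %)\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
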