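#' Fixed-threshold metabolic segmentation
#'
#' Delineates the metabolically active tumor inside a contoured site by the
#' fixed body-weight SUV threshold: every in-mask voxel with SUV at or above
#' the threshold (default 2.5) belongs to the metabolic tumor volume. The
#' comparison is inclusive, so a voxel exactly at the threshold is counted.
#'
#' The derived quantities follow the standard definitions:
#' \describe{
#'   \item{`mtv_cc`}{metabolic tumor volume MTV, segmented voxel count times
#'     voxel volume, in cc. When the site's SUVmax is below the threshold the
#'     MTV is 0.}
#'   \item{`suv_mean`}{mean SUV over the *segmented* voxels (0 when empty).}
#'   \item{`suv_max`}{maximum SUV over the full contoured mask.}
#'   \item{`tlg`}{total lesion glycolysis, `mtv_cc * suv_mean` by
#'     construction.}
#' }
#'
#' @param vol an [suv_volume].
#' @param mask a [site_mask], shape-congruent with `vol`.
#' @param threshold SUV cut-off; default 2.5.
#' @return An object of class `site_segmentation`: `site_label`, `voxels`
#'   (integer linear indices of segmented voxels), `dim`, `spacing`,
#'   `voxel_volume_cc`, `n_voxels`, `mtv_cc`, `suv_mean`, `suv_max`, `tlg`.
#' @examples
#' v <- suv_volume(array(c(3, 3, 3, rep(1, 5)), c(2, 2, 2)), c(10, 10, 10))
#' m <- site_mask(array(TRUE, c(2, 2, 2)))
#' seg <- threshold_segment(v, m)
#' seg$mtv_cc  # 3 cc
#' seg$tlg     # 9
#' @export
threshold_segment <- function(vol, mask, threshold = 2.5) {
  pair <- attach_mask(vol, mask)
  inmask <- which(pair$mask$voxels)
  suv_in <- pair$vol$voxels[inmask]
  keep <- suv_in >= threshold
  idx <- inmask[keep]
  n <- length(idx)
  mtv <- n * vol$voxel_volume_cc
  suv_mean <- if (n > 0) mean(suv_in[keep]) else 0
  suv_max <- if (length(inmask) > 0) max(suv_in) else 0
  structure(
    list(site_label = mask$site_label,
         voxels = idx,
         dim = dim(vol$voxels),
         spacing = vol$spacing,
         voxel_volume_cc = vol$voxel_volume_cc,
         n_voxels = n,
         mtv_cc = mtv,
         suv_mean = suv_mean,
         suv_max = suv_max,
         tlg = mtv * suv_mean),
    class = "site_segmentation"
  )
}

#' @export
print.site_segmentation <- function(x, ...) {
  cat(sprintf("<site_segmentation> '%s': %d voxels, MTV %.2f cc, SUVmean %.2f, SUVmax %.2f, TLG %.2f\n",
              x$site_label, x$n_voxels, x$mtv_cc, x$suv_mean, x$suv_max, x$tlg))
  invisible(x)
}

#' Exclude small metabolic volumes
#'
#' Drops segmentations whose metabolic tumor volume is below `min_cc`
#' (default 5 cc): features extracted from small lesions are poorly
#' reproducible. The cut is strict — a site of exactly `min_cc` is retained.
#' Each exclusion is reported via `message()` with its volume.
#'
#' @param segs list of [threshold_segment()] results.
#' @param min_cc minimum retained MTV in cc.
#' @return The retained sublist, in input order.
#' @export
filter_small_sites <- function(segs, min_cc = 5.0) {
  keep <- vapply(segs, function(s) s$mtv_cc >= min_cc, logical(1))
  for (s in segs[!keep])
    message(sprintf("excluding site '%s': MTV %.3f cc < %.3f cc", s$site_label,
                    s$mtv_cc, min_cc))
  segs[keep]
}
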