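## Laws texture energies: all 125 separable 3D filters built from the five
## 1D kernels (level, edge, spot, wave, ripple). The feature for each filter
## is the texture energy: mean absolute filter response over mask voxels.
## Only L5 has a nonzero sum, so the 124 filters containing a zero-sum
## factor vanish on constant volumes and every non-L5L5L5 feature is
## invariant to a constant HU offset.

laws_kernels <- function() {
  list(
    L5 = c(1, 4, 6, 4, 1),
    E5 = c(-1, -2, 0, 2, 1),
    S5 = c(-1, 0, 2, 0, -1),
    W5 = c(-1, 2, 0, -2, 1),
    R5 = c(1, -4, 6, -4, 1)
  )
}

#' Laws texture-energy features
#'
#' Applies each of the 125 separable 3D Laws filters (kernel per axis in
#' z, y, x order, replicate boundary) to the volume restricted to the mask
#' bounding box (padded by 2 voxels) and returns the mean absolute
#' response over mask voxels, in lexicographic kernel order
#' (L5, E5, S5, W5, R5 per axis).
#'
#' @param volume_arr 3D HU array.
#' @param mask aligned logical mask; its bounding box must span at least 5
#'   voxels per axis, otherwise all 125 values are `NA`.
#' @return Named numeric vector of 125 texture energies.
#' @export
laws_features <- function(volume_arr, mask) {
  nms <- laws_feature_names()
  idx <- which(mask, arr.ind = TRUE)
  ext <- apply(idx, 2, function(i) diff(range(i)) + 1)
  if (any(ext < 5)) {
    return(stats::setNames(rep(NA_real_, 125), nms))
  }
  cb <- crop_bbox(volume_arr, mask, pad = 2L)
  ks <- laws_kernels()
  kn <- names(ks)
  ## separable: precompute z-pass then y-pass, share across x kernels
  out <- numeric(125)
  pos <- 0L
  for (a in kn) {
    az <- convolve_axis(cb$arr, ks[[a]], 1L, boundary = "replicate")
    for (b in kn) {
      ay <- convolve_axis(az, ks[[b]], 2L, boundary = "replicate")
      for (d in kn) {
        ax <- convolve_axis(ay, ks[[d]], 3L, boundary = "replicate")
        pos <- pos + 1L
        out[pos] <- mean(abs(ax[cb$mask]))
      }
    }
  }
  stats::setNames(out, nms)
}
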