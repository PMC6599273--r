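## Stationary (undecimated) 3D wavelet sub-band features, coif1.
##
## The transform is the a-trous scheme with periodic boundary: level 1
## filters each axis with the low/high-pass pair, level 2 re-filters the
## level-1 approximation (LLL) with the filters upsampled by 2. Filters are
## the orthonormal coif1 taps rescaled by 1/sqrt(2), which makes the
## per-axis analysis energy-preserving: the 8 level-1 sub-band energies sum
## exactly to the input energy (Parseval).

coif1_filters <- function() {
  lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
          0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  list(lo = lo / sqrt(2), hi = hi / sqrt(2))
}

## one undecimated analysis level along all three axes; returns the 8
## sub-bands named by the z/y/x filter letters (L = low, H = high)
swt_level <- function(arr, dilation = 1L) {
  f <- coif1_filters()
  out <- list()
  zL <- convolve_axis(arr, f$lo, 1L, "periodic", dilation)
  zH <- convolve_axis(arr, f$hi, 1L, "periodic", dilation)
  for (z in c("L", "H")) {
    az <- if (z == "L") zL else zH
    yL <- convolve_axis(az, f$lo, 2L, "periodic", dilation)
    yH <- convolve_axis(az, f$hi, 2L, "periodic", dilation)
    for (y in c("L", "H")) {
      ay <- if (y == "L") yL else yH
      for (x in c("L", "H")) {
        k <- if (x == "L") f$lo else f$hi
        out[[paste0(z, y, x)]] <- convolve_axis(ay, k, 3L, "periodic", dilation)
      }
    }
  }
  out
}

#' Stationary-wavelet sub-band features
#'
#' Two-level undecimated coif1 decomposition of the masked bounding box;
#' for each of the 8 level-1 sub-bands and the 7 level-2 detail sub-bands,
#' the in-mask energy (mean squared coefficient over mask voxels) and the
#' Shannon entropy (bits) of a 32-bin histogram of in-mask coefficients.
#'
#' @param volume_arr 3D HU array.
#' @param mask aligned logical mask; its bounding box must span at least 8
#'   voxels per axis, otherwise all 30 values are `NA`.
#' @return Named numeric vector of 30 features (energy, entropy per
#'   sub-band, level 1 then level 2).
#' @export
wavelet_features <- function(volume_arr, mask) {
  nms <- wavelet_feature_names()
  idx <- which(mask, arr.ind = TRUE)
  ext <- apply(idx, 2, function(i) diff(range(i)) + 1)
  if (any(ext < 8)) {
    return(stats::setNames(rep(NA_real_, 30), nms))
  }
  cb <- crop_bbox(volume_arr, mask, pad = 2L)
  l1 <- swt_level(cb$arr, dilation = 1L)
  l2 <- swt_level(l1$LLL, dilation = 2L)
  sb <- wavelet_subband_names()
  vals <- numeric(0)
  coef_stats <- function(coefs) {
    x <- coefs[cb$mask]
    energy <- mean(x^2)
    rng <- range(x)
    ent <- if (rng[2] > rng[1]) {
      lev <- discretize_fbn(x, 32L)
      p <- tabulate(lev, 32L) / length(lev)
      -sum(p[p > 0] * log2(p[p > 0]))
    } else 0
    c(energy, ent)
  }
  for (s in sb$level1) vals <- c(vals, coef_stats(l1[[s]]))
  for (s in sb$level2) vals <- c(vals, coef_stats(l2[[s]]))
  stats::setNames(vals, nms)
}
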