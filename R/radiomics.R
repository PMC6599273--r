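## Feature-vector assembly and cohort-level extraction.

#' Extraction settings
#'
#' @param n_bins bin count for the fixed-bin-number discretization used by
#'   the texture families (and wavelet entropies).
#' @param resample_iso optional isotropic target spacing in mm; `NULL`
#'   (default) extracts on the native grid. Intended for anisotropic
#'   input; phantoms are generated isotropic.
#' @return List of settings with a stable digest.
#' @export
extraction_settings <- function(n_bins = 32L, resample_iso = NULL) {
  s <- list(n_bins = as.integer(n_bins), resample_iso = resample_iso)
  s$digest <- rlang::hash(s[c("n_bins", "resample_iso")])
  s
}

## trilinear resampling to an isotropic grid (flagged option; nearest
## neighbour for the mask)
resample_iso3d <- function(arr, spacing, target) {
  dm <- dim(arr)
  new_dm <- pmax(2L, round(dm * spacing / target))
  g <- lapply(1:3, function(ax) {
    (seq_len(new_dm[ax]) - 0.5) * (dm[ax] / new_dm[ax]) + 0.5 - 0.5
  })
  ## sample at fractional indices by trilinear interpolation
  z0 <- pmin(pmax(floor(g[[1]]), 1), dm[1] - 1); fz <- g[[1]] - z0
  y0 <- pmin(pmax(floor(g[[2]]), 1), dm[2] - 1); fy <- g[[2]] - y0
  x0 <- pmin(pmax(floor(g[[3]]), 1), dm[3] - 1); fx <- g[[3]] - x0
  out <- array(0, new_dm)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- outer(outer(ifelse(rep(dz, new_dm[1]) == 1, fz, 1 - fz),
                     ifelse(rep(dy, new_dm[2]) == 1, fy, 1 - fy)),
               ifelse(rep(dx, new_dm[3]) == 1, fx, 1 - fx))
    dim(w) <- new_dm
    out <- out + w * arr[z0 + dz, y0 + dy, x0 + dx]
  }
  out
}

#' Extract the full 364-feature vector from one mask
#'
#' Deterministic: identical volume + mask + settings give bit-identical
#' vectors. Degenerate inputs propagate `NA` per family (empty mask: an
#' all-`NA` vector with a warning; masks too small for the Laws or wavelet
#' bounding-box requirements: `NA` for those families) so that empty
#' mediastinal-derived difference cases survive the pipeline.
#'
#' @param volume a `ct_volume` (or 3D HU array with `spacing` passed via
#'   the mask attribute).
#' @param mask aligned logical mask.
#' @param settings an [extraction_settings()].
#' @return Named numeric vector `F1`..`F364` with attributes `role_names`
#'   (catalogue names) and `settings_digest`.
#' @examples
#' v <- ct_volume(array(rnorm(10^3, -100, 30), c(10, 10, 10)))
#' m <- array(TRUE, c(10, 10, 10))
#' f <- extract_all(v, m)
#' length(f)      # 364
#' f[["F311"]]    # voxel dimension x
#' @export
extract_all <- function(volume, mask, settings = extraction_settings()) {
  stopifnot(inherits(volume, "ct_volume"))
  cat364 <- feature_catalogue()
  empty <- stats::setNames(rep(NA_real_, 364), cat364$id)
  attr(empty, "feature_names") <- cat364$name
  attr(empty, "settings_digest") <- settings$digest
  if (!identical(dim(volume$data), dim(mask))) {
    stop("mask is not aligned with the volume grid", call. = FALSE)
  }
  if (!any(mask)) {
    warning("empty mask: returning all-missing feature vector", call. = FALSE)
    return(empty)
  }
  arr <- volume$data
  spacing <- volume$spacing
  if (!is.null(settings$resample_iso)) {
    t <- settings$resample_iso
    arr <- resample_iso3d(arr, spacing, t)
    mask <- resample_iso3d(array(as.numeric(mask), dim(mask)), spacing, t) >= 0.5
    spacing <- rep(t, 3)
    if (!any(mask)) {
      warning("mask vanished after resampling", call. = FALSE)
      return(empty)
    }
  }
  n_bins <- settings$n_bins
  vals <- arr[mask]
  ## all spatial families see at most the mask plus an 8-voxel halo (the
  ## largest kernel support used: the 1 cm^3 local-intensity sphere)
  halo <- crop_bbox(arr, mask, pad = 8L)
  cb <- crop_bbox(arr, mask, pad = 1L)
  lev <- array(0L, dim(cb$mask))
  lev[cb$mask] <- discretize_fbn(cb$arr[cb$mask], n_bins)

  blocks <- list(
    stats = stats_features(vals),
    ivh = ivh_features(vals),
    hist = hist_features(discretize_fbn(vals, n_bins), n_bins),
    morph = morph_features(halo$arr, halo$mask, spacing, origin = halo$origin),
    local = local_features(halo$arr, halo$mask, spacing),
    glcm = glcm_features(lev, cb$mask, n_bins, merged = FALSE),
    glrlm = glrlm_features(lev, cb$mask, n_bins),
    glszm = glszm_features(lev, cb$mask, n_bins),
    ngldm = ngldm_features(lev, cb$mask, n_bins),
    ngtdm = ngtdm_features(lev, cb$mask, n_bins),
    glcm_merged = glcm_features(lev, cb$mask, n_bins, merged = TRUE),
    voxdim = c(spacing[3], spacing[2], spacing[1])  # x, y, z
  )
  laws <- laws_features(halo$arr, halo$mask)
  wav <- wavelet_features(halo$arr, halo$mask)
  blocks$laws_a <- laws[1:60]
  blocks$laws_b <- laws[61:74]
  blocks$laws_c <- laws[75:125]
  blocks$wavelet <- wav

  lay <- catalogue_layout()
  out <- unlist(lapply(lay, function(b) {
    v <- as.numeric(blocks[[b$block]])
    stopifnot(length(v) == length(b$names))
    v
  }), use.names = FALSE)
  out <- stats::setNames(out, cat364$id)
  attr(out, "feature_names") <- cat364$name
  attr(out, "settings_digest") <- settings$digest
  out
}

#' Extract features for a cohort of segmented nodules
#'
#' Builds the wide nodule-by-feature table the selection and modelling
#' stages consume: for each observation, the 364 features of the
#' lung-window mask (columns `LW_F*`) and of the difference-region mask
#' (columns `DR_F*`).
#'
#' @param observations a list; each element a list with `volume`
#'   (`ct_volume`), `masks` (a `nodule_mask_set`), and any id fields
#'   (`patient`, `nodule`, `label`, ...) carried into the output.
#' @param settings an [extraction_settings()].
#' @return Tibble, one row per observation.
#' @export
extract_cohort <- function(observations, settings = extraction_settings()) {
  purrr::map_dfr(observations, function(ob) {
    lw <- suppressWarnings(extract_all(ob$volume, ob$masks$lw_mask, settings))
    dr <- suppressWarnings(extract_all(ob$volume, ob$masks$dr_mask, settings))
    meta <- ob[setdiff(names(ob), c("volume", "masks"))]
    tibble::as_tibble(c(
      meta,
      stats::setNames(as.list(lw), paste0("LW_", names(lw))),
      stats::setNames(as.list(dr), paste0("DR_", names(dr)))
    ))
  })
}
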