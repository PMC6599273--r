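## CT window-level transforms, threshold-surrogate segmentation and
## difference-region mask algebra.

#' CT window settings
#'
#' A window maps HU linearly to display grey in \[0, 1\]: values at or below
#' `level - width/2` (the floor) render black, values at or above
#' `level + width/2` (the ceiling) render white. The two canonical settings
#' used in screening reads are the lung window (width 1500 HU, level -400 HU)
#' and the mediastinal window (width 400 HU, level 40 HU): the lung window
#' shows parenchyma and ground-glass, the mediastinal window only
#' soft-tissue-density (solid) material.
#'
#' @param width window width in HU, > 0.
#' @param level window level (centre) in HU.
#' @return A `window_setting`: list with `width`, `level`, `floor`, `ceiling`.
#' @examples
#' lung_window()
#' mediastinal_window()$floor  # -160 HU
#' @export
window_setting <- function(width, level) {
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0) {
    stop("window `width` must be a single positive number (HU)", call. = FALSE)
  }
  structure(
    list(width = width, level = level,
         floor = level - width / 2, ceiling = level + width / 2),
    class = "window_setting"
  )
}

#' @rdname window_setting
#' @export
lung_window <- function() window_setting(1500, -400)

#' @rdname window_setting
#' @export
mediastinal_window <- function() window_setting(400, 40)

#' @export
print.window_setting <- function(x, ...) {
  cat(sprintf("<window_setting> width %g HU, level %g HU (floor %g, ceiling %g)\n",
              x$width, x$level, x$floor, x$ceiling))
  invisible(x)
}

#' Apply a window-level transform
#'
#' Maps HU to display values `clip((HU - floor)/width, 0, 1)`. Monotone in
#' HU; vectorised over arrays.
#'
#' @param volume a `ct_volume` or numeric array/vector of HU values.
#' @param setting a [window_setting()].
#' @return Display values in \[0, 1\], same shape as the input data.
#' @examples
#' apply_window(-400, lung_window())   # 0.5: the level maps to mid-grey
#' apply_window(c(350, -1150), lung_window())
#' @export
apply_window <- function(volume, setting) {
  stopifnot(inherits(setting, "window_setting"))
  hu <- if (inherits(volume, "ct_volume")) volume$data else volume
  pmin(pmax((hu - setting$floor) / setting$width, 0), 1)
}

## default segmentation threshold for a window: the documented surrogate for
## radiologist delineation. Lung window: -750 HU (captures ground-glass,
## excludes ~-850 parenchyma). Any other window: its floor (tissue rendered
## non-black), which for the mediastinal window is -160 HU.
default_threshold <- function(setting) {
  if (setting$width == 1500 && setting$level == -400) -750 else setting$floor
}

#' Threshold-surrogate nodule segmentation under a CT window
#'
#' Deterministic stand-in for semi-automatic radiologist delineation: the
#' mask is the 26-connected component containing `seed_point` of voxels with
#' HU at or above the window's segmentation threshold, followed by one
#' binary-closing pass (3x3x3 structuring element). Default thresholds:
#' -750 HU for the lung window and the window floor otherwise (-160 HU for
#' the mediastinal window).
#'
#' @param volume a `ct_volume`.
#' @param setting a [window_setting()].
#' @param seed_point integer voxel index `c(z, y, x)`, 0-based, inside the
#'   nodule.
#' @param threshold_override optional HU threshold replacing the default.
#' @param on_empty_seed what to do when the seed voxel is below the
#'   threshold: `"error"` (default) or `"empty"` (return an all-FALSE mask
#'   flagged with `attr(, "empty") = TRUE`; legitimate for fully
#'   ground-glass nodules under the mediastinal window).
#' @return Logical 3D mask with attributes `spacing` and `empty`.
#' @export
segment_window <- function(volume, setting, seed_point,
                           threshold_override = NULL,
                           on_empty_seed = c("error", "empty")) {
  stopifnot(inherits(volume, "ct_volume"), inherits(setting, "window_setting"))
  on_empty_seed <- match.arg(on_empty_seed)
  dm <- dim(volume$data)
  seed <- as.integer(seed_point) + 1L  # to 1-based
  if (length(seed) != 3 || any(seed < 1L) || any(seed > dm)) {
    stop("`seed_point` must be a 0-based (z, y, x) voxel index inside the grid",
         call. = FALSE)
  }
  t_w <- threshold_override %||% default_threshold(setting)
  above <- volume$data >= t_w
  if (!above[seed[1], seed[2], seed[3]]) {
    if (on_empty_seed == "error") {
      stop(sprintf("seed not in nodule: voxel HU %.1f is below threshold %.1f",
                   volume$data[seed[1], seed[2], seed[3]], t_w), call. = FALSE)
    }
    m <- array(FALSE, dm)
    attr(m, "spacing") <- volume$spacing
    attr(m, "empty") <- TRUE
    warning("seed voxel below threshold; returning empty mask", call. = FALSE)
    return(m)
  }
  comp <- flood_select(above, seed)
  ## closing is local: run it on the component's padded bounding box
  cb <- crop_bbox(comp, comp, pad = 2L)
  closed <- closing26(cb$mask)
  m <- array(FALSE, dm)
  hi <- cb$origin + dim(closed) - 1L
  m[cb$origin[1]:hi[1], cb$origin[2]:hi[2], cb$origin[3]:hi[3]] <- closed
  attr(m, "spacing") <- volume$spacing
  attr(m, "empty") <- !any(m)
  m
}

#' Difference-region mask algebra
#'
#' The difference region (DR) is the set of voxels inside the lung-window
#' mask but outside the mediastinal-window mask: the non-solid
#' (ground-glass) habitat of a part-solid nodule. Voxelwise `lw & !mw`.
#'
#' @param lw_mask,mw_mask aligned logical 3D masks.
#' @return Logical mask of the same shape.
#' @export
difference_region <- function(lw_mask, mw_mask) {
  if (!identical(dim(lw_mask), dim(mw_mask))) {
    stop("mask shapes differ: lung-window and mediastinal-window masks must be aligned",
         call. = FALSE)
  }
  m <- lw_mask & !mw_mask
  attr(m, "spacing") <- attr(lw_mask, "spacing")
  m
}

#' Physical volume of a binary mask
#'
#' @param mask logical 3D array.
#' @param spacing mm per voxel along (z, y, x); defaults to the mask's
#'   `spacing` attribute.
#' @return Volume in cubic millimetres.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[1:4, 1:5, 1:5] <- TRUE
#' mask_volume(m, spacing = c(0.7, 0.7, 2.5))
#' @export
mask_volume <- function(mask, spacing = attr(mask, "spacing")) {
  if (is.null(spacing)) stop("`spacing` is required", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  sum(mask) * voxel_volume_mm3(spacing)
}

#' Segment a nodule under both windows and build its mask set
#'
#' Runs the lung-window and mediastinal-window segmentations from a shared
#' seed and assembles the difference region. The mediastinal pass tolerates
#' a seed below its threshold (pure ground-glass nodule: empty mediastinal
#' mask, difference region equal to the lung-window mask). When the two
#' thresholds nest (mediastinal above lung, the default), the mediastinal
#' mask is intersected with the lung-window mask so that `mw` is contained
#' in `lw` and `|dr| = |lw| - |mw|` holds exactly.
#'
#' @inheritParams segment_window
#' @param lung,mediastinal window settings.
#' @param t_lung,t_mediastinal optional threshold overrides.
#' @return A `nodule_mask_set`: list with `lw_mask`, `mw_mask`, `dr_mask`,
#'   `seed_point`, `spacing` and a `volumes` tibble (role, voxels, mm3).
#' @export
nodule_masks <- function(volume, seed_point,
                         lung = lung_window(), mediastinal = mediastinal_window(),
                         t_lung = NULL, t_mediastinal = NULL) {
  lw <- segment_window(volume, lung, seed_point, threshold_override = t_lung)
  mw <- suppressWarnings(
    segment_window(volume, mediastinal, seed_point,
                   threshold_override = t_mediastinal, on_empty_seed = "empty")
  )
  tl <- t_lung %||% default_threshold(lung)
  tm <- t_mediastinal %||% default_threshold(mediastinal)
  if (tm >= tl) {
    was_empty <- isTRUE(attr(mw, "empty"))
    sp <- attr(mw, "spacing")
    mw <- mw & lw
    attr(mw, "spacing") <- sp
    attr(mw, "empty") <- was_empty || !any(mw)
  }
  dr <- difference_region(lw, mw)
  vols <- tibble::tibble(
    role = c("lung_window", "mediastinal_window", "difference_region"),
    voxels = c(sum(lw), sum(mw), sum(dr)),
    mm3 = c(mask_volume(lw, volume$spacing), mask_volume(mw, volume$spacing),
            mask_volume(dr, volume$spacing))
  )
  structure(
    list(lw_mask = lw, mw_mask = mw, dr_mask = dr,
         seed_point = as.integer(seed_point), spacing = volume$spacing,
         volumes = vols),
    class = "nodule_mask_set"
  )
}

#' @export
print.nodule_mask_set <- function(x, ...) {
  cat("<nodule_mask_set>\n")
  print(x$volumes)
  invisible(x)
}
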