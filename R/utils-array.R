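## Low-level 3D array helpers shared by the phantom generator, the window
## segmenter and the texture extractor. Axis order everywhere is (z, y, x),
## 1-based voxel indices internally, 0-based in user-facing seed points.

#' Shift a 3D array by an integer offset
#'
#' Returns an array of the same shape with `out[i] = a[i + d]`, i.e. the
#' value of the neighbour at offset `d = c(dz, dy, dx)`; positions whose
#' neighbour falls outside the grid are filled with `fill`.
#'
#' @param a 3D array.
#' @param d integer offset `c(dz, dy, dx)`.
#' @param fill value used outside the grid.
#' @return array of `dim(a)`.
#' @keywords internal
#' @noRd
shift3d <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      n <- dm[ax] - d[ax]
      if (n <= 0) return(out)
      dst[[ax]] <- seq_len(n)
      src[[ax]] <- seq_len(n) + d[ax]
    } else {
      n <- dm[ax] + d[ax]
      if (n <= 0) return(out)
      dst[[ax]] <- seq_len(n) - d[ax]
      src[[ax]] <- seq_len(n)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## The 26 neighbour offsets (all nonzero {−1,0,1}³) and the 13 unique
## 3D directions (one representative per ± pair) used by the texture code.
neighbour_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

directions_13 <- function() {
  off <- neighbour_offsets_26()
  keep <- apply(off, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  off[keep, , drop = FALSE]
}

#' Separable 1D convolution along one axis of a 3D array
#'
#' Correlation with kernel `k` (no flipping; all kernels used in the package
#' are symmetric or antisymmetric so the distinction only flips signs).
#' `boundary` is one of "zero", "replicate", "periodic".
#'
#' @keywords internal
#' @noRd
convolve_axis <- function(a, k, axis, boundary = "replicate", dilation = 1L) {
  nk <- length(k)
  centre <- (nk + 1L) %/% 2L
  dm <- dim(a)
  out <- array(0, dm)
  for (j in seq_len(nk)) {
    if (k[j] == 0) next
    off <- (j - centre) * dilation
    d <- c(0L, 0L, 0L)
    d[axis] <- off
    if (boundary == "periodic") {
      sh <- rotate3d_axis(a, d)
    } else {
      fill <- 0
      sh <- shift3d(a, d, fill = fill)
      if (boundary == "replicate" && off != 0) {
        sh <- replicate_edge(sh, a, d)
      }
    }
    out <- out + k[j] * sh
  }
  out
}

## circular shift (for periodic boundary)
rotate3d_axis <- function(a, d) {
  dm <- dim(a)
  idx <- lapply(1:3, function(ax) {
    if (d[ax] == 0) seq_len(dm[ax]) else ((seq_len(dm[ax]) - 1 + d[ax]) %% dm[ax]) + 1
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

## fill the out-of-range band left by shift3d with the nearest edge plane
replicate_edge <- function(sh, a, d) {
  dm <- dim(a)
  ax <- which(d != 0)
  off <- d[ax]
  n <- abs(off)
  if (n >= dm[ax]) n <- dm[ax]
  idx_all <- lapply(dm, seq_len)
  band <- idx_all
  if (off > 0) {
    band[[ax]] <- (dm[ax] - n + 1):dm[ax]
    edge <- dm[ax]
  } else {
    band[[ax]] <- 1:n
    edge <- 1L
  }
  src <- band
  src[[ax]] <- rep(edge, n)
  sh[band[[1]], band[[2]], band[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  sh
}

#' Separable 3D convolution (kernel per axis, z/y/x order)
#' @keywords internal
#' @noRd
convolve_sep3d <- function(a, kz, ky, kx, boundary = "replicate", dilation = 1L) {
  a <- convolve_axis(a, kz, 1L, boundary, dilation)
  a <- convolve_axis(a, ky, 2L, boundary, dilation)
  convolve_axis(a, kx, 3L, boundary, dilation)
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_gaussian3d <- function(a, sigma) {
  k <- gaussian_kernel_1d(sigma)
  convolve_sep3d(a, k, k, k, boundary = "replicate")
}

## ---- binary morphology (26-connectivity, 3x3x3 structuring element) ----

dilate26 <- function(m) {
  out <- m
  for (i in seq_len(26)) {
    d <- neighbour_offsets_26()[i, ]
    out <- out | shift3d(m, d, fill = FALSE)
  }
  out
}

erode26 <- function(m) {
  out <- m
  for (i in seq_len(26)) {
    d <- neighbour_offsets_26()[i, ]
    out <- out & shift3d(m, d, fill = TRUE)
  }
  out
}

#' One binary closing pass with a 3x3x3 structuring element.
#' The array is padded so dilation at the grid edge behaves as in an
#' unbounded grid.
#' @keywords internal
#' @noRd
closing26 <- function(m) {
  dm <- dim(m)
  p <- array(FALSE, dm + 2L)
  p[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  p <- erode26(dilate26(p))
  p[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
}

#' 26-connected component of `mask` containing `seed` (1-based index vector)
#'
#' Breadth-first flood fill on linear indices of a 1-voxel zero-padded
#' copy, so neighbour arithmetic never wraps across grid faces.
#' @keywords internal
#' @noRd
flood_select <- function(mask, seed) {
  stopifnot(length(seed) == 3)
  dm <- dim(mask)
  pdm <- dm + 2L
  pm <- array(FALSE, pdm)
  pm[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  comp <- array(FALSE, dm)
  if (!mask[seed[1], seed[2], seed[3]]) return(comp)
  offs <- neighbour_offsets_26()
  steps <- offs[, 1] + offs[, 2] * pdm[1] + offs[, 3] * pdm[1] * pdm[2]
  s <- seed + 1L
  lin <- s[1] + (s[2] - 1) * pdm[1] + (s[3] - 1) * pdm[1] * pdm[2]
  visited <- array(FALSE, pdm)
  visited[lin] <- TRUE
  frontier <- lin
  while (length(frontier)) {
    cand <- unique(as.vector(outer(frontier, steps, `+`)))
    cand <- cand[pm[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  comp_p <- visited & pm
  comp[] <- comp_p[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  comp
}

#' Label 26-connected zones of constant value
#'
#' Labels every maximal 26-connected region of `levels` (an integer array)
#' restricted to `mask`. Returns an integer array, 0 outside the mask,
#' with arbitrary but deterministic positive labels per zone.
#' Implemented by iterated label propagation (max over equal-level
#' neighbours), which is fully vectorised.
#'
#' @keywords internal
#' @noRd
label_zones <- function(levels, mask) {
  dm <- dim(levels)
  lab <- array(0L, dm)
  lab[mask] <- which(mask)  # linear index as initial label
  lev <- array(-1L, dm)
  lev[mask] <- levels[mask]
  offs <- neighbour_offsets_26()
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      d <- offs[i, ]
      nl <- shift3d(lab, d, fill = 0L)
      nv <- shift3d(lev, d, fill = -2L)
      upd <- mask & (nv == lev) & (nl > new)
      new[upd] <- nl[upd]
    }
    if (all(new == lab)) break
    lab <- new
  }
  ## compact labels to 1..K
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

## crop an array to the bounding box of a mask, optionally padded (clamped
## to the grid); returns list(arr, mask, origin)
crop_bbox <- function(a, mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(mask))
  list(
    arr = a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    origin = lo
  )
}
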