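## IBSI-style feature families. All texture families use a fixed 32-bin
## discretization within the mask's HU range, distance-1 neighbourhoods and
## the 13 unique 3D directions. Percentiles use the inverted-ECDF
## (sort-and-index, quantile type 1) convention throughout.

q_type1 <- function(x, p) stats::quantile(x, p, type = 1, names = FALSE)

## ---- intensity statistics (25) ----

stats_features <- function(vals) {
  n <- length(vals)
  m <- mean(vals)
  v <- mean((vals - m)^2)  # population variance
  s <- sqrt(v)
  skew <- if (s > 0) mean((vals - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((vals - m)^4) / s^4 - 3 else 0
  p10 <- q_type1(vals, 0.10); p90 <- q_type1(vals, 0.90)
  p25 <- q_type1(vals, 0.25); p75 <- q_type1(vals, 0.75)
  mid <- vals[vals >= p10 & vals <= p90]
  med <- stats::median(vals)
  c(
    m, v, skew, kurt, med, min(vals), q_type1(vals, 0.05), p10, p25,
    p75, p90, q_type1(vals, 0.95), max(vals), p75 - p25,
    max(vals) - min(vals), mean(abs(vals - m)),
    mean(abs(mid - mean(mid))), stats::median(abs(vals - med)),
    sqrt(mean(vals^2)), sum(vals^2),
    if (m != 0) s / m else NA_real_,
    if ((p75 + p25) != 0) (p75 - p25) / (p75 + p25) else NA_real_,
    s, sum(vals), n
  )
}

## ---- intensity-volume histogram (21) ----

ivh_features <- function(vals) {
  rng <- range(vals)
  frac <- seq(0.10, 0.90, 0.10)
  if (rng[2] == rng[1]) {
    iv <- rep(rng[1], 9)
    vv <- rep(1, 9)
    return(c(iv, 0, vv, 0, 1))
  }
  n <- length(vals)
  ## V(i): fraction of voxels with intensity >= i
  vfrac <- function(i) mean(vals >= i)
  ## intensity at volume fraction nu: the largest intensity i with V(i) >= nu
  ifrac <- function(nu) {
    sv <- sort(vals, decreasing = TRUE)
    sv[max(1L, floor(nu * n))]
  }
  iv <- vapply(frac, ifrac, numeric(1))
  lev <- rng[1] + frac * diff(rng)
  vv <- vapply(lev, vfrac, numeric(1))
  grid <- rng[1] + seq(0, 1, 0.01) * diff(rng)
  auc <- mean(vapply(grid, vfrac, numeric(1)))
  c(iv, iv[1] - iv[9], vv, vv[1] - vv[9], auc)
}

## ---- discretization ----

discretize_fbn <- function(vals, n_bins = 32L) {
  rng <- range(vals)
  if (rng[2] == rng[1]) return(rep(1L, length(vals)))
  lev <- floor(n_bins * (vals - rng[1]) / (rng[2] - rng[1])) + 1L
  pmin(lev, n_bins)
}

## ---- intensity histogram (25) on discretized levels ----

hist_features <- function(lev, n_bins = 32L) {
  n <- length(lev)
  p <- tabulate(lev, n_bins) / n
  m <- mean(lev)
  v <- mean((lev - m)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((lev - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((lev - m)^4) / s^4 - 3 else 0
  p10 <- q_type1(lev, 0.10); p90 <- q_type1(lev, 0.90)
  p25 <- q_type1(lev, 0.25); p75 <- q_type1(lev, 0.75)
  mid <- lev[lev >= p10 & lev <= p90]
  med <- stats::median(lev)
  cnt <- tabulate(lev, n_bins)
  grad <- diff(cnt)
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  c(
    m, v, skew, kurt, med, min(lev), p10, p25, p75, p90, max(lev),
    which.max(cnt), p75 - p25, max(lev) - min(lev),
    mean(abs(lev - m)), mean(abs(mid - mean(mid))),
    stats::median(abs(lev - med)),
    if (m != 0) s / m else NA_real_,
    if ((p75 + p25) != 0) (p75 - p25) / (p75 + p25) else NA_real_,
    ent, sum(p^2),
    if (length(grad)) max(grad) else NA_real_,
    if (length(grad)) which.max(grad) else NA_real_,
    if (length(grad)) min(grad) else NA_real_,
    if (length(grad)) which.min(grad) else NA_real_
  )
}

## ---- morphology (29) ----

## surface area by the co-area formula: integral of |grad| of the
## Gaussian-smoothed (sigma 1 voxel) indicator function
surface_area_coarea <- function(mask, spacing) {
  cb <- crop_bbox(mask, mask, pad = 5L)
  chi <- array(as.numeric(cb$mask), dim(cb$mask))
  ## pad so smoothing sees zeros beyond the grid edge
  dm <- dim(chi)
  p <- array(0, dm + 10L)
  p[6:(dm[1] + 5), 6:(dm[2] + 5), 6:(dm[3] + 5)] <- chi
  sm <- smooth_gaussian3d(p, 1.0)
  gz <- (shift3d(sm, c(1L, 0L, 0L)) - shift3d(sm, c(-1L, 0L, 0L))) / (2 * spacing[1])
  gy <- (shift3d(sm, c(0L, 1L, 0L)) - shift3d(sm, c(0L, -1L, 0L))) / (2 * spacing[2])
  gx <- (shift3d(sm, c(0L, 0L, 1L)) - shift3d(sm, c(0L, 0L, -1L))) / (2 * spacing[3])
  sum(sqrt(gz^2 + gy^2 + gx^2)) * voxel_volume_mm3(spacing)
}

## boundary voxels: in mask with at least one 6-neighbour outside
boundary_voxels <- function(mask) {
  inner <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    d <- c(0L, 0L, 0L); d[ax] <- s
    inner <- inner & shift3d(mask, d, fill = FALSE)
  }
  mask & !inner
}

morph_features <- function(volume_arr, mask, spacing, origin = c(1L, 1L, 1L)) {
  vv <- voxel_volume_mm3(spacing)
  nv <- sum(mask)
  V <- nv * vv
  A <- surface_area_coarea(mask, spacing)
  idx <- which(mask, arr.ind = TRUE)
  idx <- sweep(idx, 2, origin - 1L, `+`)  # grid-absolute voxel indices
  coords <- sweep(idx, 2, spacing, `*`)  # mm, (z,y,x)
  com <- colMeans(coords)
  hu <- volume_arr[mask]
  w <- pmax(hu + 1000, 0)  # attenuation above air; keeps weights nonnegative
  wcom <- if (sum(w) > 0) colSums(coords * w) / sum(w) else com
  if (nv >= 2) {
    cv <- stats::cov(coords) * (nv - 1) / nv
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  bv <- which(boundary_voxels(mask), arr.ind = TRUE)
  if (nrow(bv) > 1500) bv <- bv[seq(1, nrow(bv), length.out = 1500), , drop = FALSE]
  bc <- sweep(bv, 2, spacing, `*`)
  maxdiam <- if (nrow(bc) > 1) {
    d2 <- as.matrix(stats::dist(bc))
    max(d2)
  } else 0
  bbox <- apply(idx, 2, function(i) diff(range(i)) + 1) * spacing
  aee_vol <- (4 / 3) * pi * prod(axes / 2)
  ## Thomsen approximation for ellipsoid surface area
  ae <- axes / 2
  pth <- 1.6075
  aee_area <- 4 * pi * ((ae[1]^pth * ae[2]^pth + ae[1]^pth * ae[3]^pth +
                           ae[2]^pth * ae[3]^pth) / 3)^(1 / pth)
  sph <- (36 * pi * V^2)^(1 / 3) / A
  c(
    V, A, A / V,
    V / (sqrt(pi) * A^(3 / 2)), 36 * pi * V^2 / A^3,
    1 / sph, sph, (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    maxdiam, axes[1], axes[2], axes[3],
    if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_,
    sqrt(sum((wcom - com)^2)),
    wcom[1], wcom[2], wcom[3], com[1], com[2], com[3],
    V / prod(bbox), A / (2 * (bbox[1] * bbox[2] + bbox[1] * bbox[3] + bbox[2] * bbox[3])),
    if (aee_vol > 0) V / aee_vol else NA_real_,
    if (aee_area > 0) A / aee_area else NA_real_,
    mean(hu) * V, prod(bbox),
    (6 * V / pi)^(1 / 3), pi^(1 / 3) * (6 * V)^(2 / 3)
  )
}

## ---- local intensity (2): sphere-mean peaks, 1 cm^3 neighbourhood ----

local_features <- function(volume_arr, mask, spacing) {
  r_mm <- (3 / (4 * pi) * 1000)^(1 / 3)  # 1 cm^3 sphere -> 6.2 mm
  rv <- ceiling(r_mm / spacing)
  offs <- as.matrix(expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3]))
  keep <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
                 (offs[, 3] * spacing[3])^2) <= r_mm
  offs <- offs[keep, , drop = FALSE]
  dm <- dim(volume_arr)
  pad <- max(rv)
  pdm <- dm + 2L * pad
  p <- array(NA_real_, pdm)
  p[pad + seq_len(dm[1]), pad + seq_len(dm[2]), pad + seq_len(dm[3])] <- volume_arr
  idx <- which(mask, arr.ind = TRUE) + pad
  lin <- idx[, 1] + (idx[, 2] - 1) * pdm[1] + (idx[, 3] - 1) * pdm[1] * pdm[2]
  steps <- offs[, 1] + offs[, 2] * pdm[1] + offs[, 3] * pdm[1] * pdm[2]
  gather <- outer(lin, steps, `+`)
  sphere_means <- rowMeans(matrix(p[gather], nrow = length(lin)), na.rm = TRUE)
  hu <- volume_arr[mask]
  c(max(sphere_means[hu == max(hu)]), max(sphere_means))
}

## ---- grey-level co-occurrence (GLCM) ----

glcm_count_pairs <- function(lev_arr, mask, d, n_bins) {
  ls <- shift3d(lev_arr, d, fill = 0L)
  ms <- shift3d(mask, d, fill = FALSE)
  valid <- mask & ms
  if (!any(valid)) return(matrix(0, n_bins, n_bins))
  i <- lev_arr[valid]; j <- ls[valid]
  cnt <- tabulate(i + n_bins * (j - 1L), nbins = n_bins * n_bins)
  M <- matrix(cnt, n_bins, n_bins)
  M + t(M)  # symmetric: count both orientations
}

glcm_features_from_p <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(rep(NA_real_, 25))
  P <- P / tot
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_ <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  pd <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))     # diff dist, k = 0..ng-1
  ps <- as.vector(rowsum(as.vector(P), as.vector(i + j)))          # sum dist, k = 2..2ng
  if (length(pd) < ng) pd <- c(pd, rep(0, ng - length(pd)))
  if (length(ps) < 2 * ng - 1) ps <- c(ps, rep(0, 2 * ng - 1 - length(ps)))
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  da <- sum(kd * pd); dv <- sum((kd - da)^2 * pd)
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  sa <- sum(ks * ps); sv <- sum((ks - sa)^2 * ps)
  se <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pipj <- outer(pi_, pi_)
  hxy1 <- -sum(P[pipj > 0] * log2(pipj[pipj > 0]))
  hxy2 <- -sum(pipj[pipj > 0] * log2(pipj[pipj > 0]))
  hx <- -sum(pi_[pi_ > 0] * log2(pi_[pi_ > 0]))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  imc2 <- if (hxy2 >= hxy) sqrt(1 - 2^(-2 * (hxy2 - hxy))) else NA_real_
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else NA_real_
  invvar_mask <- i != j
  c(
    max(P), mu, sig2, hxy,
    da, dv, de, sa, sv, se,
    sum(P^2), sum((i - j)^2 * P), sum(abs(i - j) * P),
    sum(P / (1 + abs(i - j))), sum(P / (1 + abs(i - j) / ng)),
    sum(P / (1 + (i - j)^2)), sum(P / (1 + (i - j)^2 / ng^2)),
    if (any(P[invvar_mask] > 0)) sum(P[invvar_mask] / (i - j)[invvar_mask]^2) else 0,
    corr, sum(i * j * P),
    sum((i + j - 2 * mu)^2 * P), sum((i + j - 2 * mu)^3 * P),
    sum((i + j - 2 * mu)^4 * P), imc1, imc2
  )
}

glcm_features <- function(lev_arr, mask, n_bins, merged = FALSE) {
  dirs <- directions_13()
  if (merged) {
    M <- matrix(0, n_bins, n_bins)
    for (r in seq_len(nrow(dirs))) {
      M <- M + glcm_count_pairs(lev_arr, mask, dirs[r, ], n_bins)
    }
    return(glcm_features_from_p(M))
  }
  per <- vapply(seq_len(nrow(dirs)), function(r) {
    glcm_features_from_p(glcm_count_pairs(lev_arr, mask, dirs[r, ], n_bins))
  }, numeric(25))
  rowMeans(per, na.rm = FALSE)
}

## ---- grey-level run length (GLRLM) ----

glrlm_matrix <- function(lev_arr, mask, d, n_bins, max_len) {
  dm <- dim(lev_arr)
  step <- d[1] + d[2] * dm[1] + d[3] * dm[1] * dm[2]
  ms <- shift3d(mask, d, fill = FALSE)
  ls <- shift3d(lev_arr, d, fill = 0L)
  sn <- mask & ms & (lev_arr == ls)        # run continues from v to v+d
  sp <- shift3d(sn, -d, fill = FALSE)      # run continues into v
  starts <- which(mask & !sp)
  lev0 <- lev_arr[starts]
  len <- rep(1L, length(starts))
  cur <- starts
  alive <- sn[cur]
  while (any(alive)) {
    cur[alive] <- cur[alive] + step
    len[alive] <- len[alive] + 1L
    alive[alive] <- sn[cur[alive]]
  }
  len <- pmin(len, max_len)
  M <- matrix(0, n_bins, max_len)
  tab <- tabulate(lev0 + n_bins * (len - 1L), nbins = n_bins * max_len)
  matrix(tab, n_bins, max_len)
}

rl_features_from_matrix <- function(M, n_voxels, size_weighted = TRUE) {
  ## shared 16-feature formulation for run-length and size-zone matrices
  ns <- sum(M)
  if (ns == 0) return(rep(NA_real_, 16))
  ng <- nrow(M); nl <- ncol(M)
  i <- matrix(seq_len(ng), ng, nl)
  l <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- M / ns
  ri <- rowSums(M); rl <- colSums(M)
  li <- seq_len(nl); gi <- seq_len(ng)
  mu_g <- sum(i * p); mu_l <- sum(l * p)
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  c(
    sum(rl / li^2) / ns, sum(rl * li^2) / ns,
    sum(ri / gi^2) / ns, sum(ri * gi^2) / ns,
    sum(M / (i^2 * l^2)) / ns, sum(M * i^2 / l^2) / ns,
    sum(M * l^2 / i^2) / ns, sum(M * i^2 * l^2) / ns,
    sum(ri^2) / ns, sum(ri^2) / ns^2,
    sum(rl^2) / ns, sum(rl^2) / ns^2,
    ns / n_voxels,
    sum((i - mu_g)^2 * p), sum((l - mu_l)^2 * p), ent
  )
}

glrlm_features <- function(lev_arr, mask, n_bins) {
  dirs <- directions_13()
  max_len <- max(dim(lev_arr))
  nv <- sum(mask)
  per <- vapply(seq_len(nrow(dirs)), function(r) {
    M <- glrlm_matrix(lev_arr, mask, dirs[r, ], n_bins, max_len)
    rl_features_from_matrix(M, nv)
  }, numeric(16))
  rowMeans(per, na.rm = FALSE)
}

## ---- grey-level size zone (GLSZM) ----

glszm_features <- function(lev_arr, mask, n_bins) {
  lab <- label_zones(lev_arr, mask)
  nz <- max(lab)
  if (nz == 0) return(rep(NA_real_, 16))
  sizes <- tabulate(lab[lab > 0], nz)
  flat_lab <- lab[lab > 0]; flat_lev <- lev_arr[lab > 0]
  ord <- order(flat_lab)
  zl <- flat_lev[ord][!duplicated(flat_lab[ord])]
  max_size <- max(sizes)
  M <- matrix(tabulate(zl + n_bins * (sizes - 1L), nbins = n_bins * max_size),
              n_bins, max_size)
  rl_features_from_matrix(M, sum(mask))
}

## ---- neighbouring grey level dependence (NGLDM), coarseness 0, dist 1 ----

ngldm_features <- function(lev_arr, mask, n_bins) {
  offs <- neighbour_offsets_26()
  dep <- array(0L, dim(lev_arr))
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    same <- mask & shift3d(mask, d, fill = FALSE) &
      (lev_arr == shift3d(lev_arr, d, fill = 0L))
    dep <- dep + same
  }
  k <- dep[mask] + 1L  # dependence count including the voxel itself
  i <- lev_arr[mask]
  nk <- max(k)
  M <- matrix(tabulate(i + n_bins * (k - 1L), nbins = n_bins * nk), n_bins, nk)
  ns <- sum(M)
  gi <- seq_len(n_bins); ki <- seq_len(nk)
  im <- matrix(gi, n_bins, nk); km <- matrix(ki, n_bins, nk, byrow = TRUE)
  p <- M / ns
  si <- rowSums(M); sk <- colSums(M)
  mu_g <- sum(im * p); mu_k <- sum(km * p)
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  c(
    sum(sk / ki^2) / ns, sum(sk * ki^2) / ns,
    sum(si / gi^2) / ns, sum(si * gi^2) / ns,
    sum(M / (im^2 * km^2)) / ns, sum(M * im^2 / km^2) / ns,
    sum(M * km^2 / im^2) / ns, sum(M * im^2 * km^2) / ns,
    sum(si^2) / ns, sum(si^2) / ns^2,
    sum(sk^2) / ns, sum(sk^2) / ns^2,
    ns / sum(mask),
    sum((im - mu_g)^2 * p), sum((km - mu_k)^2 * p), ent, sum(p^2)
  )
}

## ---- neighbourhood grey tone difference (NGTDM) ----

ngtdm_features <- function(lev_arr, mask, n_bins) {
  offs <- neighbour_offsets_26()
  acc <- array(0, dim(lev_arr)); cnt <- array(0, dim(lev_arr))
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    ms <- shift3d(mask, d, fill = FALSE)
    ls <- shift3d(lev_arr, d, fill = 0L)
    acc <- acc + ifelse(ms, ls, 0)
    cnt <- cnt + ms
  }
  use <- mask & cnt > 0
  if (!any(use)) return(rep(NA_real_, 5))
  nbar <- acc[use] / cnt[use]
  lv <- lev_arr[use]
  N <- sum(use)
  ni <- tabulate(lv, n_bins)
  si <- vapply(seq_len(n_bins), function(g) sum(abs(g - nbar[lv == g])), numeric(1))
  pi_ <- ni / N
  pres <- which(pi_ > 0)
  ngp <- length(pres)
  coarse <- if (sum(pi_ * si) > 0) 1 / sum(pi_ * si) else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pi_[pres], pi_[pres]) * outer(pres, pres, `-`)^2) /
       (ngp * (ngp - 1))) * sum(si) / N
  } else 0
  busy_den <- sum(abs(outer(pres * pi_[pres], pres * pi_[pres], `-`)))
  busy <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
  cplx <- if (N > 0 && ngp > 0) {
    pp <- outer(pi_[pres], pi_[pres])
    ss <- outer(pi_[pres] * si[pres], pi_[pres] * si[pres], `+`)
    sum(abs(outer(pres, pres, `-`)) * ss / (outer(pi_[pres], pi_[pres], `+`))) / N
  } else 0
  strength <- if (sum(si) > 0) {
    sum(outer(pi_[pres], pi_[pres], `+`) * outer(pres, pres, `-`)^2) / sum(si)
  } else 0
  c(coarse, contrast, busy, cplx, strength)
}
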