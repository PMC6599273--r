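# Shared fixtures and independent oracles, built in code.

# uniform-background volume with a solid sphere (core_hu) of radius r_vox
# and optionally a concentric ground-glass shell out to r_out_vox
make_sphere_volume <- function(dim = c(24, 24, 24), centre = (dim + 1) / 2,
                               r_core = 6, r_out = NULL,
                               background = -850, core_hu = 40, rim_hu = -500,
                               spacing = c(1, 1, 1), noise_sd = 0, seed = 42) {
  set.seed(seed)
  a <- array(background, dim)
  idx <- which(array(TRUE, dim), arr.ind = TRUE)
  d <- sqrt(((idx[, 1] - centre[1]) * spacing[1])^2 +
              ((idx[, 2] - centre[2]) * spacing[2])^2 +
              ((idx[, 3] - centre[3]) * spacing[3])^2)
  if (!is.null(r_out)) a[d <= r_out] <- rim_hu
  a[d <= r_core] <- core_hu
  if (noise_sd > 0) a <- a + array(rnorm(prod(dim), 0, noise_sd), dim)
  ct_volume(a, spacing = spacing, day = 0)
}

# brute-force voxel-loop count of lw & !mw (oracle for mask algebra)
oracle_diff_count <- function(lw, mw) {
  n <- 0L
  for (k in seq_len(length(lw))) {
    if (lw[[k]] && !mw[[k]]) n <- n + 1L
  }
  n
}

# exhaustive pair-counting AUROC oracle: fraction of (pos, neg) pairs
# correctly ordered, ties get half credit
oracle_auroc_pairs <- function(score, y) {
  pos <- score[y == 1]; neg <- score[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# brute-force full 3D correlation of a separable Laws kernel triple
oracle_laws_response <- function(arr, kz, ky, kx) {
  dm <- dim(arr)
  pad <- 2L
  # replicate-padded array
  p <- array(0, dm + 2L * pad)
  for (z in seq_len(dm[1] + 4)) for (y in seq_len(dm[2] + 4)) for (x in seq_len(dm[3] + 4)) {
    p[z, y, x] <- arr[min(max(z - pad, 1), dm[1]),
                      min(max(y - pad, 1), dm[2]),
                      min(max(x - pad, 1), dm[3])]
  }
  out <- array(0, dm)
  for (z in seq_len(dm[1])) for (y in seq_len(dm[2])) for (x in seq_len(dm[3])) {
    acc <- 0
    for (a in -2:2) for (b in -2:2) for (d in -2:2) {
      acc <- acc + kz[a + 3] * ky[b + 3] * kx[d + 3] *
        p[z + pad + a, y + pad + b, x + pad + d]
    }
    out[z, y, x] <- acc
  }
  out
}

# brute-force connected components of a correlation graph (oracle for
# correlation pruning): returns component id per feature
oracle_graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (adj[a, b] && comp[b] != comp[a]) {
        m <- min(comp[a], comp[b])
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

small_cohort_config <- function(n = 8, seed = 11, ...) {
  phantom_config(n_patients = n, seed = seed, ...)
}
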