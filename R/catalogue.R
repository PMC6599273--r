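## The 364-feature catalogue: 209 IBSI-style features, 125 Laws texture
## energies, 30 stationary-wavelet sub-band features. Index anchors fixed by
## convention: F8 statistical 10th percentile, F19 root mean square, F44
## volume at intensity fraction 90, F87 weighted CoM_z, F296 a level-2
## wavelet sub-band feature, F311 voxel dimension x. The remaining
## identities are fixed by this shipped catalogue.

ibsi_stat_names <- function() c(
  "stat_mean", "stat_variance", "stat_skewness", "stat_kurtosis",
  "stat_median", "stat_minimum", "stat_p5", "stat_p10", "stat_p25",
  "stat_p75", "stat_p90", "stat_p95", "stat_maximum", "stat_iqr",
  "stat_range", "stat_mean_abs_dev", "stat_robust_mean_abs_dev",
  "stat_median_abs_dev", "stat_rms", "stat_energy", "stat_cov",
  "stat_qcod", "stat_sd", "stat_sum", "stat_n_voxels"
)

ibsi_ivh_names <- function() c(
  paste0("ivh_i", seq(10, 90, 10)), "ivh_i10_minus_i90",
  paste0("ivh_v", seq(10, 90, 10)), "ivh_v10_minus_v90", "ivh_auc"
)

ibsi_hist_names <- function() c(
  "hist_mean", "hist_variance", "hist_skewness", "hist_kurtosis",
  "hist_median", "hist_min_level", "hist_p10", "hist_p25", "hist_p75",
  "hist_p90", "hist_max_level", "hist_mode", "hist_iqr", "hist_range",
  "hist_mean_abs_dev", "hist_robust_mean_abs_dev", "hist_median_abs_dev",
  "hist_cov", "hist_qcod", "hist_entropy", "hist_uniformity",
  "hist_max_gradient", "hist_max_gradient_level", "hist_min_gradient",
  "hist_min_gradient_level"
)

ibsi_morph_names <- function() c(
  "morph_volume", "morph_surface_area", "morph_surface_to_volume",
  "morph_compactness1", "morph_compactness2", "morph_spherical_disproportion",
  "morph_sphericity", "morph_asphericity", "morph_max_3d_diameter",
  "morph_major_axis", "morph_minor_axis", "morph_least_axis",
  "morph_elongation", "morph_flatness", "morph_com_shift",
  "morph_weighted_com_z", "morph_weighted_com_y", "morph_weighted_com_x",
  "morph_com_z", "morph_com_y", "morph_com_x",
  "morph_vol_density_aabb", "morph_area_density_aabb",
  "morph_vol_density_aee", "morph_area_density_aee",
  "morph_integrated_intensity", "morph_bbox_volume",
  "morph_equiv_sphere_diameter", "morph_equiv_sphere_area"
)

ibsi_glcm_names <- function(prefix = "glcm") paste0(prefix, "_", c(
  "joint_max", "joint_average", "joint_variance", "joint_entropy",
  "diff_average", "diff_variance", "diff_entropy", "sum_average",
  "sum_variance", "sum_entropy", "energy", "contrast", "dissimilarity",
  "inv_diff", "inv_diff_norm", "inv_diff_mom", "inv_diff_mom_norm",
  "inv_variance", "correlation", "autocorrelation", "cluster_tendency",
  "cluster_shade", "cluster_prominence", "imc1", "imc2"
))

ibsi_glrlm_names <- function() paste0("glrlm_", c(
  "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
  "glnu", "glnu_norm", "rlnu", "rlnu_norm", "run_pct",
  "gl_variance", "rl_variance", "run_entropy"
))

ibsi_glszm_names <- function() paste0("glszm_", c(
  "sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
  "glnu", "glnu_norm", "zsnu", "zsnu_norm", "zone_pct",
  "gl_variance", "zs_variance", "zone_entropy"
))

ibsi_ngldm_names <- function() paste0("ngldm_", c(
  "lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge", "hdhge",
  "glnu", "glnu_norm", "dcnu", "dcnu_norm", "dc_pct",
  "gl_variance", "dc_variance", "dc_entropy", "dc_energy"
))

ibsi_ngtdm_names <- function() paste0("ngtdm_", c(
  "coarseness", "contrast", "busyness", "complexity", "strength"
))

laws_kernel_names <- function() c("L5", "E5", "S5", "W5", "R5")

## 125 Laws triples in lexicographic (z, y, x) order
laws_feature_names <- function() {
  k <- laws_kernel_names()
  g <- expand.grid(x = k, y = k, z = k, stringsAsFactors = FALSE)[, c("z", "y", "x")]
  g <- g[order(match(g$z, k), match(g$y, k), match(g$x, k)), ]
  paste0("laws_", g$z, g$y, g$x)
}

wavelet_subband_names <- function() {
  l1 <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  l2 <- setdiff(l1, "LLL")
  list(level1 = l1, level2 = l2)
}

wavelet_feature_names <- function() {
  sb <- wavelet_subband_names()
  c(
    as.vector(vapply(sb$level1, function(s)
      paste0("wav_L1_", s, c("_energy", "_entropy")), character(2))),
    as.vector(vapply(sb$level2, function(s)
      paste0("wav_L2_", s, c("_energy", "_entropy")), character(2)))
  )
}

## Block layout in catalogue index order. Single source of truth shared by
## the catalogue and the extractor assembly.
catalogue_layout <- function() {
  laws <- laws_feature_names()
  list(
    list(block = "stats",       family = "ibsi",    names = ibsi_stat_names()),
    list(block = "ivh",         family = "ibsi",    names = ibsi_ivh_names()),
    list(block = "hist",        family = "ibsi",    names = ibsi_hist_names()),
    list(block = "morph",       family = "ibsi",    names = ibsi_morph_names()),
    list(block = "local",       family = "ibsi",    names = c("loc_peak_local", "loc_peak_global")),
    list(block = "glcm",        family = "ibsi",    names = ibsi_glcm_names("glcm")),
    list(block = "glrlm",       family = "ibsi",    names = ibsi_glrlm_names()),
    list(block = "glszm",       family = "ibsi",    names = ibsi_glszm_names()),
    list(block = "ngldm",       family = "ibsi",    names = ibsi_ngldm_names()),
    list(block = "ngtdm",       family = "ibsi",    names = ibsi_ngtdm_names()),
    list(block = "glcm_merged", family = "ibsi",    names = ibsi_glcm_names("glcmm")),
    list(block = "laws_a",      family = "laws",    names = laws[1:60]),
    list(block = "wavelet",     family = "wavelet", names = wavelet_feature_names()),
    list(block = "laws_b",      family = "laws",    names = laws[61:74]),
    list(block = "voxdim",      family = "ibsi",    names = c("meta_voxel_dim_x", "meta_voxel_dim_y", "meta_voxel_dim_z")),
    list(block = "laws_c",      family = "laws",    names = laws[75:125])
  )
}

#' The 364-feature catalogue
#'
#' Ordered descriptor table of every feature the extractor emits: 209
#' IBSI-style features (intensity statistics, intensity-volume histogram,
#' intensity histogram, morphology, local intensity, GLCM averaged and
#' merged over the 13 unique 3D directions, GLRLM, GLSZM, NGLDM, NGTDM,
#' voxel-dimension metadata), 125 Laws texture energies (all 5^3 separable
#' kernels from L5/E5/S5/W5/R5), and 30 stationary-wavelet sub-band
#' features (energy and entropy for the 8 level-1 and 7 level-2 detail
#' sub-bands, coif1). Fixed anchors: F8 statistical 10th percentile, F19
#' root mean square, F44 volume at intensity fraction 90, F87 weighted
#' CoM_z, F296 a level-2 wavelet sub-band feature, F311 voxel dimension x.
#'
#' @return Tibble with columns `index`, `id` (`F1`..`F364`), `family`
#'   (`ibsi`/`laws`/`wavelet`), `block`, `name`.
#' @examples
#' cat364 <- feature_catalogue()
#' nrow(cat364)           # 364
#' table(cat364$family)   # ibsi 209, laws 125, wavelet 30
#' cat364$name[cat364$id == "F8"]
#' @export
feature_catalogue <- function() {
  lay <- catalogue_layout()
  out <- purrr::map_dfr(lay, function(b) {
    tibble::tibble(family = b$family, block = b$block, name = b$names)
  })
  out <- dplyr::mutate(out, index = dplyr::row_number(),
                       id = paste0("F", .data$index))
  dplyr::select(out, "index", "id", "family", "block", "name")
}
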