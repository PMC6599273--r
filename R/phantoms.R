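## Synthetic longitudinal part-solid nodule phantoms.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: screen-detected nodules followed over 1-2 annual intervals,
## per-interval volume-doubling times straddling the 400-day
## indolent/aggressive threshold, part-solid morphology (a solid core
## visible in the mediastinal window inside a ground-glass rim visible only
## in the lung window), a planted class-conditional rim-volume-fraction
## effect, and clinical covariates (sex, COPD) whose class association
## mirrors the screening cohort.

#' Phantom cohort configuration
#'
#' All defaults are the study conditions the package is designed around:
#' 26% indolent nodules, median VDTs near 583 (indolent) and 148
#' (aggressive) days, annual screening intervals, roughly a third of
#' patients with three scans of whom roughly half show a mixed growth
#' pattern, female fraction 0.70 / 0.31 and COPD fraction 0 / 0.21 in the
#' indolent / aggressive class.
#'
#' @param n_patients number of patients.
#' @param timepoints maximum scans per patient, 2 or 3.
#' @param three_tp_fraction fraction of patients with three scans (used
#'   only when `timepoints = 3`).
#' @param grid_shape voxels per axis (z, y, x).
#' @param voxel_spacing mm per voxel (z, y, x).
#' @param background_hu `c(mean, sd)`: lung parenchyma HU and additive
#'   Gaussian noise sd.
#' @param core_hu HU range of the solid core, drawn uniformly per nodule.
#' @param rim_hu HU range of the ground-glass rim, drawn uniformly per
#'   nodule.
#' @param indolent_fraction probability a patient's base class is indolent.
#' @param vdt_indolent,vdt_aggressive `c(meanlog, sdlog)` of the log-normal
#'   VDT distribution per class (days). Indolent draws are truncated to
#'   (400, 3000], aggressive draws to \[130, 400) so classes respect the
#'   400-day rule and nodules stay inside the grid.
#' @param mixed_fraction probability that a three-scan patient switches
#'   class between its two intervals.
#' @param mixed_direction_prob probability a mixed patient re-classifies
#'   indolent-to-aggressive (vs aggressive-to-indolent).
#' @param rim_fraction_by_class list of Beta parameters `c(shape1, shape2)`
#'   per class for the rim-to-total volume fraction: the planted radiomic
#'   effect.
#' @param clinical_odds list of per-covariate class-conditional
#'   probabilities, `list(sex = c(indolent=, aggressive=), copd = ...)`
#'   (`sex` is the probability of female).
#' @param outer_radius_mm range of the baseline outer (rim) radius.
#' @param interval_days range of days between consecutive scans.
#' @param noise_sd deprecated alias, see `background_hu[2]`.
#' @param seed integer RNG seed.
#' @return A validated `phantom_config` list.
#' @examples
#' cfg <- phantom_config(n_patients = 4, seed = 7)
#' cfg$indolent_fraction
#' @export
phantom_config <- function(n_patients = 114,
                           timepoints = 3,
                           three_tp_fraction = 36 / 114,
                           grid_shape = c(72, 72, 72),
                           voxel_spacing = c(1, 1, 1),
                           background_hu = c(-850, 20),
                           core_hu = c(20, 60),
                           rim_hu = c(-650, -350),
                           indolent_fraction = 0.26,
                           vdt_indolent = c(meanlog = log(583), sdlog = 0.20),
                           vdt_aggressive = c(meanlog = log(148), sdlog = 0.15),
                           mixed_fraction = 17 / 36,
                           mixed_direction_prob = 12 / 17,
                           rim_fraction_by_class = list(
                             indolent = c(shape1 = 9, shape2 = 6),
                             aggressive = c(shape1 = 5.25, shape2 = 9.75)
                           ),
                           clinical_odds = list(
                             sex = c(indolent = 0.70, aggressive = 0.3117),
                             copd = c(indolent = 0.00, aggressive = 0.2078)
                           ),
                           outer_radius_mm = c(4.2, 5.4),
                           interval_days = c(330, 430),
                           seed = 1) {
  cfg <- list(
    n_patients = as.integer(n_patients), timepoints = as.integer(timepoints),
    three_tp_fraction = three_tp_fraction, grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing), background_hu = background_hu,
    core_hu = core_hu, rim_hu = rim_hu, indolent_fraction = indolent_fraction,
    vdt_indolent = vdt_indolent, vdt_aggressive = vdt_aggressive,
    mixed_fraction = mixed_fraction, mixed_direction_prob = mixed_direction_prob,
    rim_fraction_by_class = rim_fraction_by_class, clinical_odds = clinical_odds,
    outer_radius_mm = outer_radius_mm, interval_days = interval_days,
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  if (!cfg$timepoints %in% c(2L, 3L)) stop("`timepoints` must be 2 or 3", call. = FALSE)
  if (cfg$indolent_fraction < 0 || cfg$indolent_fraction > 1) {
    stop("`indolent_fraction` must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("vdt_indolent", "vdt_aggressive")) {
    v <- cfg[[nm]]
    if (any(!is.finite(v)) || exp(v[[1]]) <= 0 || v[[2]] <= 0) {
      stop(sprintf("`%s` must give a positive log-normal (meanlog, sdlog > 0)", nm),
           call. = FALSE)
    }
  }
  if (exp(cfg$vdt_indolent[[1]]) <= 400) {
    stop("`vdt_indolent` must be centred above 400 days", call. = FALSE)
  }
  if (exp(cfg$vdt_aggressive[[1]]) >= 400) {
    stop("`vdt_aggressive` must be centred below 400 days", call. = FALSE)
  }
  for (nm in names(cfg$clinical_odds)) {
    p <- cfg$clinical_odds[[nm]]
    if (any(p < 0) || any(p > 1)) {
      stop(sprintf("clinical probabilities for `%s` must lie in [0, 1]", nm),
           call. = FALSE)
    }
    odds <- p / (1 - p)
    if (any(!is.nan(odds) & odds < 0)) {
      stop(sprintf("odds for `%s` must be positive", nm), call. = FALSE)
    }
  }
  ## grid must hold the largest possible nodule plus a 3-voxel margin
  worst <- worst_case_radius_vox(cfg)
  half <- min(cfg$grid_shape * cfg$voxel_spacing) / 2
  if (worst + 3 * max(cfg$voxel_spacing) > half) {
    stop(sprintf(
      "grid too small: worst-case nodule radius %.1f mm + 3-voxel margin exceeds half-extent %.1f mm",
      worst, half), call. = FALSE)
  }
  invisible(cfg)
}

## truncation bounds for the class VDT distributions (days)
vdt_bounds <- function(class) {
  if (class == "indolent") c(400 + 1e-9, 3000) else c(130, 400 - 1e-9)
}

## upper bound on final outer radius in mm (used for the grid invariant)
worst_case_radius_vox <- function(cfg) {
  n_int <- if (cfg$timepoints >= 3) 2 else 1
  scale <- 2^(max(cfg$interval_days) * n_int / (3 * vdt_bounds("aggressive")[1]))
  max(cfg$outer_radius_mm) * scale * 1.18  # 0.15 surface perturbation + slack
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

draw_vdt <- function(n, class, cfg) {
  par <- if (class == "indolent") cfg$vdt_indolent else cfg$vdt_aggressive
  b <- vdt_bounds(class)
  rlnorm_trunc(n, par[[1]], par[[2]], b[1], b[2])
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Draw the cohort's ground truth (no rasterization)
#'
#' Assigns per-patient scan schedules, per-interval VDTs and classes, nodule
#' geometry (outer radius, target rim fraction, HU levels, surface
#' perturbation) — everything except the voxel grids. Deterministic under
#' `config$seed`. Used by [generate_cohort()] and directly by statistical
#' checks that do not need images.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_truth` list with tibbles `nodules`, `scans`
#'   (volumes filled in by [generate_cohort()]), `intervals`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    n_tp <- if (cfg$timepoints >= 3) {
      ifelse(stats::runif(n) < cfg$three_tp_fraction, 3L, 2L)
    } else rep(2L, n)
    base_class <- ifelse(stats::runif(n) < cfg$indolent_fraction,
                         "indolent", "aggressive")
    mixed <- n_tp == 3L & stats::runif(n) < cfg$mixed_fraction
    dir_ia <- stats::runif(n) < cfg$mixed_direction_prob

    nodules <- tibble::tibble(
      patient = seq_len(n),
      n_timepoints = n_tp,
      base_class = base_class,
      mixed = mixed,
      outer_radius_mm = stats::runif(n, cfg$outer_radius_mm[1], cfg$outer_radius_mm[2]),
      core_hu = stats::runif(n, cfg$core_hu[1], cfg$core_hu[2]),
      rim_hu = stats::runif(n, cfg$rim_hu[1], cfg$rim_hu[2]),
      perturb = lapply(seq_len(n), function(i) stats::runif(5, -0.06, 0.06)),
      centre_jitter = lapply(seq_len(n), function(i) stats::runif(3, -2, 2))
    )

    intervals <- purrr::map_dfr(seq_len(n), function(i) {
      k <- n_tp[i] - 1L
      cls <- rep(base_class[i], k)
      if (mixed[i]) {
        cls <- if (dir_ia[i]) c("indolent", "aggressive") else c("aggressive", "indolent")
      }
      if (!mixed[i] && k == 2L) cls <- rep(base_class[i], 2L)
      vdt <- vapply(cls, function(cl) draw_vdt(1, cl, cfg), numeric(1))
      dt <- stats::runif(k, cfg$interval_days[1], cfg$interval_days[2])
      tibble::tibble(patient = i, interval = seq_len(k), dt_days = dt,
                     vdt_assigned = unname(vdt), class_assigned = cls)
    })

    ## planted rim-fraction effect: class-conditional Beta draw per interval
    ## baseline (the morphology the features see at that interval's first scan)
    rf_par <- cfg$rim_fraction_by_class
    intervals$rim_fraction_target <- vapply(seq_len(nrow(intervals)), function(r) {
      p <- rf_par[[intervals$class_assigned[r]]]
      stats::rbeta(1, p[[1]], p[[2]])
    }, numeric(1))

    scans <- intervals |>
      dplyr::group_by(.data$patient) |>
      dplyr::summarise(day = list(c(0, cumsum(.data$dt_days))), .groups = "drop") |>
      tidyr::unnest_longer("day") |>
      dplyr::group_by(.data$patient) |>
      dplyr::mutate(timepoint = dplyr::row_number()) |>
      dplyr::ungroup()

    structure(list(nodules = nodules, scans = scans, intervals = intervals,
                   config = cfg),
              class = "phantom_truth")
  })
}

## p(u): smooth radial perturbation of the rim surface from 5 second-order
## direction terms (spherical-harmonic-like), coefficients per nodule.
surface_perturbation <- function(uz, uy, ux, coef) {
  coef[1] * (uz * uy) + coef[2] * (uz * ux) + coef[3] * (uy * ux) +
    coef[4] * (uz^2 - 1 / 3) + coef[5] * (uy^2 - ux^2)
}

## rasterize one nodule at growth scale s; returns list(core, outer) logical
## arrays over the full grid (computed on a sub-box for speed)
rasterize_nodule <- function(cfg, geom, scale, rim_fraction) {
  dm <- cfg$grid_shape
  sp <- cfg$voxel_spacing
  centre <- (dm + 1) / 2 + geom$centre_jitter / sp  # voxel units
  r_out <- geom$outer_radius_mm * scale
  r_core <- r_out * (1 - rim_fraction)^(1 / 3)
  reach <- ceiling(r_out * 1.2 / min(sp)) + 2L
  lo <- pmax(1L, floor(centre - reach))
  hi <- pmin(dm, ceiling(centre + reach))
  zz <- (lo[1]:hi[1] - centre[1]) * sp[1]
  yy <- (lo[2]:hi[2] - centre[2]) * sp[2]
  xx <- (lo[3]:hi[3] - centre[3]) * sp[3]
  nz <- length(zz); ny <- length(yy); nx <- length(xx)
  Z <- array(zz, c(nz, ny, nx))
  Y <- aperm(array(yy, c(ny, nz, nx)), c(2, 1, 3))
  X <- aperm(array(xx, c(nx, nz, ny)), c(2, 3, 1))
  r <- sqrt(Z^2 + Y^2 + X^2)
  r[r == 0] <- 1e-9
  p <- surface_perturbation(Z / r, Y / r, X / r, geom$perturb)
  outer_sub <- r <= r_out * (1 + p)
  core_sub <- r <= r_core * (1 + 0.3 * p)  # core follows the outer shape mildly
  outer <- array(FALSE, dm); core <- array(FALSE, dm)
  outer[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- outer_sub
  core[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- core_sub
  ## grid-bound check: shape must keep a 3-voxel margin
  if (any(centre - r_out * (1 + max(p)) / sp < 4) ||
      any(centre + r_out * (1 + max(p)) / sp > dm - 3)) {
    stop(sprintf("nodule growth exceeds grid bounds for patient %d (outer radius %.1f mm)",
                 geom$patient, r_out), call. = FALSE)
  }
  list(core = core, outer = outer, centre = centre)
}

#' Generate a synthetic longitudinal nodule cohort
#'
#' Rasterizes every patient-timepoint volume: an ellipsoid-like solid core
#' inside a concentric irregular ground-glass rim, grown by isotropic
#' scaling about the nodule centroid so that the volume ratio over an
#' interval equals `2^(dt / VDT)` up to voxelization, embedded in noisy
#' lung-parenchyma background with one partial-volume Gaussian smoothing
#' pass (sigma 0.5 voxel) before noise. Bit-identical under a fixed
#' config + seed.
#'
#' @param config a [phantom_config()].
#' @return List with `volumes` (per patient, a list of `ct_volume`),
#'   `truth` (a `phantom_truth` whose `scans` tibble carries voxelized
#'   volumes, rim fractions and seed points), and `clinical`
#'   (see [generate_clinical()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  truth <- generate_truth(config)
  cfg <- config
  clinical <- generate_clinical(cfg, truth)

  with_seed(cfg$seed + 1000003L, {
    vols <- vector("list", cfg$n_patients)
    scan_rows <- list()
    for (i in seq_len(cfg$n_patients)) {
      geom <- as.list(truth$nodules[i, ])
      geom$perturb <- geom$perturb[[1]]
      geom$centre_jitter <- geom$centre_jitter[[1]]
      iv <- truth$intervals[truth$intervals$patient == i, ]
      days <- truth$scans$day[truth$scans$patient == i]
      n_tp <- length(days)
      ## cumulative growth scale at each timepoint
      ratio <- c(1, cumprod(2^(iv$dt_days / iv$vdt_assigned)))
      scale <- ratio^(1 / 3)
      ## rim fraction seen at each scan: the baseline of the interval it
      ## starts (last scan inherits the final interval's target)
      rim_f <- c(iv$rim_fraction_target, iv$rim_fraction_target[nrow(iv)])
      pv <- vector("list", n_tp)
      for (t in seq_len(n_tp)) {
        shp <- rasterize_nodule(cfg, geom, scale[t], rim_f[t])
        hu <- array(cfg$background_hu[1], cfg$grid_shape)
        hu[shp$outer] <- geom$rim_hu
        hu[shp$core] <- geom$core_hu
        ## partial-volume smoothing is local: away from the nodule the
        ## field is constant, so smooth only a padded box around it
        cbx <- crop_bbox(hu, shp$outer, pad = 4L)
        sm <- smooth_gaussian3d(cbx$arr, 0.5)
        hib <- cbx$origin + dim(sm) - 1L
        hu[cbx$origin[1]:hib[1], cbx$origin[2]:hib[2], cbx$origin[3]:hib[3]] <- sm
        hu <- hu + array(stats::rnorm(prod(cfg$grid_shape), 0, cfg$background_hu[2]),
                         cfg$grid_shape)
        pv[[t]] <- ct_volume(hu, spacing = cfg$voxel_spacing, day = days[t])
        scan_rows[[length(scan_rows) + 1L]] <- tibble::tibble(
          patient = i, timepoint = t, day = days[t],
          n_voxels = sum(shp$outer),
          volume_mm3 = sum(shp$outer) * voxel_volume_mm3(cfg$voxel_spacing),
          rim_fraction = 1 - sum(shp$core & shp$outer) / sum(shp$outer),
          seed_z = round(shp$centre[1]) - 1L,
          seed_y = round(shp$centre[2]) - 1L,
          seed_x = round(shp$centre[3]) - 1L
        )
      }
      vols[[i]] <- pv
    }
    truth$scans <- dplyr::bind_rows(scan_rows)
    list(volumes = vols, truth = truth, clinical = clinical)
  })
}

#' Simulate clinical covariates for a phantom cohort
#'
#' Sex and COPD are class-conditional Bernoulli draws (conditioned on the
#' patient's first-interval growth class) with the probabilities in
#' `config$clinical_odds`; age, pack-years, smoking status and family
#' history are drawn independent of class. Deterministic under the config
#' seed.
#'
#' @param config a [phantom_config()].
#' @param truth a `phantom_truth` from [generate_truth()].
#' @return Tibble: `patient`, `sex` ("female"/"male"), `copd`, `age`,
#'   `pack_years`, `smoking_status`, `family_history`, `class` (the
#'   conditioning class).
#' @export
generate_clinical <- function(config, truth) {
  stopifnot(inherits(config, "phantom_config"), inherits(truth, "phantom_truth"))
  first_class <- truth$intervals |>
    dplyr::filter(.data$interval == 1L) |>
    dplyr::arrange(.data$patient)
  with_seed(config$seed + 2000003L, {
    n <- nrow(first_class)
    cls <- first_class$class_assigned
    p_f <- unname(config$clinical_odds$sex[cls])
    p_c <- unname(config$clinical_odds$copd[cls])
    tibble::tibble(
      patient = first_class$patient,
      sex = ifelse(stats::runif(n) < p_f, "female", "male"),
      copd = as.integer(stats::runif(n) < p_c),
      age = round(stats::rnorm(n, 65, 5.3)),
      pack_years = round(pmax(stats::rnorm(n, 62, 23), 30)),
      smoking_status = ifelse(stats::runif(n) < 0.55, "current", "former"),
      family_history = as.integer(stats::runif(n) < 0.26),
      class = cls
    )
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d patients, %d intervals (%.0f%% indolent)\n",
              nrow(x$nodules), nrow(x$intervals),
              100 * mean(x$intervals$class_assigned == "indolent")))
  invisible(x)
}
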