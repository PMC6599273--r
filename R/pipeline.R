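## End-to-end orchestration: simulate -> segment -> volumes/VDT ->
## features -> select -> fit -> report.

#' Run configuration for the full analysis
#'
#' @param phantom a [phantom_config()] describing the simulated cohort.
#' @param selection a [selection_config()].
#' @param n_boot_validation bootstrap replicates for model validation.
#' @param seed seed for the model-validation bootstrap (the phantom and
#'   selection stages carry their own seeds).
#' @param out_dir optional output directory; when given, stage outputs are
#'   written as CSV/JSON.
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = phantom_config(),
                       selection = selection_config(),
                       n_boot_validation = 1000L,
                       seed = 1L, out_dir = NULL) {
  structure(list(phantom = phantom, selection = selection,
                 n_boot_validation = as.integer(n_boot_validation),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Segment every scan of a simulated cohort
#'
#' Builds the lung-window / mediastinal-window / difference-region mask
#' set for each patient-timepoint, seeded at the known nodule centre.
#'
#' @param cohort output of [generate_cohort()].
#' @return List of per-scan records: `patient`, `timepoint`, `volume`,
#'   `masks`.
#' @export
segment_cohort <- function(cohort) {
  scans <- cohort$truth$scans
  out <- vector("list", nrow(scans))
  for (r in seq_len(nrow(scans))) {
    p <- scans$patient[r]; t <- scans$timepoint[r]
    vol <- cohort$volumes[[p]][[t]]
    seed_pt <- c(scans$seed_z[r], scans$seed_y[r], scans$seed_x[r])
    out[[r]] <- list(patient = p, timepoint = t, volume = vol,
                     masks = nodule_masks(vol, seed_pt))
  }
  out
}

## growth table from segmented scans: volumes from the lung-window mask
cohort_growth <- function(segmented) {
  scan_tbl <- purrr::map_dfr(segmented, function(s) {
    tibble::tibble(patient = s$patient, timepoint = s$timepoint,
                   day = s$volume$day,
                   lw_mm3 = s$masks$volumes$mm3[s$masks$volumes$role == "lung_window"],
                   mw_mm3 = s$masks$volumes$mm3[s$masks$volumes$role == "mediastinal_window"],
                   dr_mm3 = s$masks$volumes$mm3[s$masks$volumes$role == "difference_region"])
  })
  iv <- scan_tbl |>
    dplyr::arrange(.data$patient, .data$timepoint) |>
    dplyr::group_by(.data$patient) |>
    dplyr::mutate(v0 = .data$lw_mm3,
                  vi = dplyr::lead(.data$lw_mm3),
                  ti = dplyr::lead(.data$day) - .data$day,
                  interval = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$vi))
  growth_table(iv[, c("patient", "interval", "timepoint", "v0", "vi", "ti")])
}

#' Run the full multi-window radiomics analysis on a phantom cohort
#'
#' Simulates the cohort, segments every scan under both windows, computes
#' per-interval VDTs and growth classes from the lung-window volumes,
#' extracts the 364-feature vectors from the lung-window and
#' difference-region masks of each interval's baseline scan, runs the
#' selection chain per feature source (lung window, difference region,
#' combined), fits the three radiomics models, the clinical model and the
#' clinical-augmented (nomogram) models, and evaluates them with
#' bootstrap validation. Nodule-level observations are intervals, as in a
#' screening cohort where three-scan patients contribute two.
#'
#' @param config a [run_config()].
#' @return An `mw_run` list: `growth`, `patient_labels`, `features`
#'   (wide tibble), `selection` (per source), `models`, `performance`,
#'   `nomogram`, `scores`, `manifest`.
#' @export
run_growth_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  cohort <- generate_cohort(config$phantom)
  tick("simulate")
  segmented <- segment_cohort(cohort)
  tick("segment")
  growth <- cohort_growth(segmented)
  plabels <- patient_labels(growth)
  tick("growth")

  ## one observation per interval; features from the interval's baseline scan
  seg_index <- vapply(segmented, function(s) paste(s$patient, s$timepoint), character(1))
  clin <- cohort$clinical
  observations <- lapply(seq_len(nrow(growth)), function(r) {
    p <- growth$patient[r]
    s <- segmented[[match(paste(p, growth$timepoint[r]), seg_index)]]
    ci <- clin[clin$patient == p, ]
    list(patient = p, interval = growth$interval[r],
         label = as.character(growth$class[r]),
         vdt = growth$vdt[r],
         sex_female = as.integer(ci$sex == "female"),
         copd = ci$copd,
         volume = s$volume, masks = s$masks)
  })
  features <- extract_cohort(observations)
  tick("features")

  lw_cols <- grep("^LW_F", names(features), value = TRUE)
  dr_cols <- grep("^DR_F", names(features), value = TRUE)
  sources <- list(lung_window = lw_cols, difference_region = dr_cols,
                  combined = c(lw_cols, dr_cols))
  selection <- lapply(sources, function(cols) {
    select_features(features, cols, label = "label", config = config$selection)
  })
  tick("select")

  models <- list()
  scores <- tibble::tibble(.rows = nrow(features))
  for (src in names(selection)) {
    final <- selection[[src]]$survivors$final
    if (!length(final)) {
      models[[src]] <- fit_logistic(features, character(0), label = "label",
                                    family_tag = src)
      next
    }
    models[[src]] <- fit_logistic(features, final, label = "label",
                                  family_tag = src)
    scores[[paste0("radio_", src)]] <- radiomics_score(models[[src]], features)
  }
  clin_covs <- c("sex_female", "copd")
  models$clinical <- fit_logistic(features, clin_covs, label = "label",
                                  family_tag = "clinical")
  aug_data <- dplyr::bind_cols(features[c("label", clin_covs)], scores)
  for (src in names(selection)) {
    sc <- paste0("radio_", src)
    if (!sc %in% names(scores)) next
    models[[paste0("nomogram_", src)]] <-
      combine_clinical(aug_data, sc, clin_covs, label = "label",
                       family_tag = paste0("nomogram_", src))
  }
  tick("fit")

  performance <- purrr::map_dfr(models, function(m) {
    evaluate_model(m, n_boot = config$n_boot_validation, seed = config$seed)
  })
  nomogram <- if (!is.null(models$nomogram_combined)) {
    build_nomogram(models$nomogram_combined)
  } else NULL
  tick("evaluate")

  manifest <- list(
    package_version = as.character(utils::packageVersion("mwradiomics")),
    config_digest = rlang::hash(list(config$phantom, config$selection,
                                     config$n_boot_validation, config$seed)),
    stage_digests = list(
      growth = rlang::hash(growth),
      features = rlang::hash(features),
      selection = rlang::hash(lapply(selection, function(s) s$survivors)),
      performance = rlang::hash(performance)
    ),
    seeds = list(phantom = config$phantom$seed,
                 selection = config$selection$seed,
                 validation = config$seed),
    wall_clock_s = as.list(timing)
  )

  run <- structure(
    list(growth = growth, patient_labels = plabels, features = features,
         selection = selection, models = models, performance = performance,
         nomogram = nomogram, scores = scores, manifest = manifest,
         clinical = cohort$clinical, truth = cohort$truth,
         config = config),
    class = "mw_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' @export
print.mw_run <- function(x, ...) {
  cat(sprintf("<mw_run> %d intervals (%d patients), %.0f%% indolent\n",
              nrow(x$growth), nrow(x$patient_labels),
              100 * mean(x$growth$class == "indolent")))
  print(x$performance[, c("family_tag", "auroc", "auroc_boot", "ci_lo", "ci_hi",
                          "accuracy", "sensitivity", "specificity")])
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' Emits the growth CSV, the feature CSV, the selection report JSON,
#' per-model JSONs, the performance CSV and the run manifest JSON.
#'
#' @param run an `mw_run`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$growth, file.path(dir, "growth.csv"), row.names = FALSE)
  utils::write.csv(run$features, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(run$performance, file.path(dir, "performance.csv"), row.names = FALSE)
  sel <- lapply(run$selection, function(s) list(
    survivors = s$survivors,
    ttest = s$ttest, auroc = s$auroc, pruning = s$pruning,
    elimination = s$elimination, separation = s$separation
  ))
  jsonlite::write_json(sel, file.path(dir, "selection.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  mods <- lapply(run$models, function(m) list(
    family_tag = m$family_tag, covariates = m$covariates,
    coefficients = m$coefficients, separation = m$separation
  ))
  jsonlite::write_json(mods, file.path(dir, "models.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (!is.null(run$nomogram)) {
    jsonlite::write_json(
      list(scales = run$nomogram$scales,
           points_per_unit = run$nomogram$points_per_unit,
           lp_offset = run$nomogram$lp_offset),
      file.path(dir, "nomogram.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
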