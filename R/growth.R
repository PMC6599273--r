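## Volume-doubling time and growth-pattern labelling.

#' Volume-doubling time
#'
#' Assuming exponential growth, the volume-doubling time of a nodule scanned
#' twice is `VDT = ln(2) * Ti / ln(Vi / V0)`, where `V0` is the earlier
#' volume, `Vi` the later volume and `Ti` the interval in days. The result
#' is positive for growing nodules, `Inf` when the volume is unchanged, and
#' negative for shrinking nodules. Vectorised.
#'
#' @param v0 earlier volume (mm3), > 0.
#' @param vi later volume (mm3), > 0.
#' @param ti interval between the two scans in days, > 0.
#' @return VDT in days.
#' @examples
#' compute_vdt(1000, 2000, 365)  # one doubling in a year -> 365
#' compute_vdt(1000, 4000, 200)  # two doublings -> 100
#' @export
compute_vdt <- function(v0, vi, ti) {
  if (any(!is.finite(v0)) || any(v0 <= 0)) stop("`v0` must be positive", call. = FALSE)
  if (any(!is.finite(ti)) || any(ti <= 0)) stop("`ti` must be positive", call. = FALSE)
  if (any(!is.finite(vi)) || any(vi <= 0)) {
    stop("`vi` must be positive; an empty later mask must be handled upstream",
         call. = FALSE)
  }
  r <- log(vi / v0)
  out <- log(2) * ti / r
  out[r == 0] <- Inf
  out
}

#' Classify a screening interval by its VDT
#'
#' A VDT of 400 days or more is indolent/slow-growing; a VDT strictly
#' between 0 and 400 days is aggressive/fast-growing. Non-growing lesions
#' (infinite VDT) and shrinking lesions (negative VDT) are the extreme of
#' slow growth and are classified indolent. Vectorised; returns a factor
#' with levels `indolent`, `aggressive`.
#'
#' @param vdt VDT in days (finite, `Inf`, or negative).
#' @return Factor of interval classes.
#' @examples
#' classify_interval(c(583, 148, 400, -200, Inf))
#' @export
classify_interval <- function(vdt) {
  aggressive <- is.finite(vdt) & vdt > 0 & vdt < 400
  factor(ifelse(aggressive, "aggressive", "indolent"),
         levels = c("indolent", "aggressive"))
}

#' Patient-level growth label from interval classes
#'
#' A single interval gives its own class; concordant intervals give the
#' shared class; discordant intervals give `mixed`, with the direction of
#' the first re-classification recorded in the `direction` attribute
#' (`"indolent_to_aggressive"` or `"aggressive_to_indolent"`).
#'
#' @param classes character or factor vector of interval classes, in
#'   chronological order.
#' @return Length-1 character (`indolent`, `aggressive` or `mixed`), with a
#'   `direction` attribute when mixed.
#' @examples
#' label_patient(c("indolent", "aggressive"))
#' @export
label_patient <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) == 0) stop("at least one interval class is required", call. = FALSE)
  stopifnot(all(classes %in% c("indolent", "aggressive")))
  u <- unique(classes)
  if (length(u) == 1) return(u)
  i <- which(classes[-1] != classes[-length(classes)])[1]
  structure("mixed",
            direction = paste0(classes[i], "_to_", classes[i + 1]))
}

#' Per-interval growth table
#'
#' Tidy wrapper over [compute_vdt()] and [classify_interval()]: takes one
#' row per scan interval and appends the VDT and interval class.
#'
#' @param data data frame with columns `v0`, `vi`, `ti` (and any id columns,
#'   which are carried through).
#' @return A tibble with added columns `vdt` (days) and `class`.
#' @examples
#' growth_table(data.frame(patient = 1, v0 = 1000, vi = 2000, ti = 365))
#' @export
growth_table <- function(data) {
  stopifnot(all(c("v0", "vi", "ti") %in% names(data)))
  out <- tibble::as_tibble(data)
  out$vdt <- compute_vdt(out$v0, out$vi, out$ti)
  out$class <- classify_interval(out$vdt)
  out
}

#' Cohort composition summary
#'
#' Class counts and fractions at the interval (nodule-observation) level,
#' and, when a clinical table is supplied, covariate frequencies within
#' each class (percentages as printed in screening-cohort demographic
#' tables).
#'
#' @param growth per-interval growth tibble with a `class` column.
#' @param clinical optional clinical tibble with `patient`, a `class`
#'   column and binary/categorical covariates.
#' @return List with `classes` (tibble: class, n, fraction) and, if
#'   clinical data is given, `covariates` (tibble: covariate, level,
#'   class, n, percent).
#' @examples
#' g <- growth_table(data.frame(patient = 1:3, v0 = 1000,
#'                              vi = c(1100, 3000, 2600), ti = 365))
#' cohort_summary(g)$classes
#' @export
cohort_summary <- function(growth, clinical = NULL) {
  classes <- growth |>
    dplyr::count(class = as.character(.data$class), name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  out <- list(classes = classes)
  if (!is.null(clinical)) {
    covs <- setdiff(names(clinical), c("patient", "class"))
    out$covariates <- purrr::map_dfr(covs, function(v) {
      clinical |>
        dplyr::count(.data$class, level = as.character(.data[[v]]), name = "n") |>
        dplyr::group_by(.data$class) |>
        dplyr::mutate(percent = 100 * .data$n / sum(.data$n),
                      covariate = v) |>
        dplyr::ungroup() |>
        dplyr::select("covariate", "level", "class", "n", "percent")
    })
  }
  out
}

#' Patient-level growth labels
#'
#' Collapses a per-interval growth table (one row per interval, in
#' chronological order within patient) to one row per patient with the
#' patient-level label and, for mixed patients, the direction of
#' re-classification.
#'
#' @param growth a tibble as returned by [growth_table()], with a
#'   `patient` column and a `class` column.
#' @return Tibble with columns `patient`, `label`, `direction`.
#' @export
patient_labels <- function(growth) {
  stopifnot(all(c("patient", "class") %in% names(growth)))
  growth |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(
      label = {
        l <- label_patient(.data$class)
        as.character(l)
      },
      direction = attr(label_patient(as.character(.data$class)), "direction") %||% NA_character_,
      .groups = "drop"
    )
}
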