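## Logistic growth models, radiomics scores, bootstrap-validated
## performance and nomogram point mappings.

#' Fit a logistic growth model
#'
#' Maximum-likelihood logistic regression of the (binary) growth class on
#' the given covariates. The positive class (modelled as 1) defaults to
#' aggressive. Separation is detected and flagged, mirroring how
#' quasi-separated odds ratios are reported rather than suppressed.
#'
#' @param data data frame with covariates and the label column.
#' @param covariates character vector of covariate column names.
#' @param label label column name.
#' @param family_tag model family tag (`lung_window`, `difference_region`,
#'   `combined`, `clinical`, `nomogram_*`, ...), recorded for reporting.
#' @param positive_class class modelled as 1.
#' @return A `growth_model`: list with the `glm` fit, `coefficients`
#'   tibble (estimate, odds ratio, Wald p), `covariates`, `family_tag`,
#'   `separation` flag, and the modelling data (for downstream
#'   evaluation).
#' @export
fit_logistic <- function(data, covariates, label = "label",
                         family_tag = "custom",
                         positive_class = "aggressive") {
  y <- binary_label(data[[label]], positive_class)
  df <- data.frame(.y = y, data[covariates], check.names = FALSE)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < length(covariates) + 2) {
    stop("need at least `length(covariates) + 2` complete observations", call. = FALSE)
  }
  fml <- if (length(covariates)) {
    stats::reformulate(sprintf("`%s`", covariates), response = ".y")
  } else stats::as.formula(".y ~ 1")
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = gsub("`", "", rownames(cf)),
    estimate = unname(cf[, 1]), std_error = unname(cf[, 2]),
    p_value = unname(cf[, 4]), odds_ratio = unname(exp(cf[, 1]))
  )
  structure(
    list(fit = fit, coefficients = coefs, covariates = covariates,
         label = label, positive_class = positive_class,
         family_tag = family_tag, separation = separation_flag(fit),
         data = df),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> %s: %d covariates, n = %d%s\n", x$family_tag,
              length(x$covariates), nrow(x$data),
              if (x$separation) " [separation flagged]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Radiomics score: the linear predictor of a fitted model
#'
#' `intercept + sum(beta * x)` over the model's covariates. Entering the
#' score as the single covariate of a downstream logistic fit reproduces
#' the original predicted probabilities (the refit recovers slope 1).
#'
#' @param model a `growth_model`.
#' @param newdata data frame containing the model covariates.
#' @return Numeric vector of scores (log-odds scale).
#' @export
radiomics_score <- function(model, newdata) {
  stopifnot(inherits(model, "growth_model"))
  missing_cov <- setdiff(model$covariates, names(newdata))
  if (length(missing_cov)) {
    stop(sprintf("missing covariate(s): %s", paste(missing_cov, collapse = ", ")),
         call. = FALSE)
  }
  as.numeric(stats::predict(model$fit, newdata = newdata, type = "link"))
}

#' Augment a radiomics score with clinical covariates
#'
#' Logistic fit on the radiomics score plus sex and COPD history, the
#' clinical factors with a class association in screening cohorts.
#'
#' @param data data frame with the score column, clinical columns and the
#'   label.
#' @param score_col name of the radiomics-score column.
#' @param clinical_cols clinical covariate columns.
#' @inheritParams fit_logistic
#' @return A `growth_model` tagged `nomogram_<tag>`.
#' @export
combine_clinical <- function(data, score_col, clinical_cols = c("sex_female", "copd"),
                             label = "label", family_tag = "nomogram",
                             positive_class = "aggressive") {
  fit_logistic(data, c(score_col, clinical_cols), label = label,
               family_tag = family_tag, positive_class = positive_class)
}

youden_threshold <- function(prob, y) {
  thr <- sort(unique(prob))
  cand <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  if (length(thr) == 1) cand <- c(-Inf, thr, Inf)
  j <- vapply(cand, function(t) {
    pred <- prob > t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Apparent and bootstrap-validated model performance
#'
#' Apparent AUROC by the rank-sum formulation on the model's fitted
#' probabilities; operating threshold by the Youden index on the apparent
#' ROC; accuracy, sensitivity and specificity at that threshold.
#' Internal validation refits the model on `n_boot` stratified bootstrap
#' resamples and reports the mean bootstrap AUROC with a percentile CI
#' (optimism-corrected AUROC by flag).
#'
#' @param model a `growth_model`.
#' @param n_boot bootstrap replicates (0 skips the bootstrap).
#' @param seed RNG seed.
#' @param conf confidence level of the percentile interval.
#' @param optimism also compute the optimism-corrected AUROC.
#' @return A `performance_summary` tibble row: `auroc`, `auroc_boot`,
#'   `ci_lo`, `ci_hi`, `accuracy`, `sensitivity`, `specificity`,
#'   `threshold`, `n`, `n_boot` (and `auroc_optimism_corrected` by flag).
#' @export
evaluate_model <- function(model, n_boot = 5000L, seed = 1L, conf = 0.95,
                           optimism = FALSE) {
  stopifnot(inherits(model, "growth_model"))
  df <- model$data
  y <- df$.y
  prob <- as.numeric(stats::fitted(model$fit))
  auc_app <- auroc(prob, y)
  thr <- youden_threshold(prob, y)
  pred <- prob > thr
  sens <- sum(pred & y == 1) / sum(y == 1)
  spec <- sum(!pred & y == 0) / sum(y == 0)
  acc <- mean(pred == (y == 1))
  auc_boot <- ci <- c(NA_real_, NA_real_)
  mean_boot <- NA_real_
  opt_corr <- NA_real_
  if (n_boot > 0) {
    i1 <- which(y == 1); i0 <- which(y == 0)
    with_seed(seed, {
      stats_b <- vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(i1, length(i1), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
        dfb <- df[idx, , drop = FALSE]
        fitb <- suppressWarnings(stats::glm(stats::formula(model$fit), data = dfb,
                                            family = stats::binomial()))
        ab <- auroc(stats::fitted(fitb), dfb$.y)
        ao <- auroc(stats::predict(fitb, newdata = df, type = "link"), y)
        c(ab, ab - ao)
      }, numeric(2))
      mean_boot <- mean(stats_b[1, ], na.rm = TRUE)
      a <- (1 - conf) / 2
      ci <- stats::quantile(stats_b[1, ], c(a, 1 - a), na.rm = TRUE, names = FALSE)
      if (optimism) opt_corr <- auc_app - mean(stats_b[2, ], na.rm = TRUE)
    })
  }
  out <- tibble::tibble(
    family_tag = model$family_tag, auroc = auc_app, auroc_boot = mean_boot,
    ci_lo = ci[1], ci_hi = ci[2], accuracy = acc, sensitivity = sens,
    specificity = spec, threshold = thr, n = length(y),
    n_boot = as.integer(n_boot)
  )
  if (optimism) out$auroc_optimism_corrected <- opt_corr
  structure(out, class = c("performance_summary", class(out)))
}

#' ROC curve points
#'
#' @param score numeric scores.
#' @param y 0/1 labels.
#' @return Tibble `threshold`, `tpr`, `fpr` along the apparent ROC.
#' @export
roc_points <- function(score, y) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  purrr::map_dfr(thr, function(t) {
    pred <- score >= t
    tibble::tibble(threshold = t,
                   tpr = sum(pred & y == 1) / sum(y == 1),
                   fpr = sum(pred & y == 0) / sum(y == 0))
  })
}

#' Nomogram point mapping for a logistic model
#'
#' Each covariate is mapped to a 0-100 point scale by
#' `points_i(x) = 100 |beta_i| (x - ref_i) / max_j(|beta_j| range_j)`,
#' with `ref_i` the end of the observed range that minimises the linear
#' predictor, so the most influential covariate spans exactly 0-100.
#' Total points map back to predicted probability through the inverse
#' logit of the reconstructed linear predictor; the reconstruction is
#' exact up to floating point.
#'
#' @param model a `growth_model`.
#' @param data data frame giving the observed covariate ranges (defaults
#'   to the modelling data).
#' @return A `nomogram_spec`: list with `scales` (per-covariate tibble),
#'   `points_per_unit`, `intercept_offset`, and `predict_total` /
#'   `prob_from_points` closures.
#' @export
build_nomogram <- function(model, data = NULL) {
  stopifnot(inherits(model, "growth_model"))
  df <- data %||% model$data
  beta <- stats::coef(model$fit)
  b0 <- beta[["(Intercept)"]]
  nm <- gsub("`", "", names(beta))
  covs <- model$covariates
  bmap <- stats::setNames(beta[match(covs, nm) ], covs)
  rng <- lapply(covs, function(v) range(df[[v]], na.rm = TRUE))
  names(rng) <- covs
  span <- vapply(covs, function(v) {
    b <- bmap[[v]]
    if (!is.finite(b)) return(0)  # inestimable (e.g. constant) covariate
    abs(b) * diff(rng[[v]])
  }, numeric(1))
  zero_range <- span == 0
  if (any(zero_range)) {
    warning(sprintf("zero-range covariate(s) excluded from the point scale: %s",
                    paste(covs[zero_range], collapse = ", ")), call. = FALSE)
  }
  use <- covs[!zero_range]
  if (!length(use)) stop("no covariate with a nonzero observed range", call. = FALSE)
  unit <- max(span[!zero_range]) / 100  # linear-predictor units per point
  scales <- purrr::map_dfr(use, function(v) {
    b <- bmap[[v]]
    ref <- if (b >= 0) rng[[v]][1] else rng[[v]][2]  # end minimising the LP
    tibble::tibble(term = v, beta = unname(b), ref = unname(ref),
                   lo = rng[[v]][1], hi = rng[[v]][2],
                   max_points = unname(abs(b) * diff(rng[[v]]) / unit))
  })
  ## LP = b0 + sum(b * ref) + unit * total_points
  lp_offset <- b0 + sum(vapply(use, function(v) bmap[[v]] * scales$ref[scales$term == v],
                               numeric(1))) +
    sum(vapply(covs[zero_range], function(v) {
      if (is.finite(bmap[[v]])) bmap[[v]] * df[[v]][1] else 0
    }, numeric(1)))
  spec <- list(
    scales = scales, points_per_unit = 1 / unit, lp_offset = lp_offset,
    covariates = use, model_tag = model$family_tag
  )
  spec$points_for <- function(term, x) {
    row <- scales[scales$term == term, ]
    row$beta * (x - row$ref) / unit  # nonnegative: ref minimises beta * x
  }
  spec$total_points <- function(newdata) {
    mat <- vapply(use, function(v) {
      row <- scales[scales$term == v, ]
      row$beta * (newdata[[v]] - row$ref) / unit
    }, numeric(nrow(newdata)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(newdata))
    rowSums(mat)
  }
  spec$prob_from_points <- function(total) stats::plogis(lp_offset + unit * total)
  class(spec) <- "nomogram_spec"
  spec
}

#' Predicted probability of a nomogram on new data
#' @param spec a `nomogram_spec`.
#' @param newdata data frame with the nomogram covariates.
#' @return Numeric probabilities.
#' @export
nomogram_predict <- function(spec, newdata) {
  stopifnot(inherits(spec, "nomogram_spec"))
  spec$prob_from_points(spec$total_points(newdata))
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat(sprintf("<nomogram_spec> %s, %d covariate scales (max points 100)\n",
              x$model_tag, nrow(x$scales)))
  print(x$scales)
  invisible(x)
}
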