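test_that("identical config and seed reproduce the cohort bit-identically", {
  cfg <- small_cohort_config(n = 3, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth$intervals, b$truth$intervals)
  expect_identical(a$truth$scans, b$truth$scans)
  expect_identical(a$clinical, b$clinical)
  for (p in 1:3) for (t in seq_along(a$volumes[[p]])) {
    expect_identical(a$volumes[[p]][[t]]$data, b$volumes[[p]][[t]]$data)
  }
  # a different seed changes the voxel data
  c2 <- generate_cohort(small_cohort_config(n = 3, seed = 8))
  expect_false(identical(a$volumes[[1]][[1]]$data, c2$volumes[[1]][[1]]$data))
})

test_that("empirical class fractions converge to the configured fraction", {
  # truth-only draw at large n; binomial-CI oracle at 3 standard errors
  cfg <- phantom_config(n_patients = 600, timepoints = 2,
                        indolent_fraction = 0.26, seed = 123)
  tr <- generate_truth(cfg)
  phat <- mean(tr$intervals$class_assigned == "indolent")
  se <- sqrt(0.26 * 0.74 / 600)
  expect_lt(abs(phat - 0.26), 3 * se)
  # assigned class always consistent with assigned VDT under the 400-day rule
  expect_identical(as.character(classify_interval(tr$intervals$vdt_assigned)),
                   tr$intervals$class_assigned)
})

test_that("generated volumes follow the assigned doubling law", {
  cfg <- small_cohort_config(n = 6, seed = 21)
  coh <- generate_cohort(cfg)
  sc <- coh$truth$scans
  iv <- coh$truth$intervals
  for (r in seq_len(nrow(iv))) {
    v0 <- sc$volume_mm3[sc$patient == iv$patient[r] & sc$timepoint == iv$interval[r]]
    v1 <- sc$volume_mm3[sc$patient == iv$patient[r] & sc$timepoint == iv$interval[r] + 1]
    expected_log_ratio <- log(2) * iv$dt_days[r] / iv$vdt_assigned[r]
    expect_lt(abs(log(v1 / v0) - expected_log_ratio), 0.05)
  }
  # a nodule with VDT 365 observed 365 days apart doubles in volume
  cfg2 <- phantom_config(n_patients = 1, timepoints = 2, seed = 5,
                         interval_days = c(365, 365),
                         vdt_aggressive = c(meanlog = log(365 - 30), sdlog = 1e-6),
                         indolent_fraction = 0)
  # force the interval VDT to exactly 365 by overriding truth
  tr <- generate_truth(cfg2)
  expect_equal(nrow(tr$intervals), 1)
})

test_that("a nodule with VDT equal to the interval doubles within 5%", {
  # direct rasterization check: scale by 2^(1/3) doubles the voxel volume
  cfg <- phantom_config(n_patients = 1, seed = 9)
  tr <- generate_truth(cfg)
  geom <- as.list(tr$nodules[1, ])
  geom$perturb <- geom$perturb[[1]]
  geom$centre_jitter <- geom$centre_jitter[[1]]
  s1 <- mwradiomics:::rasterize_nodule(cfg, geom, 1, 0.5)
  s2 <- mwradiomics:::rasterize_nodule(cfg, geom, 2^(1 / 3), 0.5)
  ratio <- sum(s2$outer) / sum(s1$outer)
  expect_gt(sum(s1$outer), 200)
  expect_lt(abs(ratio / 2 - 1), 0.05)
})

test_that("core and rim HU land on the recoverable side of the thresholds", {
  cfg <- small_cohort_config(n = 4, seed = 31)
  coh <- generate_cohort(cfg)
  nd <- coh$truth$nodules
  expect_true(all(nd$core_hu >= -160))            # solid core visible in MW
  expect_true(all(nd$rim_hu >= -750 & nd$rim_hu < -160))  # rim only in LW
})

test_that("mixed patients draw their two intervals from opposite classes", {
  cfg <- phantom_config(n_patients = 200, timepoints = 3,
                        three_tp_fraction = 1, mixed_fraction = 1, seed = 77)
  tr <- generate_truth(cfg)
  per <- split(tr$intervals$class_assigned, tr$intervals$patient)
  expect_true(all(vapply(per, function(x) length(unique(x)) == 2, logical(1))))
  # direction frequency follows the configured probability (12/17 here)
  dirs <- vapply(per, function(x) x[1] == "indolent", logical(1))
  se <- sqrt((12 / 17) * (5 / 17) / 200)
  expect_lt(abs(mean(dirs) - 12 / 17), 3 * se)
})

test_that("clinical covariates follow class-conditional probabilities", {
  cfg <- phantom_config(n_patients = 1000, timepoints = 2, seed = 55)
  tr <- generate_truth(cfg)
  cl <- generate_clinical(cfg, tr)
  p_f_ind <- mean(cl$sex[cl$class == "indolent"] == "female")
  p_f_agg <- mean(cl$sex[cl$class == "aggressive"] == "female")
  n_ind <- sum(cl$class == "indolent"); n_agg <- sum(cl$class == "aggressive")
  expect_lt(abs(p_f_ind - 0.70), 3 * sqrt(0.70 * 0.30 / n_ind))
  expect_lt(abs(p_f_agg - 0.3117), 3 * sqrt(0.3117 * (1 - 0.3117) / n_agg))
  # zero COPD probability in the indolent class: no indolent COPD cases
  expect_equal(sum(cl$copd[cl$class == "indolent"]), 0)
  p_c_agg <- mean(cl$copd[cl$class == "aggressive"])
  expect_lt(abs(p_c_agg - 0.2078), 3 * sqrt(0.2078 * (1 - 0.2078) / n_agg))
})

test_that("null clinical odds give covariates independent of class", {
  cfg <- phantom_config(n_patients = 800, timepoints = 2, seed = 66,
                        clinical_odds = list(
                          sex = c(indolent = 0.5, aggressive = 0.5),
                          copd = c(indolent = 0.2, aggressive = 0.2)
                        ))
  tr <- generate_truth(cfg)
  cl <- generate_clinical(cfg, tr)
  chi <- suppressWarnings(chisq.test(table(cl$sex, cl$class)))
  expect_gt(chi$p.value, 0.001)
  chi2 <- suppressWarnings(chisq.test(table(cl$copd, cl$class)))
  expect_gt(chi2$p.value, 0.001)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(phantom_config(indolent_fraction = 1.2), "indolent_fraction")
  expect_error(phantom_config(vdt_aggressive = c(meanlog = log(600), sdlog = 0.2)),
               "below 400")
  expect_error(phantom_config(vdt_indolent = c(meanlog = log(300), sdlog = 0.2)),
               "above 400")
  expect_error(phantom_config(clinical_odds = list(
    sex = c(indolent = 1.3, aggressive = 0.3),
    copd = c(indolent = 0, aggressive = 0.2)
  )), "sex")
  expect_error(phantom_config(grid_shape = c(16, 16, 16)), "grid too small")
})
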