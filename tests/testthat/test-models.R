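# Logistic models, radiomics scores, performance evaluation, nomograms.

test_that("AUROC agrees between rank-sum formula and pair-counting oracle", {
  # 4-point worked example: 3 of 4 discordant-label pairs correctly ordered
  score <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  expect_equal(auroc(score, y), 0.75)
  expect_equal(oracle_auroc_pairs(score, y), 0.75)
  # random cross-checks including ties
  set.seed(3)
  for (i in 1:25) {
    s <- sample(seq(0, 1, 0.1), 20, replace = TRUE)
    yy <- rbinom(20, 1, 0.5)
    if (length(unique(yy)) < 2) next
    expect_equal(auroc(s, yy), oracle_auroc_pairs(s, yy))
  }
})

test_that("intercept-only model on balanced labels predicts one half", {
  d <- tibble::tibble(label = rep(c("aggressive", "indolent"), 20))
  m <- fit_logistic(d, character(0), "label")
  expect_equal(unname(coef(m$fit)[1]), 0, tolerance = 1e-8)
  expect_equal(unique(round(fitted(m$fit), 8)), 0.5)
})

test_that("single binary covariate recovers the contingency-table odds ratio", {
  # 2x2 counts (20, 10 / 10, 20) -> OR = (20*20)/(10*10) = 4
  d <- tibble::tibble(
    label = c(rep("aggressive", 30), rep("indolent", 30)),
    x = c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  )
  m <- fit_logistic(d, "x", "label")
  or <- m$coefficients$odds_ratio[m$coefficients$term == "x"]
  expect_equal(or, 4.0, tolerance = 1e-6)
  expect_equal(m$coefficients$odds_ratio, exp(m$coefficients$estimate))
})

test_that("coefficient estimates are consistent on simulated data", {
  set.seed(61)
  n <- 2000
  x <- rnorm(n)
  y <- ifelse(runif(n) < plogis(0.2 + 1.0 * x), "aggressive", "indolent")
  m <- fit_logistic(tibble::tibble(label = y, x = x), "x", "label")
  est <- m$coefficients$estimate[m$coefficients$term == "x"]
  se <- m$coefficients$std_error[m$coefficients$term == "x"]
  expect_lt(abs(est - 1.0), 3 * se)
})

test_that("radiomics score is the linear predictor and refits invariantly", {
  set.seed(71)
  n <- 150
  d <- tibble::tibble(
    label = rep(c("aggressive", "indolent"), n / 2),
    f1 = rnorm(n), f2 = rnorm(n)
  )
  d$f1 <- d$f1 + 1.2 * (d$label == "aggressive")
  m <- fit_logistic(d, c("f1", "f2"), "label")
  sc <- radiomics_score(m, d)
  expect_equal(sc, unname(coef(m$fit)[1] + coef(m$fit)[2] * d$f1 + coef(m$fit)[3] * d$f2))
  # refit on the score alone reproduces the original probabilities
  d2 <- tibble::tibble(label = d$label, score = sc)
  m2 <- fit_logistic(d2, "score", "label")
  expect_equal(unname(fitted(m2$fit)), unname(fitted(m$fit)), tolerance = 1e-8)
  # a unit increase in a covariate multiplies the odds by exp(beta)
  d_plus <- d; d_plus$f1 <- d_plus$f1 + 1
  expect_equal(radiomics_score(m, d_plus) - sc,
               rep(unname(coef(m$fit)[2]), n), tolerance = 1e-10)
  expect_error(radiomics_score(m, d[, "label", drop = FALSE]), "missing covariate")
})

test_that("clinical augmentation recovers planted effects and rejects null ones", {
  set.seed(81)
  n <- 400
  score <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  # true model: logit p = -1 + 0.8 score + log(5) sex; copd plays no role
  p <- plogis(-1 + 0.8 * score + log(5) * sex)
  label <- ifelse(runif(n) < p, "aggressive", "indolent")
  d <- tibble::tibble(label = label, radio = score, sex_female = sex,
                      copd = rbinom(n, 1, 0.15))
  m <- combine_clinical(d, "radio", c("sex_female", "copd"), "label")
  cf <- m$coefficients
  expect_gt(cf$estimate[cf$term == "radio"], 0)  # orientation
  est_sex <- cf$estimate[cf$term == "sex_female"]
  se_sex <- cf$std_error[cf$term == "sex_female"]
  expect_lt(abs(est_sex - log(5)), 3 * se_sex)
  # null covariate non-significant in most replicates
  null_sig <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    d$copd <- rbinom(n, 1, 0.15)
    ms <- combine_clinical(d, "radio", c("sex_female", "copd"), "label")
    pv <- ms$coefficients$p_value[ms$coefficients$term == "copd"]
    if (pv < 0.05) null_sig <- null_sig + 1
  }
  expect_lte(null_sig, 1)
})

test_that("evaluation reports Youden-threshold metrics and bootstrap CI", {
  set.seed(91)
  n <- 120
  y01 <- rep(c(1, 0), n / 2)
  d <- tibble::tibble(label = ifelse(y01 == 1, "aggressive", "indolent"),
                      x = 3 * y01 + rnorm(n))
  m <- fit_logistic(d, "x", "label")
  perf <- evaluate_model(m, n_boot = 200, seed = 7)
  expect_true(all(c(perf$auroc, perf$accuracy, perf$sensitivity,
                    perf$specificity) >= 0))
  expect_true(all(c(perf$auroc, perf$accuracy, perf$sensitivity,
                    perf$specificity) <= 1))
  expect_lte(perf$ci_lo, perf$ci_hi)
  # perfect separation: AUROC 1 and both rates 1 at the Youden threshold
  d2 <- tibble::tibble(label = ifelse(y01 == 1, "aggressive", "indolent"),
                       x = y01 * 10 + seq_len(n) * 1e-4)
  m2 <- fit_logistic(d2, "x", "label")
  expect_true(m2$separation)
  perf2 <- evaluate_model(m2, n_boot = 0)
  expect_equal(perf2$auroc, 1)
  expect_equal(perf2$sensitivity, 1)
  expect_equal(perf2$specificity, 1)
})

test_that("label permutation keeps the AUROC bootstrap CI around chance", {
  covered <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 80
    d <- tibble::tibble(label = sample(rep(c("aggressive", "indolent"), n / 2)),
                        x = rnorm(n))
    m <- fit_logistic(d, "x", "label")
    perf <- evaluate_model(m, n_boot = 200, seed = s)
    if (perf$ci_lo <= 0.5 + 0.1 && perf$ci_hi >= 0.5 - 0.1) covered <- covered + 1
  }
  expect_gte(covered, 9)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(60, 480), function(n) {
    set.seed(417)
    y01 <- rep(c(1, 0), n / 2)
    d <- tibble::tibble(label = ifelse(y01 == 1, "aggressive", "indolent"),
                        x = 1.2 * y01 + rnorm(n))
    m <- fit_logistic(d, "x", "label")
    perf <- evaluate_model(m, n_boot = 300, seed = 11)
    perf$ci_hi - perf$ci_lo
  }, numeric(1))
  expect_lt(widths[2], widths[1])
  expect_lt(widths[2], widths[1] / 1.3)  # ~ halved at 4x n, with slack
})

test_that("nomograms scale points to 100 and reconstruct probabilities exactly", {
  set.seed(101)
  n <- 100
  y01 <- rbinom(n, 1, 0.5)
  d <- tibble::tibble(
    label = ifelse(y01 == 1, "aggressive", "indolent"),
    a = rnorm(n, 0, 2) + y01, b = rnorm(n)
  )
  m <- fit_logistic(d, c("a", "b"), "label")
  nom <- build_nomogram(m)
  expect_equal(max(nom$scales$max_points), 100)
  # round trip: probability from total points equals the model probability
  pr <- nomogram_predict(nom, m$data)
  expect_equal(pr, unname(fitted(m$fit)), tolerance = 1e-6)
  # single covariate: spans 0-100 and equals inverse-logit directly
  m1 <- fit_logistic(d, "a", "label")
  nom1 <- build_nomogram(m1)
  expect_equal(nom1$scales$max_points, 100)
  pr1 <- nomogram_predict(nom1, m1$data)
  expect_equal(pr1, unname(fitted(m1$fit)), tolerance = 1e-8)
  # |beta * range| ratio 2:1 gives max points 100 and 50
  d3 <- tibble::tibble(label = d$label, u = d$a, v = d$a / 2 + rnorm(n, 0, 0.3))
  m3 <- fit_logistic(d3, c("u", "v"), "label")
  nom3 <- build_nomogram(m3)
  span_u <- abs(coef(m3$fit)["u"]) * diff(range(m3$data$u))
  span_v <- abs(coef(m3$fit)["v"]) * diff(range(m3$data$v))
  expected_ratio <- span_v / span_u
  got <- nom3$scales$max_points[nom3$scales$term == "v"] /
    nom3$scales$max_points[nom3$scales$term == "u"]
  expect_equal(got, unname(expected_ratio), tolerance = 1e-10)
  # zero-range covariate excluded with a warning
  d4 <- tibble::tibble(label = d$label, a = d$a, z = 1)
  m4 <- fit_logistic(d4, c("a", "z"), "label")
  expect_warning(nom4 <- build_nomogram(m4), "zero-range")
  expect_false("z" %in% nom4$scales$term)
})

test_that("tidiers and autoplot produce well-formed objects", {
  set.seed(111)
  n <- 60
  y01 <- rep(c(1, 0), n / 2)
  d <- tibble::tibble(label = ifelse(y01 == 1, "aggressive", "indolent"),
                      x = y01 + rnorm(n))
  m <- fit_logistic(d, "x", "label", family_tag = "combined")
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "odds_ratio", "p_value") %in% names(td)))
  g <- glance(m)
  expect_equal(g$n, n)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
  nom <- build_nomogram(m)
  expect_s3_class(autoplot(nom), "ggplot")
  expect_s3_class(plot_growth(growth_table(
    data.frame(patient = 1:2, interval = 1, v0 = c(1000, 900),
               vi = c(1500, 2500), ti = c(365, 350)))), "ggplot")
})
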