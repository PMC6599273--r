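# The four-stage dimensionality-reduction chain.

make_labelled_data <- function(n_per_class = 50, seed = 1) {
  set.seed(seed)
  y <- rep(c("indolent", "aggressive"), each = n_per_class)
  tibble::tibble(
    label = y,
    strong = as.numeric(y == "aggressive") + rnorm(2 * n_per_class, 0, 0.1),
    null1 = rnorm(2 * n_per_class),
    null2 = rnorm(2 * n_per_class),
    constant = 1
  )
}

test_that("t-test filter keeps strong effects and drops constants", {
  d <- make_labelled_data()
  tt <- ttest_filter(d, c("strong", "null1", "constant"), "label", alpha = 0.05)
  expect_true(tt$keep[tt$feature == "strong"])       # power ~ 1 at d = 10
  expect_false(tt$keep[tt$feature == "constant"])
  expect_equal(tt$reason[tt$feature == "constant"], "constant feature")
  expect_error(ttest_filter(d[d$label == "indolent", ], "strong", "label"),
               "both classes")
})

test_that("t-test filter type-I retention is close to alpha on null features", {
  set.seed(5)
  n <- 60
  y <- rep(c("indolent", "aggressive"), each = n / 2)
  nulls <- as.data.frame(matrix(rnorm(n * 1000), n, 1000))
  names(nulls) <- paste0("N", 1:1000)
  d <- dplyr::bind_cols(tibble::tibble(label = y), nulls)
  tt <- ttest_filter(d, names(nulls), "label", alpha = 0.05)
  kept <- mean(tt$keep)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(kept - 0.05), 3 * se)
})

test_that("bootstrap AUROC filter ranks separating and anti-predictive features", {
  set.seed(9)
  n <- 40
  y <- rep(c("aggressive", "indolent"), each = n / 2)
  d <- tibble::tibble(
    label = y,
    perfect = as.numeric(y == "aggressive") * 10 + seq_len(n) * 1e-3,
    anti = -(as.numeric(y == "aggressive")) * 2 + rnorm(n, 0, 0.3),
    noise = rnorm(n)
  )
  ab <- bootstrap_auroc_filter(d, c("perfect", "anti", "noise"), "label",
                               n_boot = 100, seed = 3)
  expect_equal(ab$mean_auroc[ab$feature == "perfect"], 1.0)
  expect_true(ab$keep[ab$feature == "perfect"])
  expect_false(ab$keep[ab$feature == "anti"])   # unflipped: below the floor
  # label-independent feature: mean bootstrap AUROC near 0.5 within
  # Monte-Carlo error of the estimate (the boundary decision is not asserted)
  mc <- ab$mean_auroc[ab$feature == "noise"]
  expect_lt(abs(mc - 0.5), 3 * sqrt(1 / 12 / 20))  # generous MC bound
  # reproducible under the same seed
  ab2 <- bootstrap_auroc_filter(d, c("perfect", "anti", "noise"), "label",
                                n_boot = 100, seed = 3)
  expect_identical(ab, ab2)
})

test_that("correlation pruning matches a brute-force component oracle", {
  set.seed(13)
  n <- 80
  base1 <- rnorm(n); base2 <- rnorm(n)
  d <- tibble::tibble(
    f1 = base1, f2 = base1 + rnorm(n, 0, 0.05), f3 = base1 + rnorm(n, 0, 0.05),
    f4 = base2, f5 = base2 * -1 + rnorm(n, 0, 0.05),
    f6 = rnorm(n)
  )
  feats <- names(d)
  au <- setNames(c(0.6, 0.9, 0.7, 0.55, 0.65, 0.52), feats)
  pr <- correlation_prune(d, feats, au, r_threshold = 0.8)
  # oracle components from the explicit adjacency matrix
  cm <- abs(cor(as.matrix(d)))
  adj <- cm >= 0.8; diag(adj) <- FALSE
  comp_oracle <- oracle_graph_components(adj)
  expect_equal(length(unique(pr$component)), length(unique(comp_oracle)))
  for (k in unique(comp_oracle)) {
    members <- feats[comp_oracle == k]
    kept <- pr$feature[pr$keep & pr$feature %in% members]
    expect_length(kept, 1)
    expect_equal(kept, members[which.max(au[members])])
  }
  # f2 wins its triplet; f5 wins the anticorrelated pair; f6 survives alone
  expect_setequal(pr$feature[pr$keep], c("f2", "f5", "f6"))
})

test_that("pruning keeps everything when no pair is correlated, one of dupes otherwise", {
  set.seed(21)
  d <- tibble::tibble(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  au <- setNames(c(0.6, 0.7, 0.55), names(d))
  pr <- correlation_prune(d, names(d), au, 0.8)
  expect_true(all(pr$keep))
  d$dup <- d$a
  au2 <- c(au, dup = 0.8)
  pr2 <- correlation_prune(d, names(d), au2, 0.8)
  expect_true(pr2$keep[pr2$feature == "dup"])   # higher AUROC copy
  expect_false(pr2$keep[pr2$feature == "a"])
})

test_that("backward elimination finds the planted predictor among noise", {
  set.seed(33)
  n <- 200
  x <- rnorm(n)
  p <- plogis(-0.3 + 2.5 * x)
  y <- ifelse(runif(n) < p, "aggressive", "indolent")
  d <- tibble::tibble(label = y, strong = x)
  for (k in 1:5) d[[paste0("noise", k)]] <- rnorm(n)
  be <- backward_eliminate(d, c("strong", paste0("noise", 1:5)), "label")
  expect_true("strong" %in% be$features)
  expect_lte(length(be$features), 3)  # most noise eliminated
  expect_true(all(be$trace$action %in% c("remove", "enter")))
})

test_that("null predictors are eliminated in most replicates", {
  empty_runs <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 120
    d <- tibble::tibble(label = rep(c("aggressive", "indolent"), n / 2),
                        a = rnorm(n), b = rnorm(n), c = rnorm(n))
    be <- backward_eliminate(d, c("a", "b", "c"), "label")
    if (length(be$features) == 0) empty_runs <- empty_runs + 1
  }
  expect_gte(empty_runs, 9)
})

test_that("a single weak predictor is eliminated to the intercept-only model", {
  set.seed(7)
  n <- 80
  d <- tibble::tibble(label = rep(c("aggressive", "indolent"), n / 2),
                      weak = rnorm(n))
  # verify the fixture really is weak (p > 0.10), then eliminate
  p <- summary(glm(I(label == "aggressive") ~ weak, data = d,
                   family = binomial()))$coefficients["weak", 4]
  expect_gt(p, 0.10)
  be <- backward_eliminate(d, "weak", "label")
  expect_length(be$features, 0)
})

test_that("the full chain nests survivors and is reproducible", {
  d <- make_labelled_data(n_per_class = 60, seed = 44)
  d$corr_strong <- d$strong + rnorm(120, 0, 0.02)
  feats <- c("strong", "corr_strong", "null1", "null2", "constant")
  cfg <- selection_config(seed = 5)
  rep1 <- select_features(d, feats, "label", cfg)
  rep2 <- select_features(d, feats, "label", cfg)
  expect_identical(rep1$survivors, rep2$survivors)
  s <- rep1$survivors
  expect_true(all(s$auroc %in% s$ttest))
  expect_true(all(s$pruning %in% s$auroc))
  expect_true(all(s$final %in% s$pruning))
  # the correlated duplicate pair collapses to one survivor
  expect_equal(sum(c("strong", "corr_strong") %in% s$pruning), 1)
  expect_true(any(c("strong", "corr_strong") %in% s$final))
  g <- glance(rep1)
  expect_equal(g$n_candidates, 5)
  td <- tidy(rep1)
  expect_equal(nrow(td), 5)
  expect_true(all(is.na(td$dropped_at[td$feature %in% s$final])))
})

test_that("small backward eliminations replay step by step against a naive oracle", {
  # naive reimplementation: repeatedly drop the worst Wald p > 0.10 with no
  # re-entry check needed when nothing re-enters
  set.seed(55)
  n <- 150
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- ifelse(runif(n) < plogis(1.5 * x1 + 0.8 * x2), "aggressive", "indolent")
  d <- tibble::tibble(label = y, x1 = x1, x2 = x2, x3 = x3)
  be <- backward_eliminate(d, c("x1", "x2", "x3"), "label")
  oracle_vars <- c("x1", "x2", "x3")
  yb <- as.integer(d$label == "aggressive")
  repeat {
    fit <- glm(reformulate(oracle_vars, "yb"), data = cbind(yb = yb, d),
               family = binomial())
    pv <- summary(fit)$coefficients[-1, 4]
    if (max(pv) <= 0.10) break
    oracle_vars <- oracle_vars[-which.max(pv)]
    if (!length(oracle_vars)) break
  }
  expect_setequal(be$features, oracle_vars)
})
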