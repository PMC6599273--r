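## Dimensionality-reduction chain: univariate t-test filter, per-feature
## bootstrap AUROC filter, Pearson-correlation pruning, and
## backward-stepwise logistic elimination.

#' Selection configuration
#'
#' @param alpha_ttest significance level of the univariate t-test filter.
#' @param n_boot_feature bootstrap replicates per feature in the AUROC
#'   filter.
#' @param auroc_floor minimum mean bootstrap AUROC to retain a feature
#'   (unflipped: anti-predictive features fall below the floor and drop).
#' @param r_threshold absolute Pearson correlation at or above which two
#'   features are considered redundant.
#' @param p_enter,p_remove backward-stepwise entry/removal p-values.
#' @param positive_class label treated as positive when ranking.
#' @param welch use Welch's t-test instead of the pooled-variance Student
#'   test.
#' @param max_model_features at most this many correlation-pruning
#'   survivors (the top ranked by mean bootstrap AUROC) enter the
#'   multivariable stage, which needs more observations than covariates.
#' @param seed RNG seed for the bootstrap stage.
#' @return A `selection_config` list.
#' @export
selection_config <- function(alpha_ttest = 0.05, n_boot_feature = 200L,
                             auroc_floor = 0.5, r_threshold = 0.8,
                             p_enter = 0.05, p_remove = 0.10,
                             positive_class = "aggressive",
                             welch = FALSE, max_model_features = 30L,
                             seed = 1L) {
  stopifnot(alpha_ttest > 0, alpha_ttest < 1, n_boot_feature >= 1,
            r_threshold >= 0, r_threshold <= 1, max_model_features >= 1)
  structure(
    list(alpha_ttest = alpha_ttest, n_boot_feature = as.integer(n_boot_feature),
         auroc_floor = auroc_floor, r_threshold = r_threshold,
         p_enter = p_enter, p_remove = p_remove,
         positive_class = positive_class, welch = welch,
         max_model_features = as.integer(max_model_features),
         seed = as.integer(seed)),
    class = "selection_config"
  )
}

binary_label <- function(label, positive_class) {
  label <- as.character(label)
  u <- unique(label)
  if (length(u) != 2) stop("exactly two classes are required", call. = FALSE)
  if (!positive_class %in% u) {
    stop(sprintf("positive class '%s' not present", positive_class), call. = FALSE)
  }
  as.integer(label == positive_class)
}

#' Univariate two-sample t-test filter
#'
#' Keeps features whose two-sample (pooled-variance Student, or Welch by
#' flag) t-test p-value comparing the two growth classes is below `alpha`.
#' Constant features (zero pooled variance) are dropped with a logged
#' reason; missing values are dropped per feature.
#'
#' @param data data frame with the feature columns and a label column.
#' @param features character vector of feature column names.
#' @param label name of the label column (two classes).
#' @param alpha significance level.
#' @param welch use Welch's correction.
#' @return Tibble `feature`, `p_value`, `n_used`, `keep`, `reason`.
#' @export
ttest_filter <- function(data, features, label = "label", alpha = 0.05,
                         welch = FALSE) {
  y <- as.character(data[[label]])
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  purrr::map_dfr(features, function(f) {
    x <- data[[f]]
    ok <- is.finite(x)
    xs <- x[ok]; ys <- y[ok]
    if (length(unique(ys)) < 2 || min(table(ys)) < 2) {
      return(tibble::tibble(feature = f, p_value = NA_real_, n_used = sum(ok),
                            keep = FALSE, reason = "insufficient observations"))
    }
    if (stats::var(xs) == 0) {
      return(tibble::tibble(feature = f, p_value = NA_real_, n_used = sum(ok),
                            keep = FALSE, reason = "constant feature"))
    }
    p <- tryCatch(
      stats::t.test(xs ~ ys, var.equal = !welch)$p.value,
      error = function(e) NA_real_
    )
    tibble::tibble(feature = f, p_value = p, n_used = sum(ok),
                   keep = is.finite(p) && p < alpha,
                   reason = NA_character_)
  })
}

#' Rank-sum AUROC
#'
#' Area under the ROC curve by the Mann-Whitney formulation with 0.5
#' credit for ties: the probability that a random positive scores above a
#' random negative.
#'
#' @param score numeric scores.
#' @param y 0/1 labels (1 = positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-feature bootstrap AUROC filter
#'
#' For each feature, computes the AUROC on `n_boot` stratified bootstrap
#' resamples (resampling within class keeps both classes present) and
#' keeps features whose mean bootstrap AUROC is at or above the floor.
#' AUROC orientation is not flipped, so anti-predictive features fall
#' below a 0.5 floor and are dropped.
#'
#' @inheritParams ttest_filter
#' @param n_boot bootstrap replicates.
#' @param floor mean-AUROC retention threshold.
#' @param positive_class label treated as positive.
#' @param seed RNG seed.
#' @return Tibble `feature`, `mean_auroc`, `keep`.
#' @export
bootstrap_auroc_filter <- function(data, features, label = "label",
                                   n_boot = 200L, floor = 0.5,
                                   positive_class = "aggressive", seed = 1L) {
  y <- binary_label(data[[label]], positive_class)
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) stop("both classes must be present", call. = FALSE)
  with_seed(seed, {
    boots <- lapply(seq_len(n_boot), function(b) {
      c(sample(i1, length(i1), replace = TRUE),
        sample(i0, length(i0), replace = TRUE))
    })
    yb <- c(rep(1L, length(i1)), rep(0L, length(i0)))
    purrr::map_dfr(features, function(f) {
      x <- data[[f]]
      aucs <- vapply(boots, function(idx) {
        xi <- x[idx]
        ok <- is.finite(xi)
        auroc(xi[ok], yb[ok])
      }, numeric(1))
      m <- mean(aucs, na.rm = TRUE)
      tibble::tibble(feature = f, mean_auroc = m, keep = is.finite(m) && m >= floor)
    })
  })
}

## connected components of an undirected adjacency matrix (BFS)
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    k <- k + 1L
    frontier <- v
    comp[v] <- k
    while (length(frontier)) {
      nbr <- which(matrixStats_any(adj[frontier, , drop = FALSE]))
      nbr <- nbr[comp[nbr] == 0L]
      comp[nbr] <- k
      frontier <- nbr
    }
  }
  comp
}

matrixStats_any <- function(m) colSums(m) > 0

#' Pearson-correlation pruning
#'
#' Builds a graph on the surviving features with an edge wherever the
#' absolute pairwise Pearson correlation (pairwise-complete observations)
#' is at or above the threshold, and keeps exactly one feature per
#' connected component: the one with the largest mean bootstrap AUROC
#' (ties broken by lower catalogue position). Output preserves the input
#' feature order.
#'
#' @inheritParams ttest_filter
#' @param mean_auroc named numeric (or tibble from
#'   [bootstrap_auroc_filter()]) of mean AUROCs for all candidate features.
#' @param r_threshold absolute-correlation cut.
#' @return Tibble `feature`, `component`, `mean_auroc`, `keep`.
#' @export
correlation_prune <- function(data, features, mean_auroc, r_threshold = 0.8) {
  if (is.data.frame(mean_auroc)) {
    mean_auroc <- stats::setNames(mean_auroc$mean_auroc, mean_auroc$feature)
  }
  if (!all(features %in% names(mean_auroc))) {
    stop("mean AUROCs must be available for all features", call. = FALSE)
  }
  if (!length(features)) {
    return(tibble::tibble(feature = character(), component = integer(),
                          mean_auroc = numeric(), keep = logical()))
  }
  X <- as.matrix(data[features])
  n_missing <- sum(!is.finite(X))
  if (n_missing > 0) {
    message(sprintf("correlation pruning: %d missing values, pairwise-complete correlations",
                    n_missing))
  }
  X[!is.finite(X)] <- NA
  cm <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  adj <- abs(cm) >= r_threshold
  diag(adj) <- FALSE
  comp <- adjacency_components(adj)
  au <- mean_auroc[features]
  keep <- logical(length(features))
  for (k in unique(comp)) {
    members <- which(comp == k)
    best <- members[order(-au[members], members)][1]
    keep[best] <- TRUE
  }
  tibble::tibble(feature = features, component = comp,
                 mean_auroc = unname(au), keep = keep)
}

## Wald p-values of a fitted glm (excluding intercept)
wald_p <- function(fit) {
  cf <- summary(fit)$coefficients
  p <- cf[, 4]
  p[setdiff(names(p), "(Intercept)")]
}

separation_flag <- function(fit) {
  cf <- summary(fit)$coefficients
  any(abs(cf[, 1]) > 15) || any(cf[, 2] > 100) || !fit$converged
}

#' Backward-stepwise logistic elimination
#'
#' Starts from the full logistic model on the given features, iteratively
#' removes the covariate with the largest Wald p-value above `p_remove`,
#' and after each removal re-admits any excluded covariate whose
#' added-last p-value falls below `p_enter`; stops at a fixed point.
#' Separation (exploding coefficients or standard errors) is detected and
#' flagged, not fatal: the offending covariate is retained with the
#' capped-iteration fit and the report carries `separation = TRUE`.
#'
#' @inheritParams ttest_filter
#' @param p_enter,p_remove stepwise thresholds.
#' @param positive_class label treated as positive (modelled as 1).
#' @return List with `features` (final set), `fit` (the final `glm`),
#'   `trace` (tibble of steps), `separation` flag.
#' @export
backward_eliminate <- function(data, features, label = "label",
                               p_enter = 0.05, p_remove = 0.10,
                               positive_class = "aggressive") {
  y <- binary_label(data[[label]], positive_class)
  df <- data.frame(.y = y, data[features], check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(features) + 2) {
    stop("need at least `length(features) + 2` complete observations", call. = FALSE)
  }
  fit_on <- function(vars) {
    fml <- if (length(vars)) {
      stats::reformulate(sprintf("`%s`", vars), response = ".y")
    } else {
      stats::as.formula(".y ~ 1")
    }
    suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  }
  current <- features
  excluded <- character()
  trace <- list()
  seen <- character()
  step <- 0L
  sep_flag <- FALSE
  repeat {
    key <- paste(sort(current), collapse = "|")
    if (key %in% seen) break
    seen <- c(seen, key)
    fit <- fit_on(current)
    sep_flag <- sep_flag || separation_flag(fit)
    changed <- FALSE
    if (length(current)) {
      cf <- summary(fit)$coefficients
      rn <- gsub("`", "", rownames(cf))
      p <- vapply(current, function(v) {
        k <- match(v, rn)
        if (is.na(k) || !is.finite(cf[k, 4])) return(1)
        ## a quasi-separated covariate has an exploding coefficient and a
        ## meaningless Wald p (Hauck-Donner); protect it from removal and
        ## let the separation flag carry the caveat
        if (abs(cf[k, 1]) > 15 || cf[k, 2] > 100) return(0)
        cf[k, 4]
      }, numeric(1))
      worst <- which.max(p)
      if (p[worst] > p_remove) {
        step <- step + 1L
        trace[[step]] <- tibble::tibble(step = step, action = "remove",
                                        variable = current[worst],
                                        p_value = unname(p[worst]))
        excluded <- c(excluded, current[worst])
        current <- current[-worst]
        changed <- TRUE
      }
    }
    if (changed && length(excluded)) {
      ## re-entry: add-last p-value of each excluded covariate
      addp <- vapply(excluded, function(v) {
        f2 <- fit_on(c(current, v))
        p2 <- wald_p(f2)
        hit <- p2[names(p2) %in% c(v, sprintf("`%s`", v))]
        if (length(hit) && is.finite(hit[1])) hit[1] else 1
      }, numeric(1))
      if (length(addp) && min(addp) < p_enter) {
        best <- names(addp)[which.min(addp)]
        step <- step + 1L
        trace[[step]] <- tibble::tibble(step = step, action = "enter",
                                        variable = best,
                                        p_value = unname(min(addp)))
        current <- c(current, best)
        excluded <- setdiff(excluded, best)
      }
    }
    if (!changed) break
  }
  final_fit <- fit_on(current)
  sep_flag <- sep_flag || separation_flag(final_fit)
  list(
    features = current,
    fit = final_fit,
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), action = character(),
                     variable = character(), p_value = numeric()),
    separation = sep_flag
  )
}

#' Run the full selection chain
#'
#' t-test filter, bootstrap AUROC filter, correlation pruning, then
#' backward-stepwise logistic elimination, with survivor nesting by
#' construction. Returns a replayable report.
#'
#' @inheritParams ttest_filter
#' @param config a [selection_config()].
#' @return A `selection_report`: list with per-stage tibbles
#'   (`ttest`, `auroc`, `pruning`, `elimination` trace), per-stage
#'   survivor lists (`survivors`), the final `fit`, and flags.
#' @export
select_features <- function(data, features, label = "label",
                            config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  tt <- ttest_filter(data, features, label, config$alpha_ttest, config$welch)
  s1 <- tt$feature[tt$keep]
  n_dropped_degenerate <- sum(!is.na(tt$reason) & tt$reason == "constant feature")
  if (n_dropped_degenerate > 0) {
    message(sprintf("selection: dropped %d degenerate (constant) features",
                    n_dropped_degenerate))
  }
  ab <- if (length(s1)) {
    bootstrap_auroc_filter(data, s1, label, config$n_boot_feature,
                           config$auroc_floor, config$positive_class, config$seed)
  } else {
    tibble::tibble(feature = character(), mean_auroc = numeric(), keep = logical())
  }
  s2 <- ab$feature[ab$keep]
  pr <- correlation_prune(data, s2, ab, config$r_threshold)
  s3 <- pr$feature[pr$keep]
  cap <- min(config$max_model_features, nrow(data) - 2L)
  if (length(s3) > cap) {
    au3 <- stats::setNames(ab$mean_auroc, ab$feature)[s3]
    message(sprintf("selection: capping multivariable candidates at %d of %d (top mean AUROC)",
                    cap, length(s3)))
    s3 <- s3[order(-au3, seq_along(s3))][seq_len(cap)]
    s3 <- s3[order(match(s3, pr$feature))]  # restore catalogue order
  }
  el <- if (length(s3)) {
    backward_eliminate(data, s3, label, config$p_enter, config$p_remove,
                       config$positive_class)
  } else {
    list(features = character(), fit = NULL,
         trace = tibble::tibble(step = integer(), action = character(),
                                variable = character(), p_value = numeric()),
         separation = FALSE)
  }
  structure(
    list(
      config = config,
      ttest = tt, auroc = ab, pruning = pr, elimination = el$trace,
      survivors = list(ttest = s1, auroc = s2, pruning = s3,
                       final = el$features),
      fit = el$fit, separation = el$separation, label = label
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d -> %d (t-test) -> %d (bootstrap AUROC) -> %d (correlation) -> %d (backward elimination)%s\n",
    nrow(x$ttest), length(x$survivors$ttest), length(x$survivors$auroc),
    length(x$survivors$pruning), length(x$survivors$final),
    if (x$separation) " [separation flagged]" else ""
  ))
  invisible(x)
}
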