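#' Baseline (pre-treatment) feature screening
#'
#' Two-sample t-test per feature comparing poor responders against
#' responders on fraction-1 feature values, with Bonferroni correction over
#' the 39 tests at alpha = 0.05. Welch's unequal-variance form is the
#' default; the pooled-variance form is available via `var_equal`.
#'
#' @param X Numeric matrix (patients x features) of baseline feature values.
#' @param y Logical or 0/1 vector: `TRUE` = poor response.
#' @param alpha Significance level after correction (default 0.05).
#' @param var_equal Use the pooled-variance t-test (default `FALSE` = Welch).
#' @return A data.frame of class `screening_report` with columns `feature`,
#'   `t`, `p_raw`, `p_bonferroni` (`= min(1, p_raw * n_features)`) and
#'   `significant`.
#' @export
screen_baseline_features <- function(X, y, alpha = 0.05, var_equal = FALSE) {
  X <- as.matrix(X)
  y <- as.logical(y)
  if (length(y) != nrow(X)) stop("label length mismatch", call. = FALSE)
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 patients per class for a t-test", call. = FALSE)
  res <- apply(X, 2, function(col) {
    tt <- stats::t.test(col[y], col[!y], var.equal = var_equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  p_adj <- stats::p.adjust(res["p", ], method = "bonferroni")
  out <- data.frame(feature = colnames(X), t = res["t", ],
                    p_raw = res["p", ], p_bonferroni = p_adj,
                    significant = p_adj <= alpha, row.names = NULL)
  class(out) <- c("screening_report", "data.frame")
  out
}

#' Rank delta features by random-forest Gini importance
#'
#' Grows a classification random forest (default 500 trees, `mtry = 6`,
#' roughly the square root of the 39 delta features) on bootstrap resamples
#' drawn with replacement, and ranks features by mean decrease in Gini
#' impurity. Equal importances are broken by canonical column order (the
#' underlying stable sort), so the ranking is fully deterministic for a
#' fixed seed.
#'
#' @param X Numeric matrix or data.frame (patients x features).
#' @param y Labels (logical or two-level factor); `TRUE` = poor response.
#' @param n_trees Number of trees (default 500).
#' @param mtry Candidate features per split (default 6, capped at the number
#'   of predictors).
#' @param seed Integer RNG seed.
#' @return An object of class `gini_ranking`: `importance` (named, canonical
#'   order), `ranking` (feature names, descending importance), `top2`, and
#'   `rf_config`.
#' @export
rank_features_gini <- function(X, y, n_trees = 500, mtry = 6, seed = 1) {
  X <- as.data.frame(X)
  yf <- factor(as.logical(y), levels = c(FALSE, TRUE))
  if (nlevels(droplevels(yf)) < 2)
    stop("labels contain a single class", call. = FALSE)
  if (min(table(yf)) < 2)
    stop("need at least 2 patients per class", call. = FALSE)
  mtry_used <- min(mtry, ncol(X))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = yf, ntree = n_trees,
                                   mtry = mtry_used, importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  ord <- order(-imp)          # stable: ties keep canonical column order
  structure(list(importance = imp,
                 ranking = names(imp)[ord],
                 top2 = names(imp)[ord][1:2],
                 rf_config = list(n_trees = n_trees, mtry = mtry_used,
                                  seed = seed),
                 forest = rf),
            class = "gini_ranking")
}

#' @export
print.gini_ranking <- function(x, n = 5, ...) {
  cat(sprintf("<gini_ranking> %d features, %d trees, mtry = %d, seed = %d\n",
              length(x$importance), x$rf_config$n_trees, x$rf_config$mtry,
              x$rf_config$seed))
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  for (f in top)
    cat(sprintf("  %-40s %8.4f\n", f, x$importance[f]))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `U / (n_pos * n_neg)` with half credit for tied scores: the probability
#' that a random positive outscores a random negative. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric predictions (higher = more likely positive).
#' @param labels Logical or 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)                       # midranks give ties half credit
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ridge-penalized logistic regression by iteratively reweighted least
# squares, scored on new data. The fixed small penalty on the slope
# coefficients keeps the fit finite under complete separation (common at
# n = 22 with a strong 2-feature signal) and under single-observation
# classes, which the subsampling scheme deliberately permits. The penalty
# leaves the score ordering essentially untouched.
.lr_score <- function(X_train, y_train, X_test, lambda = 1e-3) {
  X1 <- cbind(1, X_train)
  p <- ncol(X1)
  pen <- diag(c(1e-10, rep(lambda, p - 1)), p)  # intercept unpenalized
  beta <- numeric(p)
  yt <- as.numeric(y_train)
  for (it in seq_len(50L)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, yt - mu)) - drop(pen %*% beta)
    H <- crossprod(X1 * w, X1) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  drop(cbind(1, X_test) %*% beta)
}

#' Bootstrapped logistic-regression internal validation AUC
#'
#' Monte-Carlo subsampling without replacement: each iteration draws
#' `floor(train_frac * n)` patients for training, fits a two-feature
#' logistic regression (with a small fixed ridge penalty for stability under
#' separation), scores the held-out remainder, and records the AUC. The
#' held-out third is only meaningful with subsampling *without* replacement;
#' iterations whose train or test partition contains a single class are
#' redrawn and the redraw count reported. Mean and 2.5/97.5 percentiles are
#' computed over the retained iterations.
#'
#' @param X Numeric matrix (patients x 2 selected features). More than two
#'   columns are accepted but the standard analysis uses the Gini top 2.
#' @param y Labels (logical or 0/1); `TRUE` = poor response.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param train_frac Training fraction (default 2/3).
#' @param seed Integer RNG seed.
#' @param ridge_lambda Ridge penalty for the logistic fit (default 1e-3).
#' @return Object of class `boot_auc_report`: `aucs` (length `n_iter`),
#'   `mean_auc`, `p2.5`, `p97.5`, `n_redraws`, `config`.
#' @export
bootstrap_lr_auc <- function(X, y, n_iter = 1000, train_frac = 2/3, seed = 1,
                             ridge_lambda = 1e-3) {
  X <- as.matrix(X)
  y <- as.logical(y)
  n <- nrow(X)
  if (length(y) != n) stop("label length mismatch", call. = FALSE)
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 patients per class", call. = FALSE)
  n_train <- floor(train_frac * n)
  if (n_train < 2 || n_train > n - 2)
    stop("train fraction leaves too few patients in a partition",
         call. = FALSE)
  set.seed(seed)
  aucs <- numeric(n_iter)
  redraws <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      tr <- sample.int(n, n_train)
      ytr <- y[tr]; yte <- y[-tr]
      if (any(ytr) && !all(ytr) && any(yte) && !all(yte)) break
      redraws <- redraws + 1L
    }
    sc <- suppressWarnings(
      .lr_score(X[tr, , drop = FALSE], ytr, X[-tr, , drop = FALSE],
                lambda = ridge_lambda))
    aucs[i] <- auc(sc, yte)
  }
  qs <- stats::quantile(aucs, c(0.025, 0.975), names = FALSE)
  structure(list(aucs = aucs, mean_auc = mean(aucs),
                 p2.5 = qs[1], p97.5 = qs[2], n_redraws = redraws,
                 config = list(n_iter = n_iter, train_frac = train_frac,
                               seed = seed, ridge_lambda = ridge_lambda)),
            class = "boot_auc_report")
}

#' @export
print.boot_auc_report <- function(x, ...) {
  cat(sprintf(
    "<boot_auc_report> mean AUC = %.3f (2.5-97.5 pct: %.3f-%.3f), %d iterations, %d redraw(s)\n",
    x$mean_auc, x$p2.5, x$p97.5, x$config$n_iter, x$n_redraws))
  invisible(x)
}

#' @export
summary.boot_auc_report <- function(object, ...) {
  c(mean_auc = object$mean_auc, p2.5 = object$p2.5, p97.5 = object$p97.5,
    n_redraws = object$n_redraws)
}

#' Clinical covariate presets
#'
#' Two covariate sets ship with the package: `"planned"` — BED per fraction,
#' maximum tumour dimension, sex, ethnicity, Karnofsky performance status
#' and prior cirrhosis — and `"reported"` — age, total BED, BED per fraction
#' and tumour size, the set actually tabulated for the cohort. The choice is
#' configuration, not code.
#'
#' @param preset `"planned"` or `"reported"`.
#' @return Character vector of covariate column names.
#' @export
clinical_covariate_preset <- function(preset = c("reported", "planned")) {
  preset <- match.arg(preset)
  switch(preset,
         reported = c("age", "total_bed", "bed_per_fx", "tumor_size"),
         planned = c("bed_per_fx", "tumor_size", "sex", "ethnicity", "kps",
                     "cirrhosis"))
}

#' Clinical and combined random-forest models
#'
#' Fits a clinical-only random forest (500 trees, `mtry = 6`) on the
#' requested covariates and a combined forest (`mtry = 8`) on covariates plus
#' the top-2 delta features, returning Gini rankings and out-of-bag AUC
#' estimates (labelled as out-of-bag; no resubstitution estimate is
#' reported). `mtry` is capped at the number of predictors.
#'
#' @param cohort A data.frame with one row per patient containing the
#'   requested covariate columns and a logical `poor_response` column (or
#'   supply `y`).
#' @param top2_deltas Numeric matrix (patients x 2) of the selected delta
#'   features, or `NULL` to skip the combined model.
#' @param covariates Character vector of covariate columns; defaults to the
#'   `"reported"` preset from [clinical_covariate_preset()].
#' @param y Optional labels overriding `cohort$poor_response`.
#' @param n_trees,mtry_clinical,mtry_combined Forest settings.
#' @param seed Integer RNG seed.
#' @return A list of class `clinical_models`: `clinical` and (optionally)
#'   `combined`, each with `importance`, `ranking`, `oob_auc`.
#' @export
fit_clinical_and_combined <- function(cohort, top2_deltas = NULL,
                                      covariates = clinical_covariate_preset(),
                                      y = NULL, n_trees = 500,
                                      mtry_clinical = 6, mtry_combined = 8,
                                      seed = 1) {
  cohort <- as.data.frame(cohort)
  missing <- setdiff(covariates, names(cohort))
  if (length(missing))
    stop("requested covariate(s) absent from cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(y)) {
    if (is.null(cohort$poor_response))
      stop("no labels: supply `y` or a poor_response column", call. = FALSE)
    y <- cohort$poor_response
  }
  yf <- factor(as.logical(y), levels = c(FALSE, TRUE))
  Xc <- cohort[, covariates, drop = FALSE]
  Xc[] <- lapply(Xc, function(col) if (is.character(col)) factor(col) else col)
  fit_one <- function(Xd, mtry, seed_off) {
    set.seed(seed + seed_off)
    # a never-varying covariate cannot split; drop before fitting (the
    # forest code does not terminate when every predictor is constant)
    constant <- vapply(Xd, function(col) length(unique(col)) <= 1L,
                       logical(1))
    imp <- stats::setNames(numeric(ncol(Xd)), names(Xd))
    if (all(constant))
      return(list(importance = imp, ranking = names(imp),
                  oob_auc = 0.5, mtry = 0L))
    Xv <- Xd[, !constant, drop = FALSE]
    rf <- randomForest::randomForest(
      x = Xv, y = yf, ntree = n_trees, mtry = min(mtry, ncol(Xv)))
    imp[colnames(Xv)] <- rf$importance[, "MeanDecreaseGini"]
    votes <- rf$votes[, "TRUE"]
    list(importance = imp, ranking = names(imp)[order(-imp)],
         oob_auc = auc(votes, yf == "TRUE"), mtry = min(mtry, ncol(Xv)))
  }
  out <- list(clinical = fit_one(Xc, mtry_clinical, 0L))
  if (!is.null(top2_deltas)) {
    D <- as.data.frame(top2_deltas)
    if (nrow(D) != nrow(Xc))
      stop("delta feature rows must match cohort rows", call. = FALSE)
    out$combined <- fit_one(cbind(Xc, D), mtry_combined, 1L)
  }
  structure(out, class = "clinical_models")
}

#' @export
print.clinical_models <- function(x, ...) {
  cat(sprintf("<clinical_models> clinical OOB AUC = %.3f (top: %s)\n",
              x$clinical$oob_auc, x$clinical$ranking[1]))
  if (!is.null(x$combined))
    cat(sprintf("  combined OOB AUC = %.3f (top: %s)\n",
                x$combined$oob_auc, x$combined$ranking[1]))
  invisible(x)
}
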