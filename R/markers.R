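#' Area under the ROC curve (rank statistic)
#'
#' Computed from the Mann-Whitney identity on ranks; tied scores
#' contribute 1/2, so the statistic is invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores numeric classifier scores, higher = more case-like.
#' @param labels logical (TRUE = positive class) or character/factor with
#'   `positive` naming the positive class.
#' @param positive positive-class label used when `labels` is not logical.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = "CRC") {
  if (!is.logical(labels)) labels <- labels == positive
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) mk_stop("auroc", "both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Random-forest hyperparameter specification
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @param max_features_per_tree variables tried per split (`NULL` =
#'   floor(sqrt(p))).
#' @param max_samples fraction of samples drawn per tree.
#' @param seed integer seed used when fitting.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(n_trees = 500L, max_depth = 0L,
                            max_features_per_tree = NULL,
                            max_samples = 1.0, seed = 1L) {
  stopifnot(n_trees > 0, max_depth >= 0, max_samples > 0, max_samples <= 1)
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 max_features_per_tree = max_features_per_tree,
                 max_samples = max_samples, seed = as.integer(seed)),
            class = "classifier_spec")
}

# Feature matrix (samples x panel features) and case indicator for a profile.
#' @keywords internal
design_xy <- function(profile, features, warn_missing = TRUE) {
  present <- intersect(features, rownames(profile$abundance))
  X <- matrix(0, ncol(profile$abundance), length(features),
              dimnames = list(colnames(profile$abundance), features))
  X[, present] <- t(profile$abundance[present, , drop = FALSE])
  if (warn_missing && length(present) < length(features)) {
    mk_warn("markers", length(features) - length(present),
            " panel feature(s) absent; zero-filled")
  }
  list(X = X, y = profile$metadata$group == "CRC")
}

#' @keywords internal
rf_fit <- function(X, y, spec, seed = spec$seed) {
  mtry <- spec$max_features_per_tree %||% max(1L, floor(sqrt(ncol(X))))
  ranger::ranger(
    x = as.data.frame(X), y = factor(ifelse(y, "CRC", "CTR"), c("CTR", "CRC")),
    num.trees = spec$n_trees, mtry = min(mtry, ncol(X)),
    max.depth = spec$max_depth, sample.fraction = spec$max_samples,
    probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
}

#' @keywords internal
rf_score <- function(fit, X) {
  stats::predict(fit, data = as.data.frame(X), num.threads = 1)$predictions[, "CRC"]
}

# Stratified k-fold CV AUROC of a random forest; returns fold AUROCs and
# the pooled out-of-fold scores for bootstrap CIs.
#' @keywords internal
rf_cv_auroc <- function(X, y, spec, k = 5L, seed = 1L) {
  folds <- stratified_folds(y, k, child_seed(seed, "folds"))
  oof <- numeric(length(y))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- rf_fit(X[tr, , drop = FALSE], y[tr], spec, seed = child_seed(seed, paste0("fold", f)))
    oof[!tr] <- rf_score(fit, X[!tr, , drop = FALSE])
    fold_auc[f] <- auroc(oof[!tr], y[!tr])
  }
  list(mean_auroc = mean(fold_auc), fold_aurocs = fold_auc,
       oof_scores = oof, labels = y, folds = folds)
}

#' Percentile bootstrap confidence interval for an AUROC
#'
#' Resamples pooled (score, label) pairs with replacement; draws without
#' both classes are redrawn implicitly by skipping.
#'
#' @param scores,labels pooled predictions and truth.
#' @param n_boot number of bootstrap resamples (>= 1000 recommended).
#' @param level confidence level.
#' @param seed integer seed.
#' @return `c(low, high)`.
#' @export
auroc_bootstrap_ci <- function(scores, labels, n_boot = 1000L, level = 0.95,
                               seed = 1L) {
  if (!is.logical(labels)) labels <- labels == "CRC"
  restore <- local_rng(child_seed(seed, "boot"))
  on.exit(restore())
  n <- length(scores)
  stat <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    auroc(scores[idx], labels[idx])
  }, numeric(1))
  stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
}

# Orientation-free cross-validated AUROC of a single feature used as its
# own score.
#' @keywords internal
single_feature_auroc <- function(x, y, k = 5L, seed = 1L) {
  folds <- stratified_folds(y, k, child_seed(seed, "sfolds"))
  a <- mean(vapply(seq_len(k), function(f) {
    auroc(x[folds == f], y[folds == f])
  }, numeric(1)))
  max(a, 1 - a)
}

#' Step 1 of marker selection: effective-feature screening
#'
#' Each differential feature is scored by the orientation-free
#' cross-validated AUROC of a single-feature classifier; features at or
#' above `threshold` are retained.
#'
#' @param features candidate feature ids (normally the significant
#'   differential features).
#' @param profile an [abundance_profile()].
#' @param threshold minimum orientation-free CV AUROC (default 0.55).
#' @param k CV folds.
#' @param seed integer seed.
#' @return Retained feature ids, with per-feature AUROCs attached as
#'   attribute `"auroc"`.
#' @export
effective_feature_selection <- function(features, profile, threshold = 0.55,
                                        k = 5L, seed = 1L) {
  d <- design_xy(profile, features)
  a <- vapply(features, function(f) {
    single_feature_auroc(d$X[, f], d$y, k, child_seed(seed, f))
  }, numeric(1))
  keep <- features[a >= threshold]
  if (!length(keep)) message("effective_feature_selection: no feature reached the threshold")
  structure(keep, auroc = a)
}

#' Step 2 of marker selection: collinear-feature exclusion
#'
#' Computes pairwise Spearman correlations among the candidates and
#' greedily resolves pairs with |r| above the threshold in descending |r|
#' order, dropping the member with the lower univariate AUROC (ties drop
#' the lexicographically later id).
#'
#' @param features candidate ids (ideally with the AUROC attribute from
#'   [effective_feature_selection()]).
#' @param profile an [abundance_profile()].
#' @param r_threshold collinearity cutoff on |Spearman r| (default 0.8).
#' @param aurocs optional named per-feature AUROCs; recomputed if absent.
#' @param seed integer seed (only used if AUROCs must be recomputed).
#' @return Retained feature ids.
#' @export
collinear_exclusion <- function(features, profile, r_threshold = 0.8,
                                aurocs = NULL, seed = 1L) {
  feats <- as.character(features)
  if (length(feats) < 2) return(feats)
  if (is.null(aurocs)) aurocs <- attr(features, "auroc")
  if (is.null(aurocs)) {
    d <- design_xy(profile, feats)
    aurocs <- vapply(feats, function(f) {
      single_feature_auroc(d$X[, f], d$y, seed = child_seed(seed, f))
    }, numeric(1))
  }
  r <- stats::cor(t(profile$abundance[feats, , drop = FALSE]), method = "spearman")
  greedy_collinear_drop(r, aurocs[feats], r_threshold)
}

# Greedy collinearity resolution on a correlation matrix: pairs above the
# threshold are visited in descending |r|; if both endpoints are still
# retained the one with the lower AUROC is dropped (ties drop the
# lexicographically later id); pairs touching an already-dropped feature
# are skipped.
#' @keywords internal
greedy_collinear_drop <- function(r, aurocs, r_threshold = 0.8) {
  feats <- rownames(r)
  pairs <- which(upper.tri(r) & abs(r) > r_threshold, arr.ind = TRUE)
  if (!nrow(pairs)) return(feats)
  ord <- order(-abs(r[pairs]))
  dropped <- character()
  for (idx in ord) {
    i <- feats[pairs[idx, 1]]; j <- feats[pairs[idx, 2]]
    if (i %in% dropped || j %in% dropped) next
    loser <- if (aurocs[i] < aurocs[j]) i
      else if (aurocs[j] < aurocs[i]) j
      else max(i, j)                       # tie: lexicographically later id
    dropped <- c(dropped, loser)
  }
  setdiff(feats, dropped)
}

#' Step 3 of marker selection: recursive feature elimination
#'
#' Iteratively fits a random forest, records the mean stratified 5-fold CV
#' AUROC of the current panel, and removes the feature with the lowest
#' impurity importance, down to a single feature. The returned panel is
#' the size that maximized mean CV AUROC (ties favour the smaller panel);
#' importance ranks come from a final refit on the full data.
#'
#' @param features candidate ids (>= 2).
#' @param profile an [abundance_profile()].
#' @param spec a [classifier_spec()] template used for every fit.
#' @param k CV folds.
#' @param seed integer seed.
#' @return A `marker_panel`: `feature_ids` (ordered by decreasing
#'   importance), `kingdoms`, `importance_scores`, `cv_auroc`, and
#'   `selection_log` (panel size vs CV AUROC trace, dropped order).
#' @export
recursive_feature_elimination <- function(features, profile,
                                          spec = classifier_spec(n_trees = 200L),
                                          k = 5L, seed = 1L) {
  feats <- as.character(features)
  if (length(feats) < 2) mk_stop("rfe", "need at least 2 features")
  d <- design_xy(profile, feats)
  current <- feats
  trace <- list()
  dropped <- character()
  step <- 0L
  while (length(current) >= 1) {
    step <- step + 1L
    cv <- rf_cv_auroc(d$X[, current, drop = FALSE], d$y, spec, k,
                      child_seed(seed, paste0("rfe_cv", step)))
    trace[[step]] <- list(size = length(current), features = current,
                          cv_auroc = cv$mean_auroc)
    if (length(current) == 1) break
    fit <- rf_fit(d$X[, current, drop = FALSE], d$y, spec,
                  seed = child_seed(seed, paste0("rfe_fit", step)))
    imp <- fit$variable.importance
    worst <- names(imp)[order(imp, names(imp))][1]
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  sizes <- vapply(trace, `[[`, integer(1), "size")
  cvs <- vapply(trace, `[[`, numeric(1), "cv_auroc")
  best <- which(cvs == max(cvs))
  best <- best[which.min(sizes[best])]            # tie -> smallest panel
  panel_feats <- trace[[best]]$features
  final <- rf_fit(d$X[, panel_feats, drop = FALSE], d$y, spec,
                  seed = child_seed(seed, "rfe_final"))
  imp <- sort(final$variable.importance, decreasing = TRUE)
  structure(list(
    feature_ids = names(imp),
    kingdoms = if (is.null(profile$kingdoms)) NULL else unname(profile$kingdoms[names(imp)]),
    importance_scores = unname(imp),
    cv_auroc = cvs[best],
    selection_log = list(trace = data.frame(size = sizes, cv_auroc = cvs),
                         dropped_order = dropped)
  ), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d features, CV AUROC %.3f\n",
              length(x$feature_ids), x$cv_auroc))
  utils::head(data.frame(rank = seq_along(x$feature_ids),
                         feature = x$feature_ids,
                         importance = signif(x$importance_scores, 3)), 10)
}

#' Tune hyperparameters and fit the final random-forest classifier
#'
#' Random search over the classifier-spec space (tree count, depth,
#' features per split, sample fraction), each candidate scored by mean
#' stratified 5-fold CV AUROC on shared folds; the best spec is refitted
#' on all samples. The reported `CvResult` holds the winning spec's fold
#' AUROCs and a percentile bootstrap CI over the pooled out-of-fold
#' (score, label) pairs.
#'
#' @param panel a `marker_panel` (or character vector of feature ids).
#' @param profile an [abundance_profile()].
#' @param search_budget number of random configurations evaluated.
#' @param k CV folds.
#' @param n_boot bootstrap resamples for the CI (>= 1000).
#' @param seed integer seed; fixed seed + budget give an identical spec.
#' @return List with `spec` (best [classifier_spec()]), `model` (an
#'   `mk_classifier` usable with [predict_scores()]), and `cv` (class
#'   `cv_result`: `mean_auroc`, `fold_aurocs`, `ci_low`, `ci_high`).
#' @export
tune_and_fit <- function(panel, profile, search_budget = 20L, k = 5L,
                         n_boot = 1000L, seed = 1L) {
  feats <- if (inherits(panel, "marker_panel")) panel$feature_ids else as.character(panel)
  if (!length(feats)) mk_stop("tune", "empty panel")
  d <- design_xy(profile, feats)
  p <- length(feats)
  restore <- local_rng(child_seed(seed, "tune_draw"))
  grid <- data.frame(
    n_trees = sample(c(100L, 200L, 500L), search_budget, TRUE),
    max_depth = sample(c(0L, 3L, 5L, 8L), search_budget, TRUE),
    mtry = sample(unique(c(1L, max(1L, floor(sqrt(p))), max(1L, floor(p / 3)), p)),
                  search_budget, TRUE),
    max_samples = sample(c(0.632, 0.8, 1.0), search_budget, TRUE)
  )
  restore()
  grid <- unique(grid)
  best <- NULL; best_cv <- NULL
  for (i in seq_len(nrow(grid))) {
    sp <- classifier_spec(grid$n_trees[i], grid$max_depth[i], grid$mtry[i],
                          grid$max_samples[i], seed = child_seed(seed, "fit"))
    cv <- rf_cv_auroc(d$X, d$y, sp, k, seed = child_seed(seed, "tune_folds"))
    if (is.null(best) || cv$mean_auroc > best_cv$mean_auroc) {
      best <- sp; best_cv <- cv
    }
  }
  ci <- auroc_bootstrap_ci(best_cv$oof_scores, best_cv$labels, n_boot,
                           seed = child_seed(seed, "ci"))
  fit <- rf_fit(d$X, d$y, best, seed = child_seed(seed, "final_fit"))
  model <- structure(list(fit = fit, features = feats, spec = best),
                     class = "mk_classifier")
  cvres <- structure(list(mean_auroc = best_cv$mean_auroc,
                          fold_aurocs = best_cv$fold_aurocs,
                          ci_low = ci[1], ci_high = ci[2]),
                     class = "cv_result")
  list(spec = best, model = model, cv = cvres)
}

#' Score samples with a fitted classifier
#'
#' @param model an `mk_classifier` from [tune_and_fit()] (or the internal
#'   fitting helpers).
#' @param profile an [abundance_profile()]; panel features missing from it
#'   are zero-filled with a warning.
#' @return Numeric vector of CRC probabilities named by sample id.
#' @export
predict_scores <- function(model, profile) {
  d <- design_xy(profile, model$features)
  stats::setNames(rf_score(model$fit, d$X), rownames(d$X))
}

#' Run the full three-step marker selection
#'
#' Convenience wrapper: effective-feature screening, collinear exclusion,
#' recursive feature elimination, in that order.
#'
#' @param differential data.frame from [differential_features()] (its
#'   significant features seed the selection) or a character vector.
#' @param profile an [abundance_profile()].
#' @param effective_threshold screening AUROC threshold.
#' @param r_threshold collinearity cutoff.
#' @param spec [classifier_spec()] template for the RFE fits.
#' @param seed integer seed.
#' @return A `marker_panel` (see [recursive_feature_elimination()]).
#' @export
select_markers <- function(differential, profile, effective_threshold = 0.55,
                           r_threshold = 0.8,
                           spec = classifier_spec(n_trees = 200L), seed = 1L) {
  feats <- if (is.data.frame(differential)) {
    differential$feature_id[differential$significant]
  } else {
    as.character(differential)
  }
  if (length(feats) < 2) mk_stop("markers", "need at least 2 differential features")
  eff <- effective_feature_selection(feats, profile, effective_threshold,
                                     seed = child_seed(seed, "effective"))
  if (length(eff) < 2) mk_stop("markers", "fewer than 2 features passed screening")
  dec <- collinear_exclusion(eff, profile, r_threshold)
  if (length(dec) < 2) dec <- eff                  # degenerate: keep screened set
  recursive_feature_elimination(dec, profile, spec,
                                seed = child_seed(seed, "rfe"))
}
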