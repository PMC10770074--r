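#' Cohort-to-cohort AUROC matrix
#'
#' For every ordered cohort pair (i, j), i != j, a classifier is trained
#' on cohort i restricted to the panel features and scored on cohort j;
#' the diagonal holds each cohort's within-cohort stratified 5-fold CV
#' AUROC. Rows are the training cohort, columns the test cohort.
#'
#' @param panel a `marker_panel` or character vector of feature ids.
#' @param profile an [abundance_profile()] with >= 2 cohorts.
#' @param spec [classifier_spec()] used for every fit.
#' @param k folds for the diagonal CV.
#' @param seed integer seed.
#' @return Square numeric matrix with an `off_diagonal_mean` attribute;
#'   cells involving a one-class cohort are `NA`.
#' @export
cohort_to_cohort <- function(panel, profile, spec = classifier_spec(n_trees = 200L),
                             k = 5L, seed = 1L) {
  feats <- if (inherits(panel, "marker_panel")) panel$feature_ids else as.character(panel)
  cohorts <- unique(profile$metadata$cohort)
  if (length(cohorts) < 2) mk_stop("validation", "need at least 2 cohorts")
  d <- design_xy(profile, feats)
  co <- profile$metadata$cohort
  m <- matrix(NA_real_, length(cohorts), length(cohorts),
              dimnames = list(train = cohorts, test = cohorts))
  usable <- vapply(cohorts, function(cc) {
    length(unique(d$y[co == cc])) == 2
  }, logical(1))
  if (!all(usable)) {
    mk_warn("validation", "cohort(s) with a single class marked missing: ",
            paste(cohorts[!usable], collapse = ", "))
  }
  for (ci in cohorts[usable]) {
    tr <- co == ci
    fit <- rf_fit(d$X[tr, , drop = FALSE], d$y[tr], spec,
                  seed = child_seed(seed, paste0("c2c_", ci)))
    for (cj in cohorts[usable]) {
      if (ci == cj) next
      te <- co == cj
      m[ci, cj] <- auroc(rf_score(fit, d$X[te, , drop = FALSE]), d$y[te])
    }
    cv <- rf_cv_auroc(d$X[tr, , drop = FALSE], d$y[tr], spec, k,
                      seed = child_seed(seed, paste0("diag_", ci)))
    m[ci, ci] <- cv$mean_auroc
  }
  off <- m[row(m) != col(m)]
  attr(m, "off_diagonal_mean") <- mean(off, na.rm = TRUE)
  m
}

#' Leave-one-cohort-out AUROC row
#'
#' For each cohort, a classifier is trained on all the other cohorts and
#' scored on the held-out cohort.
#'
#' @inheritParams cohort_to_cohort
#' @return Named numeric vector of held-out AUROCs with a `mean` attribute.
#' @export
loco <- function(panel, profile, spec = classifier_spec(n_trees = 200L), seed = 1L) {
  feats <- if (inherits(panel, "marker_panel")) panel$feature_ids else as.character(panel)
  cohorts <- unique(profile$metadata$cohort)
  if (length(cohorts) < 2) mk_stop("validation", "need at least 2 cohorts")
  d <- design_xy(profile, feats)
  co <- profile$metadata$cohort
  out <- stats::setNames(rep(NA_real_, length(cohorts)), cohorts)
  for (cc in cohorts) {
    te <- co == cc
    if (length(unique(d$y[te])) < 2 || length(unique(d$y[!te])) < 2) {
      mk_warn("validation", "cohort ", cc, " unusable for LOCO; marked missing")
      next
    }
    fit <- rf_fit(d$X[!te, , drop = FALSE], d$y[!te], spec,
                  seed = child_seed(seed, paste0("loco_", cc)))
    out[cc] <- auroc(rf_score(fit, d$X[te, , drop = FALSE]), d$y[te])
  }
  attr(out, "mean") <- mean(out, na.rm = TRUE)
  out
}

#' External-cohort validation
#'
#' Default mode `"refit_cv"` refits a panel-restricted classifier within
#' each external cohort under stratified 5-fold CV (with bootstrap CI over
#' pooled out-of-fold pairs). Mode `"frozen"` instead scores each external
#' cohort with an already-fitted model transferred unchanged (CI by
#' bootstrapping the scored pairs). Panel features absent from an external
#' cohort are zero-filled with a warning.
#'
#' @param panel_or_model a `marker_panel`/feature vector (refit mode) or
#'   an `mk_classifier` (frozen mode).
#' @param external an [abundance_profile()] holding the external
#'   cohort(s); each must contain both classes.
#' @param mode `"refit_cv"` or `"frozen"`.
#' @param spec [classifier_spec()] for refits.
#' @param k folds; `n_boot` bootstrap resamples.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed integer seed.
#' @return data.frame: cohort, auroc, ci_low, ci_high, n.
#' @export
external_validate <- function(panel_or_model, external,
                              mode = c("refit_cv", "frozen"),
                              spec = classifier_spec(n_trees = 200L),
                              k = 5L, n_boot = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  cohorts <- unique(external$metadata$cohort)
  rows <- lapply(cohorts, function(cc) {
    sub <- subset_profile(external, samples = external$metadata$sample_id[
      external$metadata$cohort == cc])
    if (length(unique(sub$metadata$group)) < 2) {
      mk_stop("validation", "external cohort ", cc, " lacks a class")
    }
    if (mode == "refit_cv") {
      feats <- if (inherits(panel_or_model, "marker_panel")) {
        panel_or_model$feature_ids
      } else if (inherits(panel_or_model, "mk_classifier")) {
        panel_or_model$features
      } else {
        as.character(panel_or_model)
      }
      d <- design_xy(sub, feats)
      cv <- rf_cv_auroc(d$X, d$y, spec, k, seed = child_seed(seed, paste0("ext_", cc)))
      ci <- auroc_bootstrap_ci(cv$oof_scores, cv$labels, n_boot,
                               seed = child_seed(seed, paste0("extci_", cc)))
      data.frame(cohort = cc, auroc = cv$mean_auroc, ci_low = ci[1],
                 ci_high = ci[2], n = ncol(sub$abundance))
    } else {
      if (!inherits(panel_or_model, "mk_classifier")) {
        mk_stop("validation", "frozen mode needs a fitted mk_classifier")
      }
      sc <- predict_scores(panel_or_model, sub)
      y <- sub$metadata$group == "CRC"
      ci <- auroc_bootstrap_ci(sc, y, n_boot, seed = child_seed(seed, paste0("extci_", cc)))
      data.frame(cohort = cc, auroc = auroc(sc, y), ci_low = ci[1],
                 ci_high = ci[2], n = ncol(sub$abundance))
    }
  })
  do.call(rbind, rows)
}

#' Spike-in disease-specificity assessment
#'
#' Evaluates whether a fitted classifier responds specifically to the
#' target disease: subjects from another dataset are repeatedly added to
#' the control arm of an external validation cohort (labelled CTR) and
#' the AUROC of the unchanged model is recomputed. Disease-specific
#' signatures should barely move when non-target subjects are spiked in,
#' while the baseline arm — spiking in the model's own target cases —
#' should depress the AUROC materially. When the requested class has fewer
#' than `n_spike` subjects, a 5-case + 5-control fallback draw is used
#' (logged), mirroring small donor cohorts.
#'
#' @param model an `mk_classifier` (the "original model", never refitted).
#' @param external an [abundance_profile()] of one external CRC cohort.
#' @param spike_source an [abundance_profile()] supplying spike-in
#'   subjects.
#' @param spike_class which source subjects to add: `"CRC"` or `"CTR"`.
#' @param n_spike subjects added per repeat (default 15).
#' @param n_repeats number of repeats (default 10).
#' @param allow_fallback use the 5+5 fallback when the class is too small.
#' @param seed integer seed.
#' @return A `specificity_result`: `auroc_plain`, `per_repeat_auroc`,
#'   `per_repeat_delta_pct`, `mean_delta_pct`
#'   (100 * (spiked - plain) / plain), `n_spiked`, `fallback`.
#' @export
disease_specificity <- function(model, external, spike_source,
                                spike_class = c("CRC", "CTR"),
                                n_spike = 15L, n_repeats = 10L,
                                allow_fallback = TRUE, seed = 1L) {
  spike_class <- match.arg(spike_class)
  sc_ext <- predict_scores(model, external)
  y_ext <- external$metadata$group == "CRC"
  plain <- auroc(sc_ext, y_ext)

  src_md <- spike_source$metadata
  pool <- src_md$sample_id[src_md$group == spike_class]
  if (!length(pool)) mk_stop("specificity", "spike-in source has no ", spike_class, " subjects")
  fallback <- FALSE
  if (length(pool) < n_spike) {
    if (!allow_fallback) {
      mk_stop("specificity", "only ", length(pool), " ", spike_class,
              " subjects available (need ", n_spike, ") and fallback disabled")
    }
    fallback <- TRUE
    message("disease_specificity: falling back to 5 cases + 5 controls per repeat")
  }
  sc_src <- predict_scores(model, spike_source)

  restore <- local_rng(child_seed(seed, "spike"))
  on.exit(restore())
  reps <- vapply(seq_len(n_repeats), function(i) {
    picked <- if (!fallback) {
      sample(pool, n_spike)
    } else {
      c(sample(src_md$sample_id[src_md$group == "CRC"],
               min(5L, sum(src_md$group == "CRC"))),
        sample(src_md$sample_id[src_md$group == "CTR"],
               min(5L, sum(src_md$group == "CTR"))))
    }
    # spiked subjects join the control arm regardless of their true label
    auroc(c(sc_ext, sc_src[picked]), c(y_ext, rep(FALSE, length(picked))))
  }, numeric(1))
  delta <- 100 * (reps - plain) / plain
  structure(list(auroc_plain = plain, per_repeat_auroc = reps,
                 per_repeat_delta_pct = delta, mean_delta_pct = mean(delta),
                 n_spiked = if (fallback) 10L else as.integer(n_spike),
                 fallback = fallback),
            class = "specificity_result")
}
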