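# A small two-cohort profile with planted signal shared across cohorts.
two_cohort_fixture <- function(seed = 17, n_per = 20L) {
  generate_cohorts(synthetic_config(seed = seed, n_cohorts = 2L,
                                    samples_per_cohort_per_group = n_per))
}

test_that("cohort matrix and loco agree with brute-force refits on 2 cohorts", {
  gen <- two_cohort_fixture()
  prof <- filter_features(gen$profile)$profile
  feats <- gen$truth$planted_feature_ids[
    gen$truth$planted_feature_ids %in% rownames(prof$abundance)][1:8]
  spec <- classifier_spec(n_trees = 200L)
  cm <- cohort_to_cohort(feats, prof, spec, seed = 5)
  lr <- loco(feats, prof, spec, seed = 5)
  expect_equal(dim(cm), c(2L, 2L))
  expect_true(all(cm >= 0 & cm <= 1))
  # brute-force oracle: refit with the same derived seed and score by hand
  d <- mkmarker:::design_xy(prof, feats)
  co <- prof$metadata$cohort
  fit <- mkmarker:::rf_fit(d$X[co == "cohort01", ], d$y[co == "cohort01"], spec,
                           seed = mkmarker:::child_seed(5, "c2c_cohort01"))
  manual <- auroc(mkmarker:::rf_score(fit, d$X[co == "cohort02", ]),
                  d$y[co == "cohort02"])
  expect_equal(cm["cohort01", "cohort02"], manual)
  # with 2 cohorts LOCO tests the same train/test splits as the off-diagonal
  expect_equal(unname(lr["cohort02"]), unname(cm["cohort01", "cohort02"]),
               tolerance = 0.1)
  expect_equal(unname(lr["cohort01"]), unname(cm["cohort02", "cohort01"]),
               tolerance = 0.1)
  one <- subset_profile(prof, samples = prof$metadata$sample_id[co == "cohort01"])
  expect_error(cohort_to_cohort(feats, one, spec), "at least 2")
})

test_that("external validation transfers signal and zero-fills missing features", {
  gen <- generate_cohorts(synthetic_config(seed = 71, n_cohorts = 4L,
                                           samples_per_cohort_per_group = 20L))
  prof <- filter_features(gen$profile)$profile
  md <- prof$metadata
  disc <- subset_profile(prof, samples = md$sample_id[md$cohort != "cohort04"])
  ext <- subset_profile(prof, samples = md$sample_id[md$cohort == "cohort04"])
  feats <- intersect(gen$truth$planted_feature_ids, rownames(prof$abundance))[1:6]
  spec <- classifier_spec(n_trees = 200L)
  ev <- external_validate(feats, ext, spec = spec, n_boot = 200, seed = 4)
  expect_equal(nrow(ev), 1L)
  expect_gt(ev$auroc, 0.8)
  expect_true(ev$ci_low <= ev$auroc & ev$auroc <= ev$ci_high)

  # permuted labels: no transferable signal
  extp <- ext
  set.seed(6)
  extp$metadata$group <- sample(extp$metadata$group)
  evp <- external_validate(feats, extp, spec = spec, n_boot = 200, seed = 4)
  # a 40-sample cohort gives a noisy null AUROC; permutation must still
  # destroy most of the transferable signal
  expect_lt(evp$auroc, ev$auroc - 0.1)

  # frozen-model mode with a missing panel feature
  dd <- mkmarker:::design_xy(disc, feats)
  fit <- mkmarker:::rf_fit(dd$X, dd$y, spec, seed = 1)
  model <- structure(list(fit = fit, features = feats, spec = spec),
                     class = "mk_classifier")
  ext_missing <- subset_profile(ext, features = setdiff(rownames(ext$abundance),
                                                        feats[1]))
  expect_warning(evf <- external_validate(model, ext_missing, mode = "frozen",
                                          n_boot = 200, seed = 4),
                 "zero-filled")
  expect_gt(evf$auroc, 0.6)
})

test_that("spike-in specificity is null for exchangeable donors and drops for cases", {
  gen <- generate_cohorts(synthetic_config(seed = 81, n_cohorts = 4L,
                                           samples_per_cohort_per_group = 25L))
  prof <- filter_features(gen$profile)$profile
  md <- prof$metadata
  disc <- subset_profile(prof, samples = md$sample_id[
    md$cohort %in% c("cohort01", "cohort02")])
  ext <- subset_profile(prof, samples = md$sample_id[md$cohort == "cohort03"])
  src <- subset_profile(prof, samples = md$sample_id[md$cohort == "cohort04"])
  feats <- intersect(gen$truth$planted_feature_ids, rownames(prof$abundance))
  dd <- mkmarker:::design_xy(disc, feats)
  model <- structure(list(fit = mkmarker:::rf_fit(dd$X, dd$y,
                                                  classifier_spec(200L), seed = 2),
                          features = feats),
                     class = "mk_classifier")
  before <- ext$abundance
  ctrl <- disease_specificity(model, ext, src, spike_class = "CTR", seed = 5)
  case <- disease_specificity(model, ext, src, spike_class = "CRC", seed = 5)
  expect_identical(ext$abundance, before)           # pure function contract
  expect_length(ctrl$per_repeat_auroc, 10L)
  expect_lt(abs(ctrl$mean_delta_pct), 3)
  expect_gt(abs(case$mean_delta_pct), abs(ctrl$mean_delta_pct))
  expect_lt(case$mean_delta_pct, 0)

  ctrl2 <- disease_specificity(model, ext, src, spike_class = "CTR", seed = 5)
  expect_identical(ctrl$per_repeat_auroc, ctrl2$per_repeat_auroc)

  few <- subset_profile(src, samples = src$metadata$sample_id[18:30])
  expect_error(disease_specificity(model, ext, few, spike_class = "CTR",
                                   allow_fallback = FALSE), "fallback disabled")
  expect_message(fb <- disease_specificity(model, ext, few, spike_class = "CTR",
                                           seed = 2), "5 cases")
  expect_true(fb$fallback)
})
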