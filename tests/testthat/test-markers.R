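test_that("auroc matches pair counting and is invariant to monotone transforms", {
  expect_equal(auroc(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  expect_error(auroc(1:3, rep(TRUE, 3)), "both classes")
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    sc <- sample(seq_len(10), n, replace = TRUE) / 10   # with ties
    lab <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    a <- auroc(sc, lab)
    expect_equal(a, auroc_paircount(sc, lab))
    expect_equal(auroc(exp(3 * sc), lab), a)
  }
})

test_that("effective screening keeps separating features and drops flat ones", {
  set.seed(5)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  sep <- ifelse(y, 0.02, 0.001) * runif(n, 0.9, 1.1)
  flat <- rep(0.01, n)                  # identical across classes
  # no closure here: renormalizing would couple flat to sep
  ab <- rbind(sep = sep, flat = flat, rest = 0.5)
  prof <- make_profile(ab, groups = ifelse(y, "CRC", "CTR"))
  kept <- effective_feature_selection(c("sep", "flat"), prof, seed = 2)
  expect_true("sep" %in% kept)
  expect_false("flat" %in% kept)
  a <- attr(kept, "auroc")
  expect_gt(a["sep"], 0.9)
  expect_lt(a["flat"], 0.65)
})

test_that("collinear exclusion follows the greedy lower-AUROC rule", {
  r <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.9,
                0.1, 0.9, 1), 3, dimnames = list(c("f1", "f2", "f3"),
                                                 c("f1", "f2", "f3")))
  kept <- mkmarker:::greedy_collinear_drop(
    r, c(f1 = 0.9, f2 = 0.7, f3 = 0.6), 0.8)
  expect_setequal(kept, c("f1", "f3"))
  # tie in AUROC: lexicographically later id is dropped
  kept2 <- mkmarker:::greedy_collinear_drop(
    r[1:2, 1:2], c(f1 = 0.8, f2 = 0.8), 0.8)
  expect_equal(kept2, "f1")

  # duplicated feature column: exactly one of the pair survives
  set.seed(9)
  base <- runif(40, 0, 0.01)
  ab <- rbind(a = base, b = base, c = runif(40, 0, 0.01))
  prof <- make_profile(ab, groups = rep(c("CRC", "CTR"), 20))
  kept3 <- collinear_exclusion(c("a", "b", "c"), prof,
                               aurocs = c(a = 0.7, b = 0.6, c = 0.55))
  expect_setequal(kept3, c("a", "c"))
  # independent features all retained
  ab2 <- matrix(runif(120, 0, 0.01), 3,
                dimnames = list(c("x", "y", "z"), NULL))
  prof2 <- make_profile(ab2, groups = rep(c("CRC", "CTR"), 20))
  expect_setequal(collinear_exclusion(c("x", "y", "z"), prof2,
                                      aurocs = c(x = .6, y = .6, z = .6)),
                  c("x", "y", "z"))
})

test_that("rfe keeps an informative feature among noise and handles minimal panels", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(s)
    n <- 80
    y <- rep(c(TRUE, FALSE), each = n / 2)
    ab <- matrix(runif(10 * n, 0, 0.01), 10,
                 dimnames = list(sprintf("f%02d", 1:10), NULL))
    ab["f01", ] <- ifelse(y, 0.03, 0.005) * runif(n, 0.8, 1.2)
    prof <- make_profile(ab, groups = ifelse(y, "CRC", "CTR"))
    panel <- recursive_feature_elimination(sprintf("f%02d", 1:10), prof,
                                           seed = s)
    hits <- hits + ("f01" %in% panel$feature_ids)
    expect_equal(panel$importance_scores, sort(panel$importance_scores,
                                               decreasing = TRUE))
  }
  expect_gte(hits, 4L)

  set.seed(1)
  ab <- matrix(runif(2 * 40, 0, 0.01), 2, dimnames = list(c("a", "b"), NULL))
  prof <- make_profile(ab, groups = rep(c("CRC", "CTR"), 20))
  small <- recursive_feature_elimination(c("a", "b"), prof, seed = 3)
  expect_true(length(small$feature_ids) %in% 1:2)
  expect_equal(nrow(small$selection_log$trace), 2L)
  expect_error(recursive_feature_elimination("a", prof), "at least 2")
})

test_that("marker discovery is deterministic under a fixed seed", {
  gen <- generate_cohorts(synthetic_config(seed = 55, n_cohorts = 2L,
                                           samples_per_cohort_per_group = 20L))
  prof <- filter_features(gen$profile)$profile
  d <- differential_features(prof)
  p1 <- select_markers(d, prof, seed = 7)
  p2 <- select_markers(d, prof, seed = 7)
  expect_identical(p1$feature_ids, p2$feature_ids)
  expect_identical(p1$importance_scores, p2$importance_scores)
  f1 <- tune_and_fit(p1, prof, search_budget = 5, n_boot = 200, seed = 7)
  f2 <- tune_and_fit(p1, prof, search_budget = 5, n_boot = 200, seed = 7)
  expect_identical(unclass(f1$spec), unclass(f2$spec))
  expect_identical(f1$cv$fold_aurocs, f2$cv$fold_aurocs)
  expect_identical(f1$cv$ci_low, f2$cv$ci_low)
})

test_that("tuned classifiers separate planted signal and stay null on permuted labels", {
  gen <- generate_cohorts(synthetic_config(seed = 61))
  prof <- filter_features(gen$profile)$profile
  d <- differential_features(prof)
  panel <- select_markers(d, prof, seed = 13)
  expect_true(all(panel$feature_ids %in% d$feature_id[d$significant]))
  fit <- tune_and_fit(panel, prof, search_budget = 8, seed = 13)
  expect_gte(fit$cv$mean_auroc, 0.85)
  expect_lte(fit$cv$ci_low, fit$cv$mean_auroc)
  expect_length(fit$cv$fold_aurocs, 5L)

  set.seed(99)
  perm <- prof
  perm$metadata$group <- sample(perm$metadata$group)
  dperm <- mkmarker:::design_xy(perm, panel$feature_ids)
  cv0 <- mkmarker:::rf_cv_auroc(dperm$X, dperm$y, fit$spec, seed = 3)
  expect_gte(cv0$mean_auroc, 0.35)
  expect_lte(cv0$mean_auroc, 0.65)
})
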