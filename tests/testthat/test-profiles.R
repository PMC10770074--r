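test_that("profile construction validates ids, sums and strata", {
  ab <- matrix(c(0.6, 0.4, 0.3, 0.7), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  md <- data.frame(sample_id = c("s1", "s2"), cohort = "c1",
                   group = c("CRC", "CTR"), bmi = c(28, 22))
  p <- abundance_profile(ab, md)
  expect_s3_class(p, "abundance_profile")
  expect_equal(p$metadata$stratum, c("EBW", "lean"))
  expect_error(abundance_profile(ab * 2, md), "sum")
  expect_error(abundance_profile(-ab, md), "egative")
  md2 <- md; md2$stratum <- c("lean", "lean")
  expect_error(abundance_profile(ab, md2), "inconsistent")
  md3 <- md; md3$group <- c("case", "CTR")
  expect_error(abundance_profile(ab, md3), "group")
})

test_that("profiles written by the generator round-trip bit-identically", {
  gen <- generate_cohorts(synthetic_config(n_cohorts = 2L,
                                           samples_per_cohort_per_group = 5L,
                                           seed = 3))
  ft <- tempfile(fileext = ".tsv"); mdp <- tempfile(fileext = ".tsv")
  write_profile(gen$profile, ft, mdp)
  back <- read_profile(ft, mdp)
  expect_identical(back$abundance, gen$profile$abundance)
  expect_identical(back$kingdoms, gen$profile$kingdoms)
  expect_equal(back$metadata$stratum, gen$profile$metadata$stratum)
})

test_that("reading drops orphan samples with a warning and rescales percentages", {
  ab <- matrix(c(60, 40, 30, 70), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  ft <- tempfile(fileext = ".tsv"); mdp <- tempfile(fileext = ".tsv")
  utils::write.table(cbind(feature_id = rownames(ab), as.data.frame(ab)), ft,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = c("s1", "s2", "s3"), cohort = "c1",
                   group = c("CRC", "CTR", "CTR"))
  utils::write.table(md, mdp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(expect_warning(p <- read_profile(ft, mdp), "percentages"),
                 "only in metadata")
  expect_equal(ncol(p$abundance), 2L)
  expect_equal(unname(colSums(p$abundance)), c(1, 1))
})

test_that("stratify partitions samples and errors on empty strata", {
  gen <- generate_cohorts(synthetic_config(n_cohorts = 2L,
                                           samples_per_cohort_per_group = 10L,
                                           seed = 6))
  e <- stratify(gen$profile, "EBW")
  l <- stratify(gen$profile, "lean")
  expect_equal(ncol(e$abundance) + ncol(l$abundance), ncol(gen$profile$abundance))
  expect_identical(rownames(e$abundance), rownames(gen$profile$abundance))
  expect_error(stratify(l, "EBW"), "EBW")
})

test_that("stratified discovery group sizes match the transcribed cohort table", {
  md <- counts_fixture_metadata("discovery")
  ab <- matrix(1 / 2, 2, nrow(md),
               dimnames = list(c("a", "b"), md$sample_id))
  prof <- abundance_profile(ab, md)
  e <- stratify(prof, "EBW"); l <- stratify(prof, "lean")
  expect_equal(sum(e$metadata$group == "CRC"), 135L)
  expect_equal(sum(e$metadata$group == "CTR"), 123L)
  expect_equal(sum(l$metadata$group == "CRC"), 123L)
  expect_equal(sum(l$metadata$group == "CTR"), 140L)
})

test_that("the three filtering rules match a hand-applied oracle on a toy table", {
  # 10 features x 12 samples in 3 cohorts of 4; hand-applied rules:
  # f01 zero everywhere                  -> rule 1
  # f02 present in 1 cohort only         -> rule 1 (passes in 1 < 2 cohorts)
  # f03 overall mean 3e-5 < 1e-4         -> rule 2 (cohort means pass rule 1)
  # f04 abundant in 2 samples of 2 cohorts: prevalence 2/12 < 0.2 -> rule 3
  # f05..f10 abundant, prevalent         -> retained
  ab <- matrix(0, 10, 12, dimnames = list(sprintf("f%02d", 1:10),
                                          sprintf("s%02d", 1:12)))
  ab["f02", 1:4] <- 1e-3
  ab["f03", ] <- 3e-5
  ab["f04", c(1, 5)] <- 0.05
  for (f in sprintf("f%02d", 5:10)) ab[f, ] <- 0.02
  prof <- make_profile(ab, groups = rep(c("CRC", "CTR"), 6),
                       cohorts = rep(c("c1", "c2", "c3"), each = 4))
  res <- filter_features(prof)
  expect_setequal(rownames(res$profile$abundance), sprintf("f%02d", 5:10))
  expect_setequal(res$report$removed_rule1_cohort_mean, c("f01", "f02"))
  expect_equal(res$report$removed_rule2_overall_mean, "f03")
  expect_equal(res$report$removed_rule3_prevalence, "f04")
})

test_that("filtering is idempotent and never rescales retained values", {
  gen <- generate_cohorts(synthetic_config(seed = 14))
  once <- filter_features(gen$profile)
  twice <- filter_features(once$profile)
  expect_identical(twice$profile$abundance, once$profile$abundance)
  expect_equal(sum(twice$report$n_removed), 0L)
  kept <- rownames(once$profile$abundance)
  expect_identical(once$profile$abundance, gen$profile$abundance[kept, ])
})
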