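#' Configuration for the synthetic multi-cohort generator
#'
#' Describes a multi-cohort, multi-kingdom case/control study: several
#' cohorts with balanced CRC/CTR groups, sparse compositional abundances
#' over four kingdoms with bacteria dominating totals, per-cohort batch
#' effects, planted differential features with known direction, and
#' demographic covariates (age, BMI-derived stratum, gender).
#'
#' The defaults describe the study conditions exercised throughout the
#' test-suite: 5 cohorts of 30 CRC + 30 CTR samples, 200 features of which
#' 20 carry a log-scale group shift of 2.0, cohort batch offsets with
#' standard deviation 0.5, and 30% zeros per sample.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort_per_group samples per group (CRC and CTR) in
#'   each cohort.
#' @param n_features_per_kingdom named integer vector giving the number of
#'   features per kingdom.
#' @param n_planted_differential number of features carrying a true
#'   CRC-vs-CTR shift.
#' @param effect_size log-scale shift applied to planted features in the
#'   CRC group (before compositional closure). Must be >= 0.
#' @param batch_sd standard deviation of per-cohort per-feature offsets on
#'   the log scale.
#' @param sparsity target fraction of zero cells per sample, in `[0, 1)`.
#' @param noise_sd residual log-scale noise standard deviation.
#' @param covariate_effects optional named list (names among `age`, `bmi`,
#'   `gender`) giving the standard deviation of per-feature loadings on the
#'   standardized covariate; creates community-wide covariate structure.
#' @param age_case_shift years added to the mean age of CRC cases; combined
#'   with an `age` covariate effect this creates an age confounder.
#' @param prop_ebw probability a sample belongs to the excess-body-weight
#'   stratum (BMI >= 25).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cohorts = 5L,
                             samples_per_cohort_per_group = 30L,
                             n_features_per_kingdom = c(bacteria = 140L, fungi = 30L,
                                                        archaea = 15L, viruses = 15L),
                             n_planted_differential = 20L,
                             effect_size = 2.0,
                             batch_sd = 0.5,
                             sparsity = 0.30,
                             noise_sd = 1.0,
                             covariate_effects = NULL,
                             age_case_shift = 0,
                             prop_ebw = 0.5,
                             seed = 1L) {
  if (effect_size < 0) mk_stop("synthetic", "effect_size must be >= 0")
  if (sparsity < 0 || sparsity >= 1) mk_stop("synthetic", "sparsity must be in [0, 1)")
  if (n_cohorts < 1 || samples_per_cohort_per_group < 1) {
    mk_stop("synthetic", "all counts must be positive")
  }
  if (any(n_features_per_kingdom < 1) || is.null(names(n_features_per_kingdom))) {
    mk_stop("synthetic", "n_features_per_kingdom must be a named vector of positive counts")
  }
  if (n_planted_differential > sum(n_features_per_kingdom)) {
    mk_stop("synthetic", "more planted features than total features")
  }
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), c("age", "bmi", "gender"))
    if (length(bad)) mk_stop("synthetic", "unknown covariate(s): ", paste(bad, collapse = ", "))
  }
  structure(list(
    n_cohorts = as.integer(n_cohorts),
    samples_per_cohort_per_group = as.integer(samples_per_cohort_per_group),
    n_features_per_kingdom = n_features_per_kingdom,
    n_planted_differential = as.integer(n_planted_differential),
    effect_size = effect_size, batch_sd = batch_sd, sparsity = sparsity,
    noise_sd = noise_sd, covariate_effects = covariate_effects,
    age_case_shift = age_case_shift, prop_ebw = prop_ebw,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Kingdom-specific log-abundance intercepts: bacteria dominate totals, the
# other kingdoms sit 2.5-3.5 nats lower, echoing shotgun profiles.
.kingdom_intercepts <- c(bacteria = 0, fungi = -2.5, archaea = -3.5, viruses = -3.5)

#' Generate a synthetic multi-cohort case/control profile with ground truth
#'
#' Latent log-abundances are per-feature baselines (normal with sd 2 around
#' a kingdom intercept, so abundances are log-normal and heavy-tailed with
#' bacteria dominating), plus a per-cohort batch offset, plus the planted
#' CRC shift for differential features, plus optional covariate loadings,
#' plus residual noise. Zeros are imposed by removing the smallest latent
#' values in each sample until the sparsity target is met (a detection
#' limit), and the sample is then closed to proportions.
#'
#' @param config a [synthetic_config()].
#' @return A list with `profile` (an [abundance_profile()]) and `truth`, a
#'   `ground_truth` list carrying `planted_feature_ids`,
#'   `planted_directions` (named `up`/`down`, `up` = enriched in CRC), and
#'   the `batch_offsets` matrix (cohort x feature).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  kingdoms <- rep(names(config$n_features_per_kingdom), config$n_features_per_kingdom)
  n_feat <- length(kingdoms)
  feature_ids <- sprintf("%s_%03d", substr(kingdoms, 1, 3), stats::ave(
    seq_len(n_feat), kingdoms, FUN = seq_along))

  set.seed(child_seed(config$seed, "baselines"))
  mu <- .kingdom_intercepts[kingdoms] + stats::rnorm(n_feat, sd = 2)

  # Plant effects on detectable, non-dominant features (30th-75th baseline
  # percentile): real differential species must clear the detection-limit
  # filters, and a planted shift on a dominant species would distort every
  # other feature through compositional closure.
  set.seed(child_seed(config$seed, "planted"))
  eligible <- which(mu >= stats::quantile(mu, 0.30) & mu <= stats::quantile(mu, 0.75))
  if (length(eligible) < config$n_planted_differential) eligible <- seq_len(n_feat)
  planted_idx <- sort(sample(eligible, config$n_planted_differential))
  dirs <- rep(c("up", "down"), length.out = length(planted_idx))
  dirs <- dirs[sample.int(length(dirs))]

  set.seed(child_seed(config$seed, "batch"))
  cohort_ids <- sprintf("cohort%02d", seq_len(config$n_cohorts))
  batch <- matrix(stats::rnorm(config$n_cohorts * n_feat, sd = config$batch_sd),
                  nrow = config$n_cohorts,
                  dimnames = list(cohort_ids, feature_ids))

  n_per <- config$samples_per_cohort_per_group
  n_samp <- config$n_cohorts * 2L * n_per
  metadata <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n_samp)),
    cohort = rep(cohort_ids, each = 2L * n_per),
    group = rep(rep(c("CRC", "CTR"), each = n_per), times = config$n_cohorts),
    stringsAsFactors = FALSE
  )

  set.seed(child_seed(config$seed, "covariates"))
  is_ebw <- stats::runif(n_samp) < config$prop_ebw
  metadata$stratum <- ifelse(is_ebw, "EBW", "lean")
  metadata$bmi <- ifelse(is_ebw,
                         25 + abs(stats::rnorm(n_samp, 3, 2)),
                         25 - abs(stats::rnorm(n_samp, 2.5, 1.3)) - 0.1)
  metadata$bmi <- round(pmax(metadata$bmi, 15), 1)
  metadata$age <- round(stats::rnorm(n_samp, 63, 10) +
                          ifelse(metadata$group == "CRC", config$age_case_shift, 0), 1)
  metadata$gender <- ifelse(stats::runif(n_samp) < 0.5, "female", "male")

  set.seed(child_seed(config$seed, "abundance"))
  latent <- matrix(mu, nrow = n_feat, ncol = n_samp) +
    t(batch[metadata$cohort, , drop = FALSE]) +
    matrix(stats::rnorm(n_feat * n_samp, sd = config$noise_sd), nrow = n_feat)
  shift <- ifelse(dirs == "up", config$effect_size, -config$effect_size)
  crc <- metadata$group == "CRC"
  latent[planted_idx, crc] <- latent[planted_idx, crc] + shift

  if (!is.null(config$covariate_effects)) {
    set.seed(child_seed(config$seed, "covariate_loadings"))
    for (cv in names(config$covariate_effects)) {
      x <- switch(cv,
                  age = metadata$age,
                  bmi = metadata$bmi,
                  gender = as.numeric(metadata$gender == "male"))
      x <- as.numeric(scale(x))
      load <- stats::rnorm(n_feat, sd = config$covariate_effects[[cv]])
      latent <- latent + outer(load, x)
    }
  }

  ab <- exp(latent)
  n_zero <- floor(config$sparsity * n_feat)
  if (n_zero > 0) {
    for (j in seq_len(n_samp)) {
      ab[order(ab[, j])[seq_len(n_zero)], j] <- 0
    }
  }
  ab <- sweep(ab, 2, colSums(ab), "/")
  dimnames(ab) <- list(feature_ids, metadata$sample_id)

  truth <- structure(list(
    planted_feature_ids = feature_ids[planted_idx],
    planted_directions = stats::setNames(dirs, feature_ids[planted_idx]),
    batch_offsets = batch
  ), class = "ground_truth")

  list(profile = abundance_profile(ab, metadata, kingdoms), truth = truth)
}

#' Generate a functional (pathway) profile coupled to a species profile
#'
#' Produces a pathway-by-sample table over the same samples as `profile`.
#' Uncoupled pathways are independent log-normals; each coupled pathway is
#' a monotone power transform of its partner species' abundance times
#' log-normal noise, so with `noise_sd = 0` the coupled pair has rank
#' correlation exactly 1. The table is scaled by one global constant so
#' every sample sums to at most 1 (per-sample closure would break the
#' planted monotone couplings).
#'
#' @param profile the species [abundance_profile()] to couple against.
#' @param n_pathways number of pathway features.
#' @param coupled_pairs list of `c(feature_id, pathway_id)` pairs; pathway
#'   ids are `pwy_001`, `pwy_002`, ....
#' @param seed integer seed.
#' @param noise_sd log-scale noise on coupled pathways (0 = noiseless).
#' @return An [abundance_profile()] without kingdom labels.
#' @export
generate_pathway_profile <- function(profile, n_pathways, coupled_pairs = list(),
                                     seed = 1L, noise_sd = 0.5) {
  n_samp <- ncol(profile$abundance)
  pwy_ids <- sprintf("pwy_%03d", seq_len(n_pathways))
  for (cp in coupled_pairs) {
    if (!cp[1] %in% rownames(profile$abundance)) {
      mk_stop("pathways", "unknown feature id in coupled_pairs: ", cp[1])
    }
    if (!cp[2] %in% pwy_ids) {
      mk_stop("pathways", "unknown pathway id in coupled_pairs: ", cp[2])
    }
  }
  set.seed(child_seed(seed, "pathways"))
  base <- stats::rnorm(n_pathways, sd = 1.5)
  vals <- exp(matrix(base, n_pathways, n_samp) +
                matrix(stats::rnorm(n_pathways * n_samp), n_pathways))
  dimnames(vals) <- list(pwy_ids, colnames(profile$abundance))
  for (cp in coupled_pairs) {
    a <- profile$abundance[cp[1], ]
    noise <- if (noise_sd > 0) exp(stats::rnorm(n_samp, sd = noise_sd)) else 1
    vals[cp[2], ] <- a^0.7 * noise
  }
  vals <- vals / (max(colSums(vals)) * (1 + 1e-9))
  abundance_profile(vals, profile$metadata, kingdoms = NULL)
}
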