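#' Pipeline configuration
#'
#' Declarative description of a full stratified run: where the profiles
#' come from (TSV paths, in-memory profiles, or a [synthetic_config()]),
#' which cohorts are discovery vs validation, the stratum analyzed, and
#' every threshold the stages use.
#'
#' @param species_table,metadata,pathway_table optional TSV paths.
#' @param profile,pathways optional in-memory [abundance_profile()]s
#'   (override the paths).
#' @param synthetic optional [synthetic_config()]; when given, profiles
#'   are generated (and a ground-truth record kept).
#' @param stratum `"EBW"`, `"lean"`, or `NULL` for no stratification.
#' @param discovery_cohorts,validation_cohorts disjoint cohort id vectors;
#'   `NULL` discovery means all cohorts not listed for validation.
#' @param filter a [filter_spec()].
#' @param alpha_p,alpha_q differential dual thresholds (0.05, 0.1).
#' @param effective_threshold,r_collinear marker-selection thresholds.
#' @param strong_r,network_q co-abundance strong-edge and significance
#'   cutoffs.
#' @param assoc_q association significance cutoff.
#' @param sparcc_iterations,sparcc_permutations SparCC resampling sizes
#'   used by the orchestrated network stage.
#' @param search_budget hyperparameter search budget.
#' @param output_dir artifact directory (`NULL` = no files written).
#' @param seed global seed; stages derive child seeds from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(species_table = NULL, metadata = NULL,
                            pathway_table = NULL, profile = NULL,
                            pathways = NULL, synthetic = NULL,
                            stratum = NULL, discovery_cohorts = NULL,
                            validation_cohorts = character(),
                            filter = filter_spec(),
                            alpha_p = 0.05, alpha_q = 0.1,
                            effective_threshold = 0.55, r_collinear = 0.8,
                            strong_r = 0.3, network_q = 0.05, assoc_q = 0.05,
                            sparcc_iterations = 20L, sparcc_permutations = 199L,
                            search_budget = 10L,
                            output_dir = NULL, seed = 1L) {
  if (!is.null(discovery_cohorts) &&
      length(intersect(discovery_cohorts, validation_cohorts))) {
    mk_stop("config", "discovery and validation cohorts overlap")
  }
  stopifnot(alpha_p > 0, alpha_p < 1, alpha_q > 0, alpha_q <= 1,
            effective_threshold >= 0.5, effective_threshold < 1,
            r_collinear > 0, r_collinear <= 1, strong_r >= 0, strong_r < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @keywords internal
resolve_profiles <- function(config) {
  if (!is.null(config$synthetic)) {
    gen <- generate_cohorts(config$synthetic)
    pwy <- generate_pathway_profile(
      gen$profile, n_pathways = 50L,
      coupled_pairs = lapply(seq_len(min(10L, length(gen$truth$planted_feature_ids))),
                             function(i) c(gen$truth$planted_feature_ids[i],
                                           sprintf("pwy_%03d", i))),
      seed = child_seed(config$synthetic$seed, "pipeline_pathways"))
    return(list(profile = gen$profile, pathways = pwy, truth = gen$truth))
  }
  prof <- config$profile
  if (is.null(prof)) {
    if (is.null(config$species_table)) mk_stop("config", "no profile source given")
    prof <- read_profile(config$species_table, config$metadata)
  }
  pwy <- config$pathways
  if (is.null(pwy) && !is.null(config$pathway_table)) {
    pwy <- read_profile(config$pathway_table, config$metadata)
  }
  list(profile = prof, pathways = pwy, truth = NULL)
}

#' @keywords internal
write_artifact <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, name)
  if (is.data.frame(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(path)
}

#' Discovery stage: filtering, covariates, differential analysis, markers
#'
#' Restricts the profile to the discovery cohorts (and stratum, if any),
#' applies the three filtering rules, selects batch/covariates by marginal
#' PERMANOVA, runs the meta-analytic differential analysis, performs the
#' three-step marker selection, and tunes the final random-forest
#' classifier. All artifacts are written to `config$output_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return List: `profile` (discovery, filtered), `full_profile`,
#'   `pathways`, `truth`, `filter_report`, `covariates`, `differential`,
#'   `panel`, `fit` (spec/model/cv), `config`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  src <- resolve_profiles(config)
  prof <- src$profile
  cohorts <- unique(prof$metadata$cohort)
  disc <- config$discovery_cohorts %||% setdiff(cohorts, config$validation_cohorts)
  if (!length(disc)) mk_stop("discovery", "empty discovery cohort list")
  dprof <- subset_profile(prof, samples = prof$metadata$sample_id[
    prof$metadata$cohort %in% disc])
  if (!is.null(config$stratum)) dprof <- stratify(dprof, config$stratum)

  filt <- filter_features(dprof, config$filter)
  covs <- select_covariates(filt$profile, seed = child_seed(config$seed, "covsel"))
  diff <- differential_features(filt$profile, covariates = covs$covariates,
                                alpha_p = config$alpha_p, alpha_q = config$alpha_q)
  panel <- select_markers(diff, filt$profile,
                          effective_threshold = config$effective_threshold,
                          r_threshold = config$r_collinear,
                          seed = child_seed(config$seed, "markers"))
  fit <- tune_and_fit(panel, filt$profile, search_budget = config$search_budget,
                      seed = child_seed(config$seed, "tune"))

  dir <- config$output_dir
  write_artifact(filt$report, dir, "filter_report.json")
  write_artifact(diff, dir, "differential.tsv")
  write_artifact(data.frame(rank = seq_along(panel$feature_ids),
                            feature_id = panel$feature_ids,
                            kingdom = panel$kingdoms %||% NA,
                            importance = panel$importance_scores),
                 dir, "panel.tsv")
  write_artifact(list(spec = unclass(fit$spec), cv = unclass(fit$cv),
                      covariates = covs$covariates, seed = config$seed),
                 dir, "model_card.json")
  list(profile = filt$profile, full_profile = prof, pathways = src$pathways,
       truth = src$truth, filter_report = filt$report, covariates = covs,
       differential = diff, panel = panel, fit = fit, config = config)
}

#' Validation stage: cross-cohort, LOCO, external, disease specificity
#'
#' @param config a [pipeline_config()].
#' @param discovery the result of [run_discovery()].
#' @param spike_source optional [abundance_profile()] for the spike-in
#'   specificity assessment (plus a baseline arm drawn from its cases).
#' @return List: `cohort_matrix`, `loco_row`, `external`, `specificity`
#'   (possibly NULL).
#' @export
run_validation <- function(config, discovery, spike_source = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(discovery$panel)) mk_stop("validation", "discovery artifacts missing")
  panel <- discovery$panel
  spec <- discovery$fit$spec
  seed <- child_seed(config$seed, "validation")

  cmat <- cohort_to_cohort(panel, discovery$profile, spec, seed = seed)
  lrow <- loco(panel, discovery$profile, spec, seed = seed)

  external <- NULL
  if (length(config$validation_cohorts)) {
    full <- discovery$full_profile
    eprof <- subset_profile(full, samples = full$metadata$sample_id[
      full$metadata$cohort %in% config$validation_cohorts])
    if (!is.null(config$stratum)) eprof <- stratify(eprof, config$stratum)
    external <- external_validate(panel, eprof, mode = "refit_cv", spec = spec,
                                  seed = child_seed(seed, "external"))
  }

  specificity <- NULL
  if (!is.null(spike_source) && length(config$validation_cohorts)) {
    ext1 <- subset_profile(discovery$full_profile,
                           samples = discovery$full_profile$metadata$sample_id[
                             discovery$full_profile$metadata$cohort ==
                               config$validation_cohorts[1]])
    specificity <- list(
      spike = disease_specificity(discovery$fit$model, ext1, spike_source,
                                  spike_class = "CTR",
                                  seed = child_seed(seed, "spike")),
      baseline = disease_specificity(discovery$fit$model, ext1, spike_source,
                                     spike_class = "CRC",
                                     seed = child_seed(seed, "baseline"))
    )
  }

  dir <- config$output_dir
  write_artifact(as.data.frame(cmat), dir, "cohort_matrix.tsv")
  write_artifact(list(loco = as.list(lrow), loco_mean = attr(lrow, "mean")),
                 dir, "loco.json")
  if (!is.null(external)) write_artifact(external, dir, "external.tsv")
  if (!is.null(specificity)) {
    write_artifact(lapply(specificity, unclass), dir, "specificity.json")
  }
  list(cohort_matrix = cmat, loco_row = lrow, external = external,
       specificity = specificity)
}

#' Network and association stage
#'
#' Builds the four condition co-abundance networks (stratum x group) over
#' each stratum's differential species, their summaries and sign-proportion
#' contrasts, the overlap summary of the two strata's differential sets,
#' and species-pathway association maps per stratum. Conditions with
#' fewer than 4 differential species are skipped with a warning.
#'
#' @param config a [pipeline_config()].
#' @param profile the full (unstratified) species [abundance_profile()].
#' @param differential_by_stratum named list (`EBW`, `lean`) of
#'   [differential_features()] results.
#' @param pathways optional pathway [abundance_profile()] for the
#'   association stage.
#' @return List: `networks` (condition -> network), `summaries`,
#'   `contrasts` (CRC-vs-CTR per stratum), `overlap`, `associations`.
#' @export
run_networks_and_associations <- function(config, profile,
                                          differential_by_stratum,
                                          pathways = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- child_seed(config$seed, "networks")
  networks <- list(); summaries <- list()
  for (st in names(differential_by_stratum)) {
    dd <- differential_by_stratum[[st]]
    feats <- dd$feature_id[dd$significant]
    for (gr in c("CRC", "CTR")) {
      cond <- paste0(st, "-", gr)
      keep <- profile$metadata$stratum == st & profile$metadata$group == gr
      if (length(feats) < 4) {
        mk_warn("networks", "condition ", cond,
                " has fewer than 4 differential species; skipped")
        next
      }
      sub <- subset_profile(profile,
                            samples = profile$metadata$sample_id[keep],
                            features = feats)
      cnt <- to_counts(sub)
      r <- sparcc_correlations(cnt, n_iterations = config$sparcc_iterations,
                               seed = child_seed(seed, cond))
      pq <- sparcc_pvalues(cnt, r, n_permutations = config$sparcc_permutations,
                           seed = child_seed(seed, paste0(cond, "_p")))
      net <- build_network(r, pq$q, condition = cond, mode = "strong",
                           p = pq$p, kingdoms = profile$kingdoms,
                           q_threshold = config$network_q,
                           r_threshold = config$strong_r)
      networks[[cond]] <- net
      summaries[[cond]] <- summarize_network(net)
      if (!is.null(config$output_dir)) {
        write_network(net, file.path(config$output_dir,
                                     paste0("network_", cond, ".tsv")))
      }
    }
  }
  contrasts <- list()
  for (st in names(differential_by_stratum)) {
    a <- summaries[[paste0(st, "-CRC")]]; b <- summaries[[paste0(st, "-CTR")]]
    if (!is.null(a) && !is.null(b) && a$n_edges > 0 && b$n_edges > 0 &&
        (a$n_negative + b$n_negative) > 0 && (a$n_positive + b$n_positive) > 0) {
      contrasts[[st]] <- compare_edge_proportions(a, b)
    }
  }
  ov <- NULL
  if (length(differential_by_stratum) == 2) {
    sets <- lapply(differential_by_stratum, function(d) d$feature_id[d$significant])
    ov <- overlap_summary(sets[[1]], sets[[2]])
  }
  associations <- list()
  if (!is.null(pathways)) {
    for (st in names(differential_by_stratum)) {
      dd <- differential_by_stratum[[st]]
      feats <- dd$feature_id[dd$significant]
      if (length(feats) < 1) next
      samp <- profile$metadata$sample_id[profile$metadata$stratum == st]
      associations[[st]] <- associate(
        subset_profile(profile, features = feats), pathways,
        samples = samp, condition = st)
      write_artifact(associations[[st]], config$output_dir,
                     paste0("associations_", st, ".tsv"))
    }
  }
  if (!is.null(ov)) write_artifact(unclass(ov), config$output_dir, "overlap.json")
  write_artifact(lapply(summaries, unclass), config$output_dir,
                 "network_summaries.json")
  list(networks = networks, summaries = summaries, contrasts = contrasts,
       overlap = ov, associations = associations)
}
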