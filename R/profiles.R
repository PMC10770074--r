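#' Construct an abundance profile
#'
#' The central container of the package: a feature-by-sample matrix of
#' relative abundances (fractions) together with per-feature kingdom labels
#' and per-sample metadata. Used both for taxonomic (species) tables, where
#' each feature carries a kingdom among bacteria / fungi / archaea /
#' viruses, and for functional (KO gene or pathway) tables, where the
#' kingdom column is absent.
#'
#' @param abundance numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids. Values are
#'   fractions in `[0, 1]`; each sample sums to at most `1 + 1e-6`.
#' @param metadata data.frame with one row per sample. Required columns:
#'   `sample_id`, `cohort`, `group` (`CRC`/`CTR`). Optional: `stratum`
#'   (`EBW`/`lean`), `age`, `bmi`, `gender` (`female`/`male`). If `bmi` is
#'   present and `stratum` absent, the stratum is derived as `EBW` when
#'   BMI >= 25 kg/m^2 and `lean` otherwise.
#' @param kingdoms optional character vector parallel to the rows of
#'   `abundance`, with values in `bacteria`, `fungi`, `archaea`, `viruses`.
#'   `NULL` for functional tables.
#' @return An object of class `abundance_profile`: a list with elements
#'   `abundance`, `metadata`, `kingdoms`.
#' @export
abundance_profile <- function(abundance, metadata, kingdoms = NULL) {
  stopifnot(is.matrix(abundance), is.numeric(abundance), is.data.frame(metadata))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    mk_stop("profile", "abundance matrix needs feature row names and sample column names")
  }
  if (anyDuplicated(rownames(abundance))) mk_stop("profile", "duplicate feature ids")
  if (anyDuplicated(colnames(abundance))) mk_stop("profile", "duplicate sample ids")
  if (any(abundance < 0)) mk_stop("profile", "negative abundances")
  if (any(colSums(abundance) > 1 + 1e-6)) {
    mk_stop("profile", "a sample's abundances sum to more than 1")
  }
  need <- c("sample_id", "cohort", "group")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) mk_stop("profile", "missing metadata columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) mk_stop("profile", "duplicate sample ids in metadata")
  if (!setequal(metadata$sample_id, colnames(abundance))) {
    mk_stop("profile", "metadata sample ids do not match abundance columns")
  }
  metadata <- metadata[match(colnames(abundance), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$group %in% c("CRC", "CTR"))) {
    mk_stop("profile", "group must be CRC or CTR")
  }
  if (is.null(metadata$stratum) && !is.null(metadata$bmi)) {
    metadata$stratum <- ifelse(metadata$bmi >= 25, "EBW", "lean")
  }
  if (!is.null(metadata$stratum) && !is.null(metadata$bmi)) {
    bad <- (metadata$bmi >= 25) != (metadata$stratum == "EBW")
    bad[is.na(bad)] <- FALSE
    if (any(bad)) mk_stop("profile", "stratum inconsistent with BMI for ",
                          sum(bad), " sample(s) (EBW iff BMI >= 25)")
  }
  if (!is.null(kingdoms)) {
    if (length(kingdoms) != nrow(abundance)) {
      mk_stop("profile", "kingdoms length must equal number of features")
    }
    ok <- kingdoms %in% c("bacteria", "fungi", "archaea", "viruses")
    if (!all(ok)) mk_stop("profile", "unknown kingdom label(s): ",
                          paste(unique(kingdoms[!ok]), collapse = ", "))
    kingdoms <- stats::setNames(kingdoms, rownames(abundance))
  }
  structure(
    list(abundance = abundance, metadata = metadata, kingdoms = kingdoms),
    class = "abundance_profile"
  )
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf(
    "abundance_profile: %d features x %d samples (%d cohorts; %d CRC / %d CTR)\n",
    nrow(x$abundance), ncol(x$abundance),
    length(unique(x$metadata$cohort)),
    sum(x$metadata$group == "CRC"), sum(x$metadata$group == "CTR")
  ))
  if (!is.null(x$kingdoms)) {
    tb <- table(x$kingdoms)
    cat("kingdoms:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.abundance_profile <- function(x) dim(x$abundance)

#' Subset a profile by samples and/or features
#'
#' @param profile an [abundance_profile()].
#' @param samples sample ids (or logical/integer index over columns) to keep.
#' @param features feature ids (or index over rows) to keep.
#' @return The subset profile; abundances are never renormalized.
#' @export
subset_profile <- function(profile, samples = NULL, features = NULL) {
  ab <- profile$abundance
  md <- profile$metadata
  kg <- profile$kingdoms
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, colnames(ab))
    ab <- ab[, samples, drop = FALSE]
    md <- md[match(colnames(ab), md$sample_id), , drop = FALSE]
  }
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, rownames(ab))
    ab <- ab[features, , drop = FALSE]
    if (!is.null(kg)) kg <- kg[rownames(ab)]
  }
  structure(list(abundance = ab, metadata = md,
                 kingdoms = if (is.null(kg)) NULL else kg),
            class = "abundance_profile")
}

#' Read a profile from feature-table and metadata TSV files
#'
#' The feature table has one row per feature with columns `feature_id`,
#' optionally `kingdom`, then one column per sample. The metadata table has
#' columns `sample_id`, `cohort`, `group`, and optionally `stratum`, `age`,
#' `bmi`, `gender`. Samples present in only one of the two files are
#' dropped with a warning. Values are interpreted as fractions; if any
#' value exceeds 1.5 the whole table is assumed to be in percent and is
#' divided by 100 (with a warning).
#'
#' @param feature_table_path path to the abundance TSV.
#' @param metadata_path path to the metadata TSV.
#' @return An [abundance_profile()].
#' @export
read_profile <- function(feature_table_path, metadata_path) {
  ft <- utils::read.delim(feature_table_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  md <- utils::read.delim(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(ft)) mk_stop("read", "feature table lacks a feature_id column")
  kingdoms <- NULL
  meta_cols <- "feature_id"
  if ("kingdom" %in% names(ft)) {
    kingdoms <- ft$kingdom
    meta_cols <- c(meta_cols, "kingdom")
  }
  ab <- as.matrix(ft[, setdiff(names(ft), meta_cols), drop = FALSE])
  if (!is.numeric(ab)) mk_stop("read", "non-numeric abundance values")
  rownames(ab) <- ft$feature_id
  if (any(ab < 0)) mk_stop("read", "negative abundance values")
  if (max(ab) > 1.5) {
    mk_warn("read", "values exceed 1.5; assuming percentages, dividing by 100")
    ab <- ab / 100
  }
  shared <- intersect(colnames(ab), md$sample_id)
  if (length(shared) == 0) mk_stop("read", "no shared samples between table and metadata")
  orphan_tab <- setdiff(colnames(ab), shared)
  orphan_md <- setdiff(md$sample_id, shared)
  if (length(orphan_tab)) {
    mk_warn("read", length(orphan_tab), " sample(s) only in feature table dropped")
  }
  if (length(orphan_md)) {
    mk_warn("read", length(orphan_md), " sample(s) only in metadata dropped")
  }
  ab <- ab[, shared, drop = FALSE]
  md <- md[md$sample_id %in% shared, , drop = FALSE]
  abundance_profile(ab, md, kingdoms)
}

#' Write a profile to feature-table and metadata TSV files
#'
#' Inverse of [read_profile()]; numeric values are written with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param profile an [abundance_profile()].
#' @param feature_table_path,metadata_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_profile <- function(profile, feature_table_path, metadata_path) {
  ab <- profile$abundance
  df <- data.frame(feature_id = rownames(ab), stringsAsFactors = FALSE)
  if (!is.null(profile$kingdoms)) df$kingdom <- unname(profile$kingdoms)
  num <- as.data.frame(apply(ab, 2, function(col) sprintf("%.17g", col)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, num)
  utils::write.table(df, feature_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(profile$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(feature_table_path, metadata_path))
}

#' Restrict a profile to one body-weight stratum
#'
#' @param profile an [abundance_profile()].
#' @param stratum `"EBW"` (BMI >= 25 kg/m^2) or `"lean"` (BMI < 25).
#' @return The profile restricted to matching samples; features unchanged.
#' @export
stratify <- function(profile, stratum = c("EBW", "lean")) {
  stratum <- match.arg(stratum)
  if (is.null(profile$metadata$stratum)) {
    mk_stop("stratify", "metadata has neither stratum nor bmi")
  }
  keep <- which(profile$metadata$stratum == stratum)
  if (length(keep) == 0) mk_stop("stratify", "no samples in stratum ", stratum)
  subset_profile(profile, samples = profile$metadata$sample_id[keep])
}

#' Feature-filtering thresholds
#'
#' Defaults encode the workflow's three sequential rules: a feature must
#' (1) reach a per-cohort mean relative abundance of at least 0.001%
#' (1e-5) in at least two cohorts, (2) have an overall mean relative
#' abundance of at least 0.01% (1e-4), and (3) be present (non-zero) in at
#' least 20% of samples. Thresholds are stored as fractions, not percent.
#'
#' @param max_cohort_mean_min per-cohort mean abundance floor (fraction).
#' @param min_cohorts_passing minimum number of cohorts passing rule 1.
#' @param overall_mean_min overall mean abundance floor (fraction).
#' @param prevalence_min minimum fraction of samples with non-zero abundance.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(max_cohort_mean_min = 1e-5, min_cohorts_passing = 2L,
                        overall_mean_min = 1e-4, prevalence_min = 0.20) {
  stopifnot(
    max_cohort_mean_min >= 0, max_cohort_mean_min <= 1,
    overall_mean_min >= 0, overall_mean_min <= 1,
    prevalence_min >= 0, prevalence_min <= 1,
    min_cohorts_passing >= 1
  )
  structure(list(max_cohort_mean_min = max_cohort_mean_min,
                 min_cohorts_passing = as.integer(min_cohorts_passing),
                 overall_mean_min = overall_mean_min,
                 prevalence_min = prevalence_min),
            class = "filter_spec")
}

#' Apply the three sequential feature-filtering rules
#'
#' Rules are applied in order; each operates on the survivors of the
#' previous one. Retained abundances are never renormalized, so downstream
#' differential modelling sees the original relative abundances.
#'
#' @param profile an [abundance_profile()].
#' @param spec a [filter_spec()].
#' @return A list with `profile` (the filtered profile) and `report`
#'   (features in/out and counts removed by each rule).
#' @export
filter_features <- function(profile, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  ab <- profile$abundance
  cohorts <- profile$metadata$cohort
  if (length(unique(cohorts)) < 1) mk_stop("filter", "no cohorts present")

  # rule 1: per-cohort mean abundance >= threshold in >= k cohorts
  cohort_means <- vapply(unique(cohorts), function(co) {
    rowMeans(ab[, cohorts == co, drop = FALSE])
  }, numeric(nrow(ab)))
  n_pass <- rowSums(cohort_means >= spec$max_cohort_mean_min)
  keep1 <- n_pass >= spec$min_cohorts_passing
  removed1 <- rownames(ab)[!keep1]
  ab <- ab[keep1, , drop = FALSE]

  # rule 2: overall mean abundance
  keep2 <- rowMeans(ab) >= spec$overall_mean_min
  removed2 <- rownames(ab)[!keep2]
  ab <- ab[keep2, , drop = FALSE]

  # rule 3: prevalence (fraction of samples with non-zero abundance)
  keep3 <- rowMeans(ab > 0) >= spec$prevalence_min
  removed3 <- rownames(ab)[!keep3]
  ab <- ab[keep3, , drop = FALSE]

  out <- subset_profile(profile, features = rownames(ab))
  report <- list(
    n_input = nrow(profile$abundance),
    n_retained = nrow(ab),
    removed_rule1_cohort_mean = removed1,
    removed_rule2_overall_mean = removed2,
    removed_rule3_prevalence = removed3,
    n_removed = c(rule1 = length(removed1), rule2 = length(removed2),
                  rule3 = length(removed3)),
    spec = unclass(spec)
  )
  list(profile = out, report = report)
}
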