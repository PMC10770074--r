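#' @keywords internal
asin_sqrt <- function(p) asin(sqrt(pmin(pmax(p, 0), 1)))

# Per-cohort group effects for every feature at once. One QR factorization
# of the shared design (group indicator + covariates) serves all features;
# returns effect and SE of the CRC coefficient, NA for features with no
# within-cohort variance.
#' @keywords internal
cohort_effects_all <- function(profile, covariates = character()) {
  md <- profile$metadata
  if (length(unique(md$group)) < 2) return(NULL)
  y <- t(asin_sqrt(profile$abundance))          # samples x features
  grp <- factor(md$group, levels = c("CTR", "CRC"))
  df <- data.frame(group = grp)
  for (cv in covariates) {
    x <- md[[cv]]
    if (is.character(x)) x <- factor(x)
    if (length(unique(x)) < 2) next               # constant within cohort
    df[[cv]] <- x
  }
  X <- stats::model.matrix(~ ., data = df)
  n <- nrow(X); p <- ncol(X)
  if (n - p < 1) return(NULL)
  qrX <- qr(X)
  if (qrX$rank < p) return(NULL)
  B <- qr.coef(qrX, y)
  res <- y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qrX))
  gcol <- which(colnames(X) == "groupCRC")
  eff <- B[gcol, ]
  se <- sqrt(sigma2 * xtx_inv[gcol, gcol])
  no_var <- apply(y, 2, function(col) stats::sd(col) == 0)
  eff[no_var] <- NA_real_
  se[no_var | se < 1e-12] <- NA_real_
  cbind(effect = eff, se = se)
}

#' Per-cohort differential-abundance effect for one feature
#'
#' Fits a linear model of the arcsine-square-root-transformed relative
#' abundance on the CRC/CTR indicator plus any covariates, within a single
#' cohort, and returns the group coefficient (positive = enriched in CRC)
#' and its standard error.
#'
#' @param profile an [abundance_profile()] restricted to one cohort, with
#'   both groups present.
#' @param feature a feature id.
#' @param covariates metadata column names to adjust for.
#' @return Named numeric vector `c(effect=, se=)`; both `NA` if the
#'   feature has no variance in the cohort.
#' @export
per_cohort_effect <- function(profile, feature, covariates = character()) {
  if (length(unique(profile$metadata$cohort)) > 1) {
    mk_warn("meta_diff", "profile spans several cohorts; fitting them pooled")
  }
  if (length(unique(profile$metadata$group)) < 2) {
    mk_warn("meta_diff", "cohort lacks one of CRC/CTR; skipped")
    return(c(effect = NA_real_, se = NA_real_))
  }
  est <- cohort_effects_all(subset_profile(profile, features = feature), covariates)
  if (is.null(est)) return(c(effect = NA_real_, se = NA_real_))
  c(effect = unname(est[1, "effect"]), se = unname(est[1, "se"]))
}

#' Pool per-cohort effects into a meta-analytic estimate
#'
#' Fixed-effect inverse-variance pooling by default: weights w_i = 1/se_i^2,
#' pooled effect sum(w b)/sum(w), pooled SE (sum w)^(-1/2), two-sided
#' normal p. With `method = "random"` a DerSimonian-Laird random-effects
#' model is fitted via \pkg{metafor} and I^2 heterogeneity is reported.
#'
#' @param effects,ses per-cohort estimates and standard errors (NA pairs
#'   are dropped).
#' @param method `"fixed"` or `"random"`.
#' @return List `effect`, `se`, `p`, `n_cohorts_used` (plus `i2` for the
#'   random-effects model); all NA with `n_cohorts_used = 0` when no
#'   cohort is usable.
#' @export
pool_effects <- function(effects, ses, method = c("fixed", "random")) {
  method <- match.arg(method)
  ok <- is.finite(effects) & is.finite(ses) & ses > 0
  effects <- effects[ok]; ses <- ses[ok]
  if (!length(effects)) {
    return(list(effect = NA_real_, se = NA_real_, p = NA_real_, n_cohorts_used = 0L))
  }
  if (method == "random") {
    if (!requireNamespace("metafor", quietly = TRUE)) {
      mk_stop("meta_diff", "random-effects pooling needs the metafor package")
    }
    fit <- metafor::rma(yi = effects, sei = ses, method = "DL")
    return(list(effect = as.numeric(fit$beta), se = fit$se, p = fit$pval,
                n_cohorts_used = length(effects), i2 = fit$I2))
  }
  w <- 1 / ses^2
  beta <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  list(effect = beta, se = se, p = 2 * stats::pnorm(-abs(z)),
       n_cohorts_used = length(effects))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, mapped back to the input
#' order; NAs propagate.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  fin <- p_values[is.finite(p_values)]
  if (any(fin < 0 | fin > 1)) mk_stop("bh_fdr", "p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Multi-cohort differential-abundance analysis
#'
#' Runs the batch-aware meta-analytic workflow over every feature of a
#' (filtered) profile: per-cohort linear models on arcsine-square-root
#' abundances with covariate adjustment (the cohort is the batch and is
#' never pooled across), inverse-variance pooling, BH adjustment, and the
#' dual significance call p < `alpha_p` and FDR q < `alpha_q`.
#'
#' @param profile a filtered [abundance_profile()].
#' @param stratum optional `"EBW"`/`"lean"` restriction applied first.
#' @param covariates metadata columns to adjust for (e.g. the output of
#'   [select_covariates()]).
#' @param method pooling method, `"fixed"` (default) or `"random"`.
#' @param alpha_p,alpha_q the dual significance thresholds (defaults 0.05
#'   and 0.1).
#' @return A data.frame with one row per feature: `feature_id`, `kingdom`,
#'   `effect`, `se`, `p`, `q`, `direction` (`enriched`/`depleted` in CRC),
#'   `n_cohorts_used`, `significant`. Per-cohort estimates are attached as
#'   attribute `"per_cohort"`.
#' @export
differential_features <- function(profile, stratum = NULL,
                                  covariates = character(),
                                  method = "fixed",
                                  alpha_p = 0.05, alpha_q = 0.1) {
  if (!is.null(stratum)) profile <- stratify(profile, stratum)
  cohorts <- unique(profile$metadata$cohort)
  if (length(cohorts) < 2) {
    mk_warn("meta_diff", "fewer than 2 usable cohorts; pooled estimates are single-cohort fits")
  }
  per_cohort <- list()
  for (co in cohorts) {
    sub <- subset_profile(profile, samples = profile$metadata$sample_id[
      profile$metadata$cohort == co])
    if (length(unique(sub$metadata$group)) < 2) {
      mk_warn("meta_diff", "cohort ", co, " lacks one of CRC/CTR; skipped")
      next
    }
    est <- cohort_effects_all(sub, covariates)
    if (!is.null(est)) per_cohort[[co]] <- est
  }
  if (!length(per_cohort)) mk_stop("meta_diff", "no cohort with both groups")
  feats <- rownames(profile$abundance)
  pooled <- lapply(feats, function(f) {
    eff <- vapply(per_cohort, function(m) m[f, "effect"], numeric(1))
    ses <- vapply(per_cohort, function(m) m[f, "se"], numeric(1))
    pool_effects(eff, ses, method = method)
  })
  out <- data.frame(
    feature_id = feats,
    kingdom = if (is.null(profile$kingdoms)) NA_character_ else unname(profile$kingdoms[feats]),
    effect = vapply(pooled, `[[`, numeric(1), "effect"),
    se = vapply(pooled, `[[`, numeric(1), "se"),
    p = vapply(pooled, `[[`, numeric(1), "p"),
    n_cohorts_used = vapply(pooled, `[[`, integer(1), "n_cohorts_used"),
    stringsAsFactors = FALSE
  )
  out$q <- bh_fdr(out$p)
  out$direction <- ifelse(is.na(out$effect), NA_character_,
                          ifelse(out$effect > 0, "enriched", "depleted"))
  out$significant <- !is.na(out$p) & out$p < alpha_p & !is.na(out$q) & out$q < alpha_q
  attr(out, "per_cohort") <- per_cohort
  out
}

#' Overlap summary of two differential-feature sets
#'
#' Percentages are relative to the union, matching the Venn-style
#' reporting of shared and stratum-specific differential species.
#'
#' @param set_a,set_b character vectors of feature ids.
#' @return List with `n_a`, `n_b`, `n_shared`, `n_union`, `pct_shared`,
#'   `pct_a_specific`, `pct_b_specific` (percentages of the union, full
#'   precision; NA when both sets are empty).
#' @export
overlap_summary <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  n_shared <- length(intersect(set_a, set_b))
  n_union <- length(union(set_a, set_b))
  pct <- function(n) if (n_union == 0) NA_real_ else 100 * n / n_union
  structure(list(
    n_a = length(set_a), n_b = length(set_b),
    n_shared = n_shared, n_union = n_union,
    pct_shared = pct(n_shared),
    pct_a_specific = pct(length(setdiff(set_a, set_b))),
    pct_b_specific = pct(length(setdiff(set_b, set_a)))
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: |A|=%d |B|=%d shared=%d union=%d\n", x$n_a, x$n_b,
              x$n_shared, x$n_union))
  cat(sprintf("shared %.2f%% | A-specific %.2f%% | B-specific %.2f%%\n",
              x$pct_shared, x$pct_a_specific, x$pct_b_specific))
  invisible(x)
}
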