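#' Shannon diversity of one sample (natural log)
#'
#' @param x nonnegative abundance vector with a positive sum; renormalized
#'   internally.
#' @return H = -sum p_i ln p_i over the non-zero entries, in nats.
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) mk_stop("shannon", "negative abundances")
  s <- sum(x)
  if (s <= 0) mk_stop("shannon", "all-zero abundance vector")
  unname(vegan::diversity(x / s, index = "shannon"))
}

#' Bray-Curtis distance matrix between samples
#'
#' @param profile an [abundance_profile()] (or a feature-by-sample matrix).
#' @return A `dist` object labelled by sample id;
#'   d(u,v) = sum|u_i - v_i| / sum(u_i + v_i), in `[0, 1]`.
#' @export
bray_curtis <- function(profile) {
  ab <- if (inherits(profile, "abundance_profile")) profile$abundance else profile
  if (ncol(ab) < 2) mk_stop("braycurtis", "need at least 2 samples")
  if (any(colSums(ab) <= 0)) mk_stop("braycurtis", "zero-sum sample")
  vegan::vegdist(t(ab), method = "bray")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers -d^2/2 and eigendecomposes it. Axes are ordered by
#' eigenvalue; variance explained is computed over positive eigenvalues
#' only (negative eigenvalues, which Bray-Curtis semimetrics can produce,
#' are dropped from the denominator with a message).
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param k number of axes requested.
#' @return List with `points` (samples x axes), `eig` (all eigenvalues)
#'   and `var_explained` (fraction per returned axis).
#' @export
pcoa <- function(d, k = 2L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  stopifnot(k >= 1)
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  pos <- fit$eig[fit$eig > sqrt(.Machine$double.eps)]
  if (any(fit$eig < 0)) {
    message(sprintf("pcoa: %d negative eigenvalue(s) dropped from variance-explained denominator",
                    sum(fit$eig < 0)))
  }
  pts <- fit$points
  if (ncol(pts) < k) {
    mk_warn("pcoa", "only ", ncol(pts), " positive axes available; truncating from k=", k)
  }
  keep <- seq_len(min(k, ncol(pts)))
  list(points = pts[, keep, drop = FALSE],
       eig = fit$eig,
       var_explained = (fit$eig[keep]) / sum(pos))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the sum of
#' squared distances between and within groups (or along a numeric
#' covariate) and compares the pseudo-F statistic against label
#' permutations. The permutation p-value carries the +1 correction, so its
#' minimum is 1/(n_permutations + 1).
#'
#' @param d a `dist` or symmetric distance matrix over samples.
#' @param variable grouping factor or numeric covariate, one value per
#'   sample in the order of `d`'s labels.
#' @param n_permutations number of permutations (999 by default).
#' @param seed integer seed for the permutation stream.
#' @return A `permanova_result` list: `r2`, `p`, `f`, `n_permutations`.
#' @export
permanova <- function(d, variable, n_permutations = 999L, seed = 1L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (length(variable) != attr(d, "Size")) {
    mk_stop("permanova", "variable length does not match distance matrix")
  }
  if (length(unique(variable)) < 2) mk_stop("permanova", "constant variable")
  df <- data.frame(v = variable)
  restore <- local_rng(child_seed(seed, "permanova"))
  on.exit(restore())
  fit <- vegan::adonis2(d ~ v, data = df, permutations = n_permutations)
  structure(list(r2 = fit$R2[1], p = fit$`Pr(>F)`[1], f = fit$F[1],
                 n_permutations = as.integer(n_permutations)),
            class = "permanova_result")
}

#' Select the batch variable and adjustment covariates by marginal PERMANOVA
#'
#' Runs a one-variable-at-a-time PERMANOVA of each candidate demographic
#' variable on the profile's Bray-Curtis distances. The cohort is always
#' designated as the batch (it is the dominant source of heterogeneity in
#' multi-study profiles); every other candidate with permutation p < 0.05
#' is returned as a model covariate.
#'
#' @param profile an [abundance_profile()].
#' @param candidates metadata columns to screen (default gender, age, BMI).
#' @param n_permutations permutations per test.
#' @param alpha inclusion threshold on the permutation p-value.
#' @param seed integer seed.
#' @return List with `batch` (`"cohort"`, or `NA` for single-cohort input),
#'   `covariates` (selected names) and `table` (per-variable R2 and p).
#' @export
select_covariates <- function(profile, candidates = c("gender", "age", "bmi"),
                              n_permutations = 999L, alpha = 0.05, seed = 1L) {
  md <- profile$metadata
  candidates <- intersect(candidates, names(md))
  d <- bray_curtis(profile)
  rows <- lapply(candidates, function(v) {
    x <- md[[v]]
    if (length(unique(x)) < 2) {
      return(data.frame(variable = v, r2 = NA_real_, p = NA_real_))
    }
    res <- permanova(d, x, n_permutations = n_permutations,
                     seed = child_seed(seed, v))
    data.frame(variable = v, r2 = res$r2, p = res$p)
  })
  tab <- do.call(rbind, rows)
  batch <- "cohort"
  if (length(unique(md$cohort)) < 2) {
    message("select_covariates: single cohort; batch designation skipped")
    batch <- NA_character_
  }
  sel <- tab$variable[!is.na(tab$p) & tab$p < alpha]
  list(batch = batch, covariates = sel, table = tab)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration for small tie-free samples (both groups <= 20),
#' normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b numeric vectors, both nonempty.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) mk_stop("wilcoxon", "empty group")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && max(length(values_a), length(values_b)) <= 20
  stats::wilcox.test(values_a, values_b, exact = exact, correct = FALSE)$p.value
}
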