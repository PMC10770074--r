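# Small in-code fixtures shared across the suite.

# Minimal profile from an explicit abundance matrix.
make_profile <- function(ab, groups, cohorts = rep("c1", ncol(ab)),
                         kingdoms = NULL, bmi = NULL) {
  if (is.null(colnames(ab))) colnames(ab) <- sprintf("s%02d", seq_len(ncol(ab)))
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("f%02d", seq_len(nrow(ab)))
  md <- data.frame(sample_id = colnames(ab), cohort = cohorts, group = groups,
                   stringsAsFactors = FALSE)
  if (!is.null(bmi)) md$bmi <- bmi
  abundance_profile(ab, md, kingdoms)
}

# Compositions whose log-scale basis has a prescribed correlation matrix;
# the forward model behind the SparCC tests.
make_correlated_compositions <- function(n_samples, sigma, baseline_sd = 1.5,
                                         seed = 1) {
  set.seed(seed)
  d <- nrow(sigma)
  z <- t(chol(sigma)) %*% matrix(rnorm(d * n_samples), d, n_samples)
  lat <- z + rnorm(d, 0, baseline_sd)
  ab <- exp(lat)
  ab <- sweep(ab, 2, colSums(ab), "/")
  dimnames(ab) <- list(sprintf("f%02d", seq_len(d)),
                       sprintf("s%03d", seq_len(n_samples)))
  ab
}

# Metadata expanded from the transcribed per-cohort demographic counts.
counts_fixture_metadata <- function(phase = "discovery") {
  tab <- utils::read.delim(system.file("extdata", "cohort_group_counts.tsv",
                                       package = "mkmarker"))
  tab <- tab[tab$phase %in% phase, ]
  md <- tab[rep(seq_len(nrow(tab)), tab$n), c("cohort", "stratum", "group")]
  md$sample_id <- sprintf("t%04d", seq_len(nrow(md)))
  rownames(md) <- NULL
  md
}

# Brute-force BH from its definition: q_i = min over j with p_j >= p_i of
# min(1, m * p_j / rank_j).
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[js] / rank(p, ties.method = "max")[js]))
  }
  q
}

# Pair-counting AUROC oracle.
auroc_paircount <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
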