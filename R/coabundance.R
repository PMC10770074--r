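#' Convert relative abundances to count-like values
#'
#' SparCC's Dirichlet resampling needs count-like input. Relative
#' abundances are multiplied by a nominal sequencing depth and rounded;
#' the conversion is documented in the output attribute.
#'
#' @param profile an [abundance_profile()] or a feature-by-sample matrix
#'   of fractions.
#' @param depth nominal per-sample depth (default 1e5).
#' @return Integer-valued matrix, features x samples.
#' @export
to_counts <- function(profile, depth = 1e5) {
  ab <- if (inherits(profile, "abundance_profile")) profile$abundance else profile
  structure(round(ab * depth), nominal_depth = depth)
}

# One SparCC estimate from one Dirichlet draw: log-ratio variance matrix,
# basis variances solved from the linear approximation, then pairwise
# correlations with iterative exclusion of the strongest pairs.
#' @keywords internal
sparcc_once <- function(counts, n_exclusion_rounds, exclusion_threshold) {
  d <- nrow(counts)
  fracs <- apply(counts + 1, 2, function(col) {
    g <- stats::rgamma(length(col), shape = col, rate = 1)
    g / sum(g)
  })
  lf <- log(fracs)
  v <- stats::cov(t(lf))
  tmat <- outer(diag(v), diag(v), "+") - 2 * v       # var(log x_i / x_j)
  m <- matrix(1, d, d); diag(m) <- d - 1
  tvec <- rowSums(tmat)
  rho_from <- function() {
    omega2 <- solve(m, tvec)
    # non-positive solutions (the linear approximation can undershoot for
    # small feature sets) are replaced by the smallest positive variance
    if (any(omega2 <= 0)) {
      floor_v <- if (any(omega2 > 0)) min(omega2[omega2 > 0]) else min(diag(v))
      omega2[omega2 <= 0] <- floor_v
    }
    w <- sqrt(omega2)
    r <- (outer(omega2, omega2, "+") - tmat) / (2 * outer(w, w))
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r
  }
  excluded <- matrix(FALSE, d, d)
  for (round in seq_len(n_exclusion_rounds)) {
    r <- rho_from()
    cand <- abs(r)
    cand[excluded | !upper.tri(cand)] <- 0
    # a component cannot drop out of its own basis equation entirely
    blocked <- diag(m) <= 2
    cand[blocked, ] <- 0; cand[, blocked] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    m[i, i] <- m[i, i] - 1; m[j, j] <- m[j, j] - 1
    m[i, j] <- m[i, j] - 1; m[j, i] <- m[j, i] - 1
    tvec[i] <- tvec[i] - tmat[i, j]
    tvec[j] <- tvec[j] - tmat[i, j]
  }
  rho_from()
}

#' SparCC correlations among features of a compositional table
#'
#' Implements the SparCC estimator for correlations among underlying
#' (basis) abundances from compositional data: per iteration, fractions
#' are resampled from a Dirichlet posterior (pseudocount 1), the log-ratio
#' variance matrix is formed, basis variances are solved from its row sums
#' under the sparse-correlation approximation, pairwise correlations are
#' derived, and the most strongly correlated pairs (above
#' `exclusion_threshold`) are iteratively removed from the basis system.
#' The element-wise median over iterations is returned.
#'
#' @param counts count-like matrix, features x samples (see [to_counts()]).
#' @param n_iterations Dirichlet resampling iterations (default 50).
#' @param n_exclusion_rounds maximum strong-pair exclusions per iteration
#'   (default 10).
#' @param exclusion_threshold |r| above which a pair is excluded from the
#'   basis system (default 0.1).
#' @param seed integer seed.
#' @return Symmetric correlation matrix in `[-1, 1]`.
#' @export
sparcc_correlations <- function(counts, n_iterations = 50L,
                                n_exclusion_rounds = 10L,
                                exclusion_threshold = 0.1, seed = 1L) {
  if (nrow(counts) < 4) {
    mk_stop("sparcc", "SparCC's basis-variance system is underdetermined below 4 features")
  }
  if (ncol(counts) < 10) mk_warn("sparcc", "fewer than 10 samples; estimates will be noisy")
  restore <- local_rng(child_seed(seed, "sparcc"))
  on.exit(restore())
  arr <- array(NA_real_, c(nrow(counts), nrow(counts), n_iterations))
  for (it in seq_len(n_iterations)) {
    arr[, , it] <- sparcc_once(counts, n_exclusion_rounds, exclusion_threshold)
  }
  r <- apply(arr, c(1, 2), stats::median)
  dimnames(r) <- list(rownames(counts), rownames(counts))
  r
}

#' Permutation p-values for SparCC correlations
#'
#' Each feature's samples are permuted independently, the full SparCC
#' estimate is recomputed, and a two-sided per-pair p-value is taken as
#' (1 + #\{|r_perm| >= |r_obs|\}) / (n_permutations + 1), BH-adjusted over
#' all tested pairs.
#'
#' @param counts count-like matrix, features x samples.
#' @param observed_r correlation matrix from [sparcc_correlations()].
#' @param n_permutations number of permutations (>= 99).
#' @param n_iterations,n_exclusion_rounds,exclusion_threshold passed to
#'   the per-permutation SparCC estimate.
#' @param seed integer seed.
#' @return List of symmetric matrices `p` and `q`.
#' @export
sparcc_pvalues <- function(counts, observed_r, n_permutations = 1000L,
                           n_iterations = 5L, n_exclusion_rounds = 10L,
                           exclusion_threshold = 0.1, seed = 1L) {
  if (n_permutations < 99) mk_stop("sparcc", "need at least 99 permutations")
  restore <- local_rng(child_seed(seed, "sparcc_perm"))
  on.exit(restore())
  d <- nrow(counts); n <- ncol(counts)
  hits <- matrix(0L, d, d)
  for (b in seq_len(n_permutations)) {
    perm <- counts
    for (i in seq_len(d)) perm[i, ] <- perm[i, sample.int(n)]
    rp <- sparcc_correlations(perm, n_iterations, n_exclusion_rounds,
                              exclusion_threshold,
                              seed = child_seed(seed, paste0("perm", b)))
    hits <- hits + (abs(rp) >= abs(observed_r))
  }
  p <- (1 + hits) / (n_permutations + 1)
  diag(p) <- NA_real_
  q <- p
  ut <- upper.tri(p)
  q[ut] <- bh_fdr(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  dimnames(p) <- dimnames(q) <- dimnames(observed_r)
  list(p = p, q = q)
}

#' Build a co-abundance network from correlations and significance
#'
#' `significant` mode keeps pairs with FDR q < 0.05; `strong` mode
#' additionally requires |r| strictly above 0.3. Nodes without any
#' retained edge are dropped.
#'
#' @param correlations symmetric correlation matrix.
#' @param q symmetric FDR matrix from [sparcc_pvalues()].
#' @param condition label such as `"EBW-CRC"`.
#' @param mode `"significant"` or `"strong"`.
#' @param p optional raw p-value matrix carried onto the edges.
#' @param kingdoms optional named kingdom vector for the nodes.
#' @param q_threshold significance cutoff (default 0.05).
#' @param r_threshold strong-edge cutoff on |r| (default 0.3, strict).
#' @return A `coabundance_network`: `nodes` (feature, kingdom, degree),
#'   `edges` (u < v, r, p, q), `condition`, `mode`.
#' @export
build_network <- function(correlations, q, condition = "",
                          mode = c("significant", "strong"), p = NULL,
                          kingdoms = NULL, q_threshold = 0.05,
                          r_threshold = 0.3) {
  mode <- match.arg(mode)
  stopifnot(all(dim(correlations) == dim(q)))
  ids <- rownames(correlations)
  ut <- which(upper.tri(q), arr.ind = TRUE)
  keep <- !is.na(q[ut]) & q[ut] < q_threshold
  if (mode == "strong") keep <- keep & abs(correlations[ut]) > r_threshold
  ut <- ut[keep, , drop = FALSE]
  edges <- data.frame(
    u = ids[ut[, 1]], v = ids[ut[, 2]],
    r = correlations[ut], q = q[ut],
    p = if (is.null(p)) rep(NA_real_, nrow(ut)) else p[ut],
    stringsAsFactors = FALSE
  )
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  used <- sort(unique(c(edges$u, edges$v)))
  deg <- table(factor(c(edges$u, edges$v), levels = used))
  nodes <- data.frame(
    feature = used,
    kingdom = if (is.null(kingdoms)) rep(NA_character_, length(used)) else unname(kingdoms[used]),
    degree = as.integer(deg),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges, condition = condition,
                 mode = mode),
            class = "coabundance_network")
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat(sprintf("coabundance_network [%s, %s]: %d nodes, %d edges\n",
              x$condition, x$mode, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Summarize a co-abundance network
#'
#' @param net a `coabundance_network`.
#' @param k_key number of key species to report (top degree; ties broken
#'   by summed |r|, then lexicographically).
#' @return A `network_summary`: node/edge counts, positive and negative
#'   edge counts, `pct_negative` (0 for an empty network), interkingdom
#'   edge count, and `key_nodes`.
#' @export
summarize_network <- function(net, k_key = 5L) {
  e <- net$edges
  n_pos <- sum(e$r > 0); n_neg <- sum(e$r < 0)
  inter <- 0L
  if (nrow(e) && !all(is.na(net$nodes$kingdom))) {
    kg <- stats::setNames(net$nodes$kingdom, net$nodes$feature)
    inter <- sum(kg[e$u] != kg[e$v], na.rm = TRUE)
  }
  key <- character()
  if (nrow(net$nodes)) {
    strength <- vapply(net$nodes$feature, function(f) {
      sum(abs(e$r[e$u == f | e$v == f]))
    }, numeric(1))
    ord <- order(-net$nodes$degree, -strength, net$nodes$feature)
    key <- net$nodes$feature[ord][seq_len(min(k_key, nrow(net$nodes)))]
  }
  structure(list(
    condition = net$condition, mode = net$mode,
    n_nodes = nrow(net$nodes), n_edges = nrow(e),
    n_positive = n_pos, n_negative = n_neg,
    pct_negative = if (nrow(e)) 100 * n_neg / nrow(e) else 0,
    n_interkingdom = inter, key_nodes = key
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("[%s/%s] %d nodes, %d edges (%d+/%d-, %.2f%% negative), %d interkingdom\n",
              x$condition, x$mode, x$n_nodes, x$n_edges, x$n_positive,
              x$n_negative, x$pct_negative, x$n_interkingdom))
  if (length(x$key_nodes)) cat("key:", paste(x$key_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square contrast of positive/negative edge proportions
#'
#' 2x2 chi-square (positive/negative x network), without Yates continuity
#' correction, comparing the sign composition of two networks.
#'
#' @param summary_a,summary_b `network_summary` objects (or lists with
#'   `n_positive`/`n_negative`).
#' @return List `chi2`, `p`, `table`.
#' @export
compare_edge_proportions <- function(summary_a, summary_b) {
  tab <- rbind(a = c(pos = summary_a$n_positive, neg = summary_a$n_negative),
               b = c(pos = summary_b$n_positive, neg = summary_b$n_negative))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    mk_stop("networks", "a zero row/column; use an exact test instead")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Write a network's edge list as TSV and GraphML
#'
#' @param net a `coabundance_network`.
#' @param tsv_path edge-list TSV path (u, v, r, p, q).
#' @param graphml_path optional GraphML path for visualization tools.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, tsv_path, graphml_path = NULL) {
  utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    con <- file(graphml_path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="kingdom" for="node" attr.name="kingdom" attr.type="string"/>',
      '<key id="r" for="edge" attr.name="r" attr.type="double"/>',
      '<graph edgedefault="undirected">'
    ), con)
    for (i in seq_len(nrow(net$nodes))) {
      writeLines(sprintf('<node id="%s"><data key="kingdom">%s</data></node>',
                         net$nodes$feature[i], net$nodes$kingdom[i]), con)
    }
    for (i in seq_len(nrow(net$edges))) {
      writeLines(sprintf('<edge source="%s" target="%s"><data key="r">%g</data></edge>',
                         net$edges$u[i], net$edges$v[i], net$edges$r[i]), con)
    }
    writeLines(c("</graph>", "</graphml>"), con)
  }
  invisible(c(tsv_path, graphml_path))
}
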