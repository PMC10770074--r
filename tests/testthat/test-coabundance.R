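test_that("sparcc suppresses closure-induced spurious correlation vs naive Pearson", {
  sig <- diag(16)
  ab <- make_correlated_compositions(80, sig, seed = 3)
  r <- sparcc_correlations(to_counts(ab), n_iterations = 20, seed = 3)
  off <- abs(r[upper.tri(r)])
  pear <- abs(cor(t(ab))[upper.tri(r)])
  expect_lt(median(off), 0.15)
  expect_lt(max(off), max(pear))
  expect_lt(mean(off), mean(pear))
  expect_equal(r, t(r))
  expect_true(all(r >= -1 & r <= 1))
  expect_error(sparcc_correlations(to_counts(ab[1:3, ])), "4 features")
})

test_that("sparcc recovers a planted basis correlation and reacts to permutation", {
  sig <- diag(20); sig[1, 2] <- sig[2, 1] <- 0.8
  ab <- make_correlated_compositions(100, sig, seed = 7)
  cnt <- to_counts(ab)
  r <- sparcc_correlations(cnt, n_iterations = 20, seed = 7)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  best <- ut[which.max(abs(r[upper.tri(r)])), ]
  expect_equal(sort(unname(best)), c(1L, 2L))
  expect_lt(abs(r[1, 2] - 0.8), 0.15)

  # permuting one feature's samples shrinks its correlations toward zero
  cnt_perm <- cnt
  set.seed(11)
  cnt_perm[1, ] <- cnt_perm[1, sample.int(ncol(cnt_perm))]
  rp <- sparcc_correlations(cnt_perm, n_iterations = 20, seed = 7)
  expect_lt(abs(rp[1, 2]), abs(r[1, 2]) / 2)
})

test_that("permutation p-values respect the floor and flag the planted pair", {
  sig <- diag(10); sig[1, 2] <- sig[2, 1] <- 0.9
  ab <- make_correlated_compositions(80, sig, baseline_sd = 1.0, seed = 13)
  cnt <- to_counts(ab)
  r <- sparcc_correlations(cnt, n_iterations = 10, seed = 13)
  pq <- sparcc_pvalues(cnt, r, n_permutations = 999, n_iterations = 3, seed = 13)
  expect_equal(min(pq$p, na.rm = TRUE), 1 / 1000)
  expect_equal(pq$p[1, 2], 1 / 1000)
  expect_lt(pq$q[1, 2], 0.05)
  expect_error(sparcc_pvalues(cnt, r, n_permutations = 50), "99")
})

test_that("network construction applies strict cutoffs and drops isolated nodes", {
  ids <- sprintf("f%d", 1:5)
  r <- q <- matrix(0, 5, 5, dimnames = list(ids, ids))
  r[1, 2] <- r[2, 1] <- 0.5;  q[1, 2] <- q[2, 1] <- 0.01
  r[1, 3] <- r[3, 1] <- -0.4; q[1, 3] <- q[3, 1] <- 0.04
  r[2, 3] <- r[3, 2] <- 0.3;  q[2, 3] <- q[3, 2] <- 0.01   # boundary |r| = 0.3
  r[4, 5] <- r[5, 4] <- 0.9;  q[4, 5] <- q[5, 4] <- 0.20   # not significant
  q[q == 0] <- 1
  kg <- setNames(c("bacteria", "bacteria", "fungi", "viruses", "archaea"), ids)
  strong <- build_network(r, q, "toy", "strong", kingdoms = kg)
  expect_equal(nrow(strong$edges), 2L)
  expect_setequal(paste(strong$edges$u, strong$edges$v),
                  c("f1 f2", "f1 f3"))
  expect_setequal(strong$nodes$feature, c("f1", "f2", "f3"))
  signif <- build_network(r, q, "toy", "significant", kingdoms = kg)
  expect_equal(nrow(signif$edges), 3L)   # boundary edge enters significant mode
  expect_true(all(paste(strong$edges$u, strong$edges$v) %in%
                    paste(signif$edges$u, signif$edges$v)))

  s <- summarize_network(strong)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_positive + s$n_negative, s$n_edges)
  expect_equal(s$pct_negative, 50)
  expect_equal(s$n_interkingdom, 1L)
  expect_equal(s$key_nodes[1], "f1")

  empty <- build_network(r, matrix(1, 5, 5, dimnames = list(ids, ids)),
                         "toy", "strong")
  se <- summarize_network(empty)
  expect_equal(se$n_edges, 0L)
  expect_equal(se$pct_negative, 0)
})

test_that("negative-edge proportions match the printed network arithmetic", {
  mk <- function(pos, neg) list(n_positive = pos, n_negative = neg,
                                n_edges = pos + neg)
  ebw_crc <- mk(218 - 76, 76)
  ebw_ctr <- mk(349 - 157, 157)
  expect_equal(round(100 * ebw_crc$n_negative / ebw_crc$n_edges, 2), 34.86)
  expect_equal(round(100 * ebw_ctr$n_negative / ebw_ctr$n_edges, 2), 44.99)

  res <- compare_edge_proportions(ebw_crc, ebw_ctr)
  # closed-form chi-square oracle on the 2x2 table
  tab <- rbind(c(142, 76), c(192, 157))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi2, sum((tab - E)^2 / E))
  expect_equal(res$p, pchisq(sum((tab - E)^2 / E), 1, lower.tail = FALSE))

  same <- compare_edge_proportions(mk(90, 10), mk(90, 10))
  expect_gt(same$p, 0.99)
  flip <- compare_edge_proportions(mk(90, 10), mk(10, 90))
  expect_lt(flip$p, 1e-10)
  expect_error(compare_edge_proportions(mk(5, 0), mk(7, 0)), "zero")
})

test_that("sparcc sign recovery holds across seeds for strong basis correlations", {
  sig <- diag(12)
  sig[1, 2] <- sig[2, 1] <- 0.7
  sig[3, 4] <- sig[4, 3] <- -0.6
  ok <- 0L
  for (s in 1:10) {
    ab <- make_correlated_compositions(80, sig, seed = 300 + s)
    r <- sparcc_correlations(to_counts(ab), n_iterations = 10, seed = s)
    ok <- ok + (r[1, 2] > 0 && r[3, 4] < 0)
  }
  expect_gte(ok, 9L)
})

test_that("network export writes edge-list TSV and GraphML", {
  ids <- sprintf("g%d", 1:4)
  r <- q <- matrix(0, 4, 4, dimnames = list(ids, ids))
  r[1, 2] <- r[2, 1] <- 0.6; q[] <- 1; q[1, 2] <- q[2, 1] <- 0.001
  net <- build_network(r, q, "toy", "strong",
                       kingdoms = setNames(rep("bacteria", 4), ids))
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  write_network(net, tsv, gml)
  back <- utils::read.delim(tsv)
  expect_equal(back$u, "g1")
  expect_true(any(grepl("graphml", readLines(gml))))
})
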