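#' All-against-all species-pathway association testing
#'
#' Spearman correlation between every (species, pathway) pair over a
#' shared sample set, with a two-sided t-approximation p-value, BH
#' adjustment across all tested pairs, and significance tiers at
#' q <= 0.05 / 0.01 / 0.001. This is the pairwise layer of hierarchical
#' all-against-all testing; no hierarchical blocking is applied.
#'
#' @param species_profile,pathway_profile [abundance_profile()]s sharing
#'   samples (typically restricted to differential features).
#' @param samples optional sample ids defining the condition (e.g. the
#'   EBW-CRC samples); defaults to the shared samples.
#' @param condition label stored on the result.
#' @return An `association_map` data.frame: `species`, `pathway`, `rho`,
#'   `p`, `q`, `tier` (`***`, `**`, `*` or empty), `untestable`.
#' @export
associate <- function(species_profile, pathway_profile, samples = NULL,
                      condition = "") {
  shared <- intersect(colnames(species_profile$abundance),
                      colnames(pathway_profile$abundance))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (!length(shared)) mk_stop("associate", "no shared samples")
  if (length(shared) < 5) mk_stop("associate", "need at least 5 shared samples")
  if (length(shared) < 10) mk_warn("associate", "fewer than 10 samples; power is limited")
  sp <- species_profile$abundance[, shared, drop = FALSE]
  pw <- pathway_profile$abundance[, shared, drop = FALSE]
  n <- length(shared)

  rs <- apply(sp, 1, rank)         # samples x species, rank-transformed
  rp <- apply(pw, 1, rank)
  sd_s <- apply(rs, 2, stats::sd)
  sd_p <- apply(rp, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(rs, rp))   # Pearson on ranks = Spearman
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  untest <- outer(sd_s == 0, sd_p == 0, "|")
  rho[untest] <- NA_real_; p[untest] <- NA_real_

  out <- data.frame(
    species = rep(rownames(sp), times = nrow(pw)),
    pathway = rep(rownames(pw), each = nrow(sp)),
    rho = as.vector(rho), p = as.vector(p),
    stringsAsFactors = FALSE
  )
  out$q <- bh_fdr(out$p)
  out$tier <- ifelse(is.na(out$q), "",
               ifelse(out$q <= 0.001, "***",
                ifelse(out$q <= 0.01, "**",
                 ifelse(out$q <= 0.05, "*", ""))))
  out$untestable <- is.na(out$p)
  attr(out, "condition") <- condition
  attr(out, "n_samples") <- n
  class(out) <- c("association_map", "data.frame")
  out
}
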