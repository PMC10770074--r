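#' Derive a deterministic child seed from a parent seed and a step tag
#'
#' Every stochastic sub-step of the pipeline draws its own seed from the
#' single user-supplied seed so that stages can be re-run independently and
#' reproducibly. The derivation is a small string hash folded into the
#' parent seed, kept strictly below 2^31 - 1 so it is always a valid R
#' integer seed.
#'
#' @param seed parent integer seed.
#' @param tag character tag naming the sub-step.
#' @return integer seed in [0, 2^31 - 2].
#' @keywords internal
child_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% (2^31 - 1))
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a stage-prefixed message
#' @keywords internal
mk_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

#' Emit a logged warning with a stage prefix
#' @keywords internal
mk_warn <- function(stage, ...) {
  warning(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds so that both classes appear in
#' every fold (classes are split separately and folds balanced in size).
#'
#' @param labels logical vector (TRUE = positive class).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @keywords internal
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (min(sum(labels), sum(!labels)) < k) {
    mk_stop("folds", "each class needs at least k=", k, " samples for stratified folds")
  }
  folds <- integer(n)
  rng <- local_rng(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  rng()
  folds
}

# Sets the RNG state and returns a restorer; keeps fold assignment and
# model fitting reproducible without clobbering the caller's stream.
#' @keywords internal
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
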