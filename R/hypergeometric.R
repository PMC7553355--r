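## The hypergeometric index: the association statistic connecting two node
## sets through a shared patient layer. For two entities with marginal
## patient counts n_a and n_b in a cohort of N patients, the index is
## -log10 of the inclusive upper-tail probability P(X >= k) where
## X ~ Hypergeometric(N, n_a, n_b) and k is the observed shared-patient
## count. An index >= 2 corresponds to a tail probability <= 0.01.

## Log upper-tail probabilities for every k = 0..min(nA, nB), computed by
## pairwise log-add from the top of the tail so that small tails keep full
## relative precision.
.logTailAllK <- function(nA, nB, N) {
  m <- min(nA, nB)
  i <- seq.int(0L, m)
  lt <- lchoose(nA, i) + lchoose(N - nA, nB - i) - lchoose(N, nB)
  out <- numeric(m + 1L)
  acc <- lt[m + 1L]
  out[m + 1L] <- acc
  if (m >= 1L) {
    for (j in seq.int(m, 1L)) {
      acc <- .logaddexp(acc, lt[j])
      out[j] <- acc
    }
  }
  ## tail at k = 0 is exactly 1
  out[1L] <- 0
  pmin(out, 0)
}

.checkHyperArgs <- function(k, nA, nB, N) {
  if (any(nA < 1L) || any(nB < 1L))
    stop("n_a and n_b must be >= 1")
  if (any(nA > N) || any(nB > N))
    stop("marginal counts cannot exceed the population size N")
  if (any(k < 0L))
    stop("k must be non-negative")
  if (any(k > pmin(nA, nB)))
    stop("k cannot exceed min(n_a, n_b)")
}

#' Hypergeometric index of patient overlap
#'
#' Computes \eqn{-\log_{10} P(X \ge k)} for \eqn{X} hypergeometric with
#' population size `N`, `nA` successes and `nB` draws. This is the
#' association score used throughout the workflow: between two phenotypes
#' sharing patients, and between a phenotype and a genomic segment (SOR)
#' sharing patients. A value of 2 corresponds to a tail probability of 0.01,
#' the default cut separating more-specific (comorbid) from less-specific
#' pairs.
#'
#' The tail is summed in log space (log-gamma binomials combined by pairwise
#' log-add-exp), so very small tail probabilities retain full relative
#' precision even for large cohorts.
#'
#' @param k observed shared-patient count(s).
#' @param nA,nB marginal patient counts of the two entities.
#' @param N cohort size.
#' @return Non-negative numeric vector of index values; `k = 0` gives 0.
#' @examples
#' hypergeometricIndex(4, 5, 4, 10)  # -log10(5/210)
#' @export
hypergeometricIndex <- function(k, nA, nB, N) {
  -.logTailVec(k, nA, nB, N) / log(10)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, nA, nB)`; the probability scale
#' companion of [hypergeometricIndex()]. Also the one-sided (enrichment)
#' Fisher exact p-value for the 2x2 table with margins `nA`, `nB` over a
#' universe of size `N` and joint count `k`.
#'
#' @inheritParams hypergeometricIndex
#' @return Numeric vector of tail probabilities in (0, 1].
#' @export
hyperTailP <- function(k, nA, nB, N) {
  exp(.logTailVec(k, nA, nB, N))
}

## Vectorised log-tail; amortises work across entries sharing the same
## margins by computing the full tail vector once per unique (nA, nB, N).
.logTailVec <- function(k, nA, nB, N) {
  n <- max(length(k), length(nA), length(nB), length(N))
  k <- rep_len(as.integer(k), n)
  nA <- rep_len(as.integer(nA), n)
  nB <- rep_len(as.integer(nB), n)
  N <- rep_len(as.integer(N), n)
  .checkHyperArgs(k, nA, nB, N)
  key <- paste(nA, nB, N)
  out <- numeric(n)
  for (grp in split(seq_len(n), key)) {
    tails <- .logTailAllK(nA[grp[1L]], nB[grp[1L]], N[grp[1L]])
    out[grp] <- tails[k[grp] + 1L]
  }
  out
}
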