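## Phenotype-phenotype comorbidity network: pair table construction from
## patient overlap, specificity split, sampling and the two random models.

#' Incidence matrix of patients x phenotypes
#'
#' Sparse 0/1 matrix with one row per patient and one column per phenotype
#' term, in sorted order. Internal building block for pair and SOR
#' association counting.
#' @noRd
.phenotypeIncidence <- function(cohort) {
  terms <- phenotypeUniverse(cohort)
  sets <- phenotypeSets(cohort)
  j <- match(unlist(sets, use.names = FALSE), terms)
  i <- rep(seq_along(sets), lengths(sets))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(sets), length(terms)),
                       dimnames = list(names(sets), terms))
}

#' Build the phenotype pair association table
#'
#' Projects the patient-phenotype bipartite network onto phenotypes: for each
#' unordered pair of terms co-occurring in at least one patient, records the
#' shared-patient count `k`, the marginal counts `n_a` and `n_b`, the cohort
#' size `N` and the hypergeometric index. Pairs with `k = 0` are excluded
#' here; they form the unconnected universe (see [unconnectedUniverse()]).
#'
#' @param cohort a [PatientCohort-class] with at least two patients.
#' @return data.frame with columns `term_a`, `term_b` (canonical order),
#'   `k`, `n_a`, `n_b`, `N`, `index`, sorted by term pair.
#' @export
buildPairTable <- function(cohort) {
  if (nPatients(cohort) < 2L) stop("cohort must have at least two patients")
  inc <- .phenotypeIncidence(cohort)
  co <- Matrix::crossprod(inc)          # phenotype x phenotype co-occurrence
  nTerm <- Matrix::diag(co)
  co <- Matrix::triu(co, k = 1)
  idx <- Matrix::which(co > 0, arr.ind = TRUE)
  terms <- colnames(inc)
  if (nrow(idx) == 0L)
    return(data.frame(term_a = character(), term_b = character(),
                      k = integer(), n_a = integer(), n_b = integer(),
                      N = integer(), index = numeric()))
  k <- as.integer(co[idx])
  df <- data.frame(term_a = terms[idx[, 1]], term_b = terms[idx[, 2]],
                   k = k,
                   n_a = as.integer(nTerm[idx[, 1]]),
                   n_b = as.integer(nTerm[idx[, 2]]),
                   N = nPatients(cohort), stringsAsFactors = FALSE)
  df$index <- hypergeometricIndex(df$k, df$n_a, df$n_b, df$N)
  df[order(df$term_a, df$term_b), , drop = FALSE]
}

#' Split pairs into more-specific and less-specific lists
#'
#' Partition by the hypergeometric index: pairs with `index >= threshold` are
#' more-specific (comorbid, ties at the threshold included), the rest
#' less-specific. The two lists are exhaustive and disjoint.
#'
#' @param pairs pair table from [buildPairTable()].
#' @param threshold index cut, default 2 (tail probability 0.01).
#' @return list with elements `more_specific` and `less_specific`.
#' @export
splitPairs <- function(pairs, threshold = 2) {
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- pairs$index >= threshold
  list(more_specific = pairs[keep, , drop = FALSE],
       less_specific = pairs[!keep, , drop = FALSE])
}

#' Sample pair-list replicates
#'
#' Uniform sampling without replacement of `size` pairs from a pair universe,
#' repeated `R` times. Replicate `r` uses a child seed derived from
#' `(seed, r)`, so each replicate is individually reproducible and the
#' collection is reproducible as a whole. Used to down-sample the
#' less-specific and unconnected pair lists to the length of the
#' more-specific list.
#'
#' @param universe data.frame of candidate pairs.
#' @param size rows per replicate; must not exceed `nrow(universe)`.
#' @param R replicate count (default 50).
#' @param seed integer seed.
#' @return list of `R` data.frames; each carries attributes `replicate` and
#'   `seed`.
#' @export
samplePairs <- function(universe, size, R = 50L, seed = 1L) {
  if (size > nrow(universe))
    stop("sample size exceeds the pair universe (", nrow(universe), ")")
  lapply(seq_len(R), function(r) {
    cs <- .childSeed(seed, r)
    rows <- .withSeed(cs, sample.int(nrow(universe), size))
    out <- universe[sort(rows), , drop = FALSE]
    attr(out, "replicate") <- r
    attr(out, "seed") <- cs
    out
  })
}

#' Unconnected phenotype pair universe
#'
#' All unordered phenotype pairs that share no patient at all in the
#' bipartite phenotype-patient network (`k = 0`), i.e. the complement of the
#' pair table within all C(V, 2) term pairs.
#'
#' @param cohort a [PatientCohort-class].
#' @param pairs optional precomputed pair table (recomputed if missing).
#' @return data.frame with columns `term_a`, `term_b`.
#' @export
unconnectedUniverse <- function(cohort, pairs = NULL) {
  terms <- phenotypeUniverse(cohort)
  if (is.null(pairs)) pairs <- buildPairTable(cohort)
  connected <- matrix(FALSE, length(terms), length(terms),
                      dimnames = list(terms, terms))
  if (nrow(pairs))
    connected[cbind(pairs$term_a, pairs$term_b)] <- TRUE
  sel <- which(upper.tri(connected) & !connected, arr.ind = TRUE)
  data.frame(term_a = terms[sel[, 1]], term_b = terms[sel[, 2]],
             stringsAsFactors = FALSE)[order(terms[sel[, 1]], terms[sel[, 2]]), ,
                                       drop = FALSE]
}

#' Degree-preserving (links-based) randomisation
#'
#' Rewires a simple undirected pair list by repeated double-edge swaps,
#' rejecting swaps that would create self-loops or parallel edges, so the
#' degree of every phenotype is exactly preserved. The target is 10 x |E|
#' accepted swaps; on graphs where few swaps are feasible the attempt budget
#' caps the loop and a warning is raised.
#'
#' @param pairs data.frame with columns `term_a`, `term_b`.
#' @param seed integer seed.
#' @return data.frame of rewired pairs, canonical order.
#' @export
randomizeLinks <- function(pairs, seed = 1L) {
  E <- nrow(pairs)
  if (E < 2L) {
    warning("fewer than 2 edges; returned unchanged")
    return(pairs[, c("term_a", "term_b"), drop = FALSE])
  }
  nodes <- sort(unique(c(pairs$term_a, pairs$term_b)))
  V <- length(nodes)
  a <- match(pairs$term_a, nodes)
  b <- match(pairs$term_b, nodes)
  ## edge-set membership as a flat logical vector over ordered node pairs;
  ## random draws are consumed from pre-generated blocks to keep the swap
  ## loop cheap
  lo <- ifelse(a < b, a, b); hi <- ifelse(a < b, b, a)
  present <- logical(V * V)
  present[(lo - 1) * V + hi] <- TRUE
  target <- 10L * E
  maxAttempts <- 200L * E
  .withSeed(seed, {
    accepted <- 0L; attempts <- 0L
    block <- 8192L; pos <- block  # force initial refill
    ei <- ej <- orient <- NULL
    while (accepted < target && attempts < maxAttempts) {
      attempts <- attempts + 1L
      pos <- pos + 1L
      if (pos > block) {
        ei <- sample.int(E, block, replace = TRUE)
        ej <- sample.int(E, block, replace = TRUE)
        orient <- runif(block) < 0.5
        pos <- 1L
      }
      i <- ei[pos]; j <- ej[pos]
      if (i == j) next
      ## double-edge swap with one of the two pairings chosen at random
      if (orient[pos]) {
        x1 <- a[i]; y1 <- b[j]; x2 <- a[j]; y2 <- b[i]
      } else {
        x1 <- a[i]; y1 <- a[j]; x2 <- b[i]; y2 <- b[j]
      }
      if (x1 == y1 || x2 == y2) next
      k1 <- if (x1 < y1) (x1 - 1) * V + y1 else (y1 - 1) * V + x1
      k2 <- if (x2 < y2) (x2 - 1) * V + y2 else (y2 - 1) * V + x2
      if (k1 == k2 || present[k1] || present[k2]) next
      ai <- a[i]; bi <- b[i]; aj <- a[j]; bj <- b[j]
      present[if (ai < bi) (ai - 1) * V + bi else (bi - 1) * V + ai] <- FALSE
      present[if (aj < bj) (aj - 1) * V + bj else (bj - 1) * V + aj] <- FALSE
      present[k1] <- TRUE; present[k2] <- TRUE
      a[i] <- x1; b[i] <- y1
      a[j] <- x2; b[j] <- y2
      accepted <- accepted + 1L
    }
    if (accepted < target)
      warning("attempt budget reached after ", accepted, " accepted swaps")
  })
  out <- .canonPairs(nodes[a], nodes[b])
  deg <- function(ta, tb)
    as.integer(table(factor(c(ta, tb), levels = nodes)))
  stopifnot(identical(deg(out$term_a, out$term_b),
                      deg(pairs$term_a, pairs$term_b)))
  out
}

#' Label-permuting (nodes-based) randomisation
#'
#' Applies one uniform random permutation of the phenotype labels to both
#' endpoints of every pair. The edge count and the degree multiset are
#' preserved, but individual phenotypes generally change degree.
#'
#' @inheritParams randomizeLinks
#' @return data.frame of relabelled pairs, canonical order.
#' @export
randomizeNodes <- function(pairs, seed = 1L) {
  nodes <- sort(unique(c(pairs$term_a, pairs$term_b)))
  perm <- .withSeed(seed, sample(nodes))
  names(perm) <- nodes
  .canonPairs(unname(perm[pairs$term_a]), unname(perm[pairs$term_b]))
}

#' Phenotype prevalence
#'
#' Percentage of patients carrying each phenotype term.
#'
#' @param cohort a [PatientCohort-class].
#' @return data.frame with `term`, `count`, `prevalence` (percent).
#' @export
phenotypePrevalence <- function(cohort) {
  counts <- table(unlist(phenotypeSets(cohort), use.names = FALSE))
  data.frame(term = names(counts), count = as.integer(counts),
             prevalence = 100 * as.integer(counts) / nPatients(cohort),
             stringsAsFactors = FALSE)
}

#' Mean prevalence per pair
#'
#' Average of the two endpoint prevalences for each pair; the quantity whose
#' distribution separates more-specific from less-specific pair lists.
#'
#' @param pairs data.frame with `term_a`, `term_b`.
#' @param prevalence output of [phenotypePrevalence()].
#' @return numeric vector, one value per pair.
#' @export
pairPrevalence <- function(pairs, prevalence) {
  p <- setNames(prevalence$prevalence, prevalence$term)
  (unname(p[pairs$term_a]) + unname(p[pairs$term_b])) / 2
}
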