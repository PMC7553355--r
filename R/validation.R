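## External-evidence statistics: disease overlap for pairs, literature
## co-mention Fisher tests, and patient-level cluster support.

#' Number of diseases annotated with both phenotypes of each pair
#'
#' @param pairs data.frame with `term_a`, `term_b`.
#' @param diseases a [DiseaseAnnotations-class].
#' @return integer vector, one count per pair.
#' @export
pairDiseaseCounts <- function(pairs, diseases) {
  ann <- diseasePhenotypes(diseases)
  if (!length(ann) || !nrow(pairs)) return(integer(nrow(pairs)))
  terms <- sort(unique(c(pairs$term_a, pairs$term_b)))
  inc <- vapply(ann, function(ph) terms %in% ph, logical(length(terms)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(terms))
  rownames(inc) <- terms
  as.integer(rowSums(inc[pairs$term_a, , drop = FALSE] &
                     inc[pairs$term_b, , drop = FALSE]))
}

#' Count pairs supported by known diseases
#'
#' Number of pairs whose two phenotypes co-occur in at least `minDiseases`
#' diseases. Counts are monotone non-increasing in `minDiseases`.
#'
#' @inheritParams pairDiseaseCounts
#' @param minDiseases disease-count threshold (typically 1, 2 or 3).
#' @return integer count of supported pairs.
#' @export
pairDiseaseOverlap <- function(pairs, diseases, minDiseases = 1L) {
  sum(pairDiseaseCounts(pairs, diseases) >= minDiseases)
}

#' Literature co-mention test for a phenotype pair
#'
#' Builds the 2x2 contingency table of abstract ids over the corpus universe
#' and computes the one-sided (enrichment) Fisher exact p-value for joint
#' mention, which for this table equals the upper hypergeometric tail
#' `P(X >= n11)`. A term absent from the corpus yields an explicit
#' missing-term result rather than p = 1.
#'
#' @param corpus a [LiteratureCorpus-class].
#' @param termA,termB term ids (phenotypes or genes).
#' @return list with `term_a`, `term_b`, `n11`, `n10`, `n01`, `n00`, `U`,
#'   `p`, and `missing` (character vector of absent terms, empty when both
#'   are present; `p` is `NA` then).
#' @export
comentionTest <- function(corpus, termA, termB) {
  idx <- corpusIndex(corpus)
  absent <- c(termA, termB)[!(c(termA, termB) %in% names(idx))]
  U <- corpusUniverseSize(corpus)
  if (length(absent))
    return(list(term_a = termA, term_b = termB, n11 = NA_integer_,
                n10 = NA_integer_, n01 = NA_integer_, n00 = NA_integer_,
                U = U, p = NA_real_, missing = absent))
  A <- idx[[termA]]; B <- idx[[termB]]
  n11 <- length(intersect(A, B))
  n10 <- length(A) - n11
  n01 <- length(B) - n11
  n00 <- U - n11 - n10 - n01
  p <- if (n11 == 0L) 1 else hyperTailP(n11, length(A), length(B), U)
  list(term_a = termA, term_b = termB, n11 = n11, n10 = n10, n01 = n01,
       n00 = n00, U = U, p = p, missing = character())
}

#' Co-mention support for a phenotype-gene map with a permutation null
#'
#' Observed statistic: the number of (phenotype, gene) pairs in the map that
#' share at least one abstract in the corpus (a gene or phenotype absent from
#' the corpus contributes an empty abstract set). Null: the gene -> abstract
#' set assignment is permuted uniformly among the map's genes, preserving the
#' multiset of abstract-set sizes, and the statistic recomputed; the z-score
#' is taken against the null mean and standard deviation.
#'
#' @param corpus a [LiteratureCorpus-class].
#' @param map phenotype-gene map (named list).
#' @param nRandomizations null replicates (default 100).
#' @param seed integer seed.
#' @return list with `observed`, `nullMean`, `nullSd`, `z` (`NA` when the
#'   null sd is 0), `nRandomizations`.
#' @export
geneComentionCount <- function(corpus, map, nRandomizations = 100L,
                               seed = 1L) {
  idx <- corpusIndex(corpus)
  genes <- sort(unique(unlist(map, use.names = FALSE)))
  geneAbs <- lapply(setNames(genes, genes), function(g) idx[[g]] %||% character())
  phenoAbs <- lapply(setNames(names(map), names(map)), function(p)
    idx[[p]] %||% character())
  countShared <- function(assign) {
    total <- 0L
    for (p in names(map)) {
      pa <- phenoAbs[[p]]
      if (!length(pa)) next
      for (g in map[[p]])
        if (length(intersect(pa, assign[[g]])) > 0L) total <- total + 1L
    }
    total
  }
  observed <- countShared(geneAbs)
  nulls <- vapply(seq_len(nRandomizations), function(r) {
    perm <- .withSeed(.childSeed(seed, r), sample(length(genes)))
    assign <- setNames(geneAbs[perm], genes)
    countShared(assign)
  }, numeric(1))
  mu <- mean(nulls); s <- sd(nulls)
  list(observed = observed, nullMean = mu, nullSd = s,
       z = if (isTRUE(s > 0)) (observed - mu) / s else NA_real_,
       nRandomizations = nRandomizations)
}

#' Patient support for phenotype clusters, against a randomised null
#'
#' For every patient with at least one phenotype in at least one cluster,
#' computes the maximum number of their phenotypes co-located in a single
#' cluster, and summarises how many patients reach 2 and 3. The null
#' randomises the cluster-phenotype assignment: the pooled phenotype multiset
#' is redistributed over clusters of identical sizes, and the same summaries
#' recomputed.
#'
#' @param cohort a [PatientCohort-class].
#' @param clusters list of character phenotype sets.
#' @param nRandomizations null replicates (default 100).
#' @param seed integer seed.
#' @return list with `perPatient` (data.frame `patient_id`,
#'   `n_phenotypes`, `clusters_touched`, `max_in_cluster`), `real`
#'   (named counts `ge2`, `ge3`), `nullMean`, `nullSd` (same names), and
#'   `nRandomizations`.
#' @export
patientClusterSupport <- function(cohort, clusters, nRandomizations = 100L,
                                  seed = 1L) {
  summarise <- function(cl) {
    stats <- t(vapply(patientIds(cohort), function(id) {
      ph <- phenotypeSets(cohort)[[id]]
      inCl <- vapply(cl, function(s) length(intersect(ph, s)), integer(1))
      c(touched = sum(inCl > 0L), maxIn = if (length(inCl)) max(inCl) else 0L)
    }, integer(2)))
    stats
  }
  real <- summarise(clusters)
  perPatient <- data.frame(
    patient_id = patientIds(cohort),
    n_phenotypes = lengths(phenotypeSets(cohort)),
    clusters_touched = real[, "touched"],
    max_in_cluster = real[, "maxIn"], row.names = NULL,
    stringsAsFactors = FALSE)
  perPatient <- perPatient[perPatient$clusters_touched > 0L, , drop = FALSE]
  counts <- function(stats) c(ge2 = sum(stats[, "maxIn"] >= 2L),
                              ge3 = sum(stats[, "maxIn"] >= 3L))
  pool <- unlist(clusters, use.names = FALSE)
  sizes <- lengths(clusters)
  nulls <- vapply(seq_len(nRandomizations), function(r) {
    shuffled <- .withSeed(.childSeed(seed, r), sample(pool))
    cl <- split(shuffled, rep(seq_along(sizes), sizes))
    counts(summarise(cl))
  }, numeric(2))
  list(perPatient = perPatient, real = counts(real),
       nullMean = rowMeans(nulls), nullSd = apply(nulls, 1, sd),
       nRandomizations = nRandomizations)
}

#' Per-patient phenotype-count vs clusters-touched contingency
#'
#' Exact contingency table of the number of distinct phenotypes a patient
#' holds against the number of distinct clusters those phenotypes belong to.
#' Patients with no phenotype in any cluster are excluded.
#'
#' @param cohort a [PatientCohort-class].
#' @param clusters list of character phenotype sets.
#' @return data.frame with `n_phenotypes`, `n_clusters`, `n_patients`.
#' @export
clusterMembershipSummary <- function(cohort, clusters) {
  rows <- lapply(patientIds(cohort), function(id) {
    ph <- phenotypeSets(cohort)[[id]]
    touched <- sum(vapply(clusters, function(s)
      length(intersect(ph, s)) > 0L, logical(1)))
    if (touched == 0L) return(NULL)
    data.frame(n_phenotypes = length(ph), n_clusters = touched)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(n_phenotypes = integer(), n_clusters = integer(),
                      n_patients = integer()))
  agg <- stats::aggregate(list(n_patients = rep(1L, nrow(rows))),
                          by = rows[c("n_phenotypes", "n_clusters")], FUN = sum)
  agg[order(agg$n_phenotypes, agg$n_clusters), , drop = FALSE]
}
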