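## Resnik semantic similarity over the phenotype ontology, with the
## information content estimated from a disease-annotation corpus and
## normalised by the maximum observed IC, so similarities live in [0, 1].

#' Information content table from annotated objects
#'
#' Each annotated object (typically a disease) contributes its phenotype
#' terms propagated to all ancestors; the annotation probability of a term is
#' the fraction of objects annotated (directly or through descendants) with
#' it, and `IC = -ln p`. The root of a connected ontology receives IC 0.
#' Terms never reached by any annotation have undefined IC and are absent
#' from the table.
#'
#' @param ontology a [PhenOntology-class].
#' @param annotations a [DiseaseAnnotations-class] (or any named list of term
#'   sets); terms unknown to the ontology are ignored.
#' @return list with `ic` (named numeric), `icMax` (maximum finite IC over
#'   annotated terms) and `nObjects`.
#' @export
buildInformationContent <- function(ontology, annotations) {
  sets <- if (is(annotations, "DiseaseAnnotations"))
    diseasePhenotypes(annotations) else annotations
  known <- ontologyTerms(ontology)
  counts <- setNames(numeric(length(known)), known)
  n <- 0L
  for (ph in sets) {
    ph <- intersect(ph, known)
    if (!length(ph)) next
    n <- n + 1L
    anc <- unique(unlist(termAncestors(ontology, ph), use.names = FALSE))
    counts[anc] <- counts[anc] + 1
  }
  if (n == 0L) stop("no annotation object maps to the ontology")
  p <- counts[counts > 0] / n
  ic <- -log(p)
  list(ic = ic, icMax = max(ic), nObjects = n)
}

#' Resnik similarity between two ontology terms
#'
#' The information content of the most informative common ancestor (MICA),
#' normalised by the maximum IC so the score lies in `[0, 1]`. When the only
#' common ancestor is the root (IC 0) the similarity is 0; `sim(a, a)` equals
#' `IC(a) / IC_max`. A term with undefined IC (never annotated) is an error
#' naming the term.
#'
#' @param ontology a [PhenOntology-class].
#' @param icTable output of [buildInformationContent()].
#' @param termA,termB term ids.
#' @return similarity in `[0, 1]`.
#' @export
resnikSimilarity <- function(ontology, icTable, termA, termB) {
  ic <- icTable$ic
  for (t in c(termA, termB))
    if (!(t %in% names(ic)))
      stop("term with undefined information content: ", t)
  common <- intersect(termAncestors(ontology, termA),
                      termAncestors(ontology, termB))
  common <- intersect(common, names(ic))
  if (!length(common)) return(0)
  if (icTable$icMax <= 0) return(0)
  max(ic[common]) / icTable$icMax
}

#' Mean within-cluster semantic similarity, with a randomised-cluster null
#'
#' Observed statistic: the mean Resnik similarity over all unordered
#' phenotype pairs within each cluster, pooled across clusters. Null
#' replicate: the pooled phenotype multiset is reassigned uniformly at random
#' to clusters of identical sizes (the phenotype distribution and cluster
#' sizes are preserved) and the statistic recomputed. The z-score compares
#' the observed mean against the null distribution.
#'
#' @param clusters list of character phenotype sets (each of size >= 2).
#' @param ontology a [PhenOntology-class].
#' @param icTable output of [buildInformationContent()].
#' @param nRandomizations null replicates (default 1000).
#' @param seed integer seed.
#' @return list with `observed`, `nullMean`, `nullSd`, `z` (`NA` when the
#'   null sd is 0) and `nRandomizations`.
#' @export
clusterSemanticScore <- function(clusters, ontology, icTable,
                                 nRandomizations = 1000L, seed = 1L) {
  if (any(lengths(clusters) < 2L))
    stop("every cluster must contain at least 2 phenotypes")
  cache <- new.env(hash = TRUE, parent = emptyenv())
  simOf <- function(a, b) {
    k <- .pairKey(a, b)
    if (!exists(k, envir = cache))
      assign(k, resnikSimilarity(ontology, icTable, a, b), envir = cache)
    get(k, envir = cache)
  }
  meanSim <- function(cls) {
    sims <- unlist(lapply(cls, function(ph) {
      if (length(ph) < 2L) return(numeric())
      cmb <- utils::combn(ph, 2L)
      vapply(seq_len(ncol(cmb)), function(i)
        simOf(cmb[1, i], cmb[2, i]), numeric(1))
    }), use.names = FALSE)
    mean(sims)
  }
  observed <- meanSim(clusters)
  pool <- unlist(clusters, use.names = FALSE)
  sizes <- lengths(clusters)
  nulls <- vapply(seq_len(nRandomizations), function(r) {
    shuffled <- .withSeed(.childSeed(seed, r), sample(pool))
    meanSim(split(shuffled, rep(seq_along(sizes), sizes)))
  }, numeric(1))
  mu <- mean(nulls); s <- sd(nulls)
  list(observed = observed, nullMean = mu, nullSd = s,
       z = if (isTRUE(s > 0)) (observed - mu) / s else NA_real_,
       nRandomizations = nRandomizations)
}
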