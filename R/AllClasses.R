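#' @import methods
#' @importClassesFrom GenomicRanges GRanges
NULL

.CNV_KINDS <- c("deletion", "duplication")

#' Patient cohort with phenotype sets and CNV intervals
#'
#' Container for the cohort the whole workflow operates on: each patient has
#' an opaque id, a non-empty set of ontology phenotype term ids, and zero or
#' more copy-number-variant intervals (stored as `GRanges` with a `kind`
#' metadata column, `deletion` or `duplication`). Patients without CNVs take
#' part in the phenotype-only stages and are skipped by the genotype stages.
#' Patients are kept sorted by id and phenotype sets are deduplicated, so
#' loading order never influences downstream results.
#'
#' @slot ids character vector of unique patient ids.
#' @slot phenotypes named list (by patient id) of sorted character vectors of
#'   phenotype term ids.
#' @slot cnvs named list (by patient id) of `GRanges` with a `kind` column.
#'
#' @param ids,phenotypes,cnvs see slots; `cnvs = NULL` gives every patient an
#'   empty range set.
#' @return `PatientCohort()` returns a validated object.
#' @aliases nPatients patientIds phenotypeSets cnvRanges phenotypeUniverse
#' @export PatientCohort
#' @exportClass PatientCohort
setClass("PatientCohort",
         slots = c(ids = "character", phenotypes = "list", cnvs = "list"))

setValidity("PatientCohort", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids))
    msg <- c(msg, "patient ids must be unique")
  if (!identical(names(object@phenotypes), object@ids) ||
      !identical(names(object@cnvs), object@ids))
    msg <- c(msg, "phenotypes and cnvs must be named by patient id, in order")
  if (any(!vapply(object@phenotypes, is.character, logical(1))) ||
      any(lengths(object@phenotypes) == 0L))
    msg <- c(msg, "every patient needs a non-empty character phenotype set")
  for (gr in object@cnvs) {
    if (!is(gr, "GRanges")) {
      msg <- c(msg, "cnvs must be GRanges")
      break
    }
    if (length(gr) && (is.null(gr$kind) || !all(gr$kind %in% .CNV_KINDS))) {
      msg <- c(msg, "CNV kind must be 'deletion' or 'duplication'")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

PatientCohort <- function(ids, phenotypes, cnvs = NULL) {
  ids <- as.character(ids)
  if (is.null(cnvs))
    cnvs <- rep(list(GenomicRanges::GRanges(kind = character())), length(ids))
  ord <- order(ids)
  ids <- ids[ord]
  phenotypes <- lapply(phenotypes[ord], function(p) sort(unique(as.character(p))))
  cnvs <- lapply(cnvs[ord], function(gr) if (length(gr) > 1L) sort(gr) else gr)
  names(phenotypes) <- ids
  names(cnvs) <- ids
  new("PatientCohort", ids = ids, phenotypes = phenotypes, cnvs = cnvs)
}

#' Phenotype ontology (DAG with ancestor closure)
#'
#' Minimal in-memory representation of an `is_a` ontology: term ids, names,
#' parent lists, the reflexive-transitive ancestor closure, an alt-id map
#' used to resolve secondary ids in annotation files, and the set of terms
#' flagged obsolete.
#'
#' @slot terms character vector of primary term ids.
#' @slot termNames named character vector of term names.
#' @slot parents named list of parent ids per term.
#' @slot ancestors named list: reflexive-transitive closure per term.
#' @slot altIds named character: alternative id -> primary id.
#' @slot obsolete character vector of obsolete term ids.
#' @aliases ontologyTerms termAncestors termParents altIdMap
#' @exportClass PhenOntology
setClass("PhenOntology",
         slots = c(terms = "character", termNames = "character",
                   parents = "list", ancestors = "list",
                   altIds = "character", obsolete = "character"))

setValidity("PhenOntology", function(object) {
  msg <- character()
  if (anyDuplicated(object@terms))
    msg <- c(msg, "term ids must be unique")
  if (!all(names(object@ancestors) == object@terms))
    msg <- c(msg, "ancestor closure must cover every term")
  ok <- vapply(object@terms, function(t)
    t %in% object@ancestors[[t]], logical(1))
  if (!all(ok))
    msg <- c(msg, "ancestor closure must be reflexive")
  if (length(msg)) msg else TRUE
})

#' Functional-system gene-set collection
#'
#' A named collection of gene sets (GO biological-process terms, KEGG or
#' Reactome pathways, or synthetic equivalents), as read from a GMT file.
#' The gene universe is the union of all member sets.
#'
#' @slot sets named list of character gene-id vectors (all non-empty).
#' @slot labels named character vector of human-readable labels.
#' @aliases funsysSets funsysLabels geneUniverse
#' @export FunSysCollection
#' @exportClass FunSysCollection
setClass("FunSysCollection",
         slots = c(sets = "list", labels = "character"))

setValidity("FunSysCollection", function(object) {
  msg <- character()
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "functional-system ids must be unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "every gene set must be non-empty")
  if (!identical(names(object@labels), names(object@sets)))
    msg <- c(msg, "labels must be named by set id, in order")
  if (length(msg)) msg else TRUE
})

FunSysCollection <- function(sets, labels = NULL) {
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  sets <- sets[order(names(sets))]
  if (is.null(labels)) labels <- setNames(names(sets), names(sets))
  labels <- labels[names(sets)]
  names(labels) <- names(sets)
  new("FunSysCollection", sets = sets, labels = labels)
}

#' Disease-to-phenotype annotations
#'
#' Maps disease ids to the phenotype terms annotated to them (as in the HPO
#' annotation releases for OMIM/Orphanet). Phenotype ids are resolved through
#' the ontology alt-id map at load time.
#'
#' @slot annotations named list: disease id -> character phenotype-term ids.
#' @slot source free-text label of the annotation source.
#' @aliases diseasePhenotypes
#' @export DiseaseAnnotations
#' @exportClass DiseaseAnnotations
setClass("DiseaseAnnotations",
         slots = c(annotations = "list", source = "character"))

DiseaseAnnotations <- function(annotations, source = "disease_db") {
  annotations <- lapply(annotations, function(p) sort(unique(as.character(p))))
  if (length(annotations))
    annotations <- annotations[order(names(annotations))]
  new("DiseaseAnnotations", annotations = annotations, source = source)
}

#' Literature co-mention corpus
#'
#' Precomputed term-to-abstract-id index (phenotype terms and gene symbols in
#' one namespace) standing in for live literature queries. The universe size
#' is the number of distinct abstract ids anywhere in the corpus and is the
#' population size of the co-mention Fisher tests.
#'
#' @slot index named list: term id -> character abstract ids.
#' @slot universeSize integer count of distinct abstract ids.
#' @aliases corpusIndex corpusUniverseSize
#' @export LiteratureCorpus
#' @exportClass LiteratureCorpus
setClass("LiteratureCorpus",
         slots = c(index = "list", universeSize = "integer"))

setValidity("LiteratureCorpus", function(object) {
  if (any(lengths(object@index) > object@universeSize))
    "universe size must be >= every per-term abstract count" else TRUE
})

LiteratureCorpus <- function(index, universeSize = NULL) {
  index <- lapply(index, function(a) sort(unique(as.character(a))))
  index <- index[order(names(index))]
  if (is.null(universeSize))
    universeSize <- length(unique(unlist(index, use.names = FALSE)))
  new("LiteratureCorpus", index = index, universeSize = as.integer(universeSize))
}

#' Workflow configuration
#'
#' Bundles the tunable parameters of the pipeline. Defaults are the study
#' conditions: index threshold 2 (tail probability 0.01), enrichment alpha
#' 0.05 (BH-adjusted), coherence threshold 0.70, 50 sampling/randomisation
#' replicates, 100 SOR gene-content randomisations, disease-overlap
#' thresholds 1/2/3 diseases, and one allowed missing phenotype for
#' cluster-disease overlap.
#'
#' @slot indexThreshold hypergeometric-index cut for more-specific pairs and
#'   for phenotype-SOR associations.
#' @slot enrichmentAlpha BH-adjusted significance level for ORA.
#' @slot coherenceTheta minimum fraction of cluster phenotypes sharing a
#'   functional system for the cluster to count as coherent.
#' @slot replicates number of sampled/randomised pair-list replicates.
#' @slot sorRandomizationReps number of SOR gene-content randomisations.
#' @slot pairDiseaseThresholds disease-count thresholds for pair overlap.
#' @slot clusterAllowedMissing phenotypes a disease may miss and still
#'   overlap a cluster.
#' @slot seed root random seed for the run.
#'
#' @param indexThreshold,enrichmentAlpha,coherenceTheta,replicates see slots.
#' @param sorRandomizationReps,pairDiseaseThresholds see slots.
#' @param clusterAllowedMissing,seed see slots.
#' @return `pipelineConfig()` returns a validated `PipelineConfig`.
#' @export pipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
         slots = c(indexThreshold = "numeric", enrichmentAlpha = "numeric",
                   coherenceTheta = "numeric", replicates = "integer",
                   sorRandomizationReps = "integer",
                   pairDiseaseThresholds = "integer",
                   clusterAllowedMissing = "integer", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@indexThreshold < 0) msg <- c(msg, "indexThreshold must be >= 0")
  if (object@coherenceTheta <= 0 || object@coherenceTheta > 1)
    msg <- c(msg, "coherenceTheta must be in (0, 1]")
  if (object@enrichmentAlpha <= 0 || object@enrichmentAlpha >= 1)
    msg <- c(msg, "enrichmentAlpha must be in (0, 1)")
  counts <- c(object@replicates, object@sorRandomizationReps,
              object@pairDiseaseThresholds)
  if (any(counts < 1L)) msg <- c(msg, "counts must be positive")
  if (object@clusterAllowedMissing < 0L)
    msg <- c(msg, "clusterAllowedMissing must be >= 0")
  if (length(msg)) msg else TRUE
})

pipelineConfig <- function(indexThreshold = 2, enrichmentAlpha = 0.05,
                           coherenceTheta = 0.70, replicates = 50L,
                           sorRandomizationReps = 100L,
                           pairDiseaseThresholds = c(1L, 2L, 3L),
                           clusterAllowedMissing = 1L, seed = 1L) {
  new("PipelineConfig", indexThreshold = indexThreshold,
      enrichmentAlpha = enrichmentAlpha, coherenceTheta = coherenceTheta,
      replicates = as.integer(replicates),
      sorRandomizationReps = as.integer(sorRandomizationReps),
      pairDiseaseThresholds = as.integer(pairDiseaseThresholds),
      clusterAllowedMissing = as.integer(clusterAllowedMissing),
      seed = as.integer(seed))
}

#' Link-community solution
#'
#' Result of clustering the edges of a phenotype pair network: the edge list,
#' the community membership of every edge at the partition-density-optimal
#' dendrogram cut, and the density profile over candidate cut heights.
#' Edge communities partition the edge set; node memberships may overlap.
#'
#' @slot edges two-column character matrix of edges (canonical order).
#' @slot membership integer community id per edge at the chosen cut.
#' @slot M total edge count.
#' @slot D partition density at the chosen cut.
#' @slot cutHeight chosen dendrogram height.
#' @slot heights,densities candidate cut heights and their densities.
#' @aliases communities partitionDensity communityNodeSets
#' @exportClass LinkCommunitySolution
setClass("LinkCommunitySolution",
         slots = c(edges = "matrix", membership = "integer", M = "integer",
                   D = "numeric", cutHeight = "numeric",
                   heights = "numeric", densities = "numeric"))

setValidity("LinkCommunitySolution", function(object) {
  msg <- character()
  if (nrow(object@edges) != length(object@membership))
    msg <- c(msg, "one membership per edge required")
  if (object@M != nrow(object@edges))
    msg <- c(msg, "M must equal the edge count")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort scenario configuration
#'
#' Describes a simulated patient cohort with planted comorbidity/genotype
#' modules. Each module is a set of phenotypes made comorbid through a group
#' of carrier patients sharing a common CNV locus, plus per-phenotype carrier
#' groups whose CNVs cover phenotype-specific gene slices of one planted
#' functional system; the common locus carries background genes split across
#' housekeeping-style gene sets. See [simConfig()] for the scenario defaults
#' and [generateCohort()] for the generative procedure.
#'
#' @slot nPatients cohort size.
#' @slot nPhenotypes number of background (non-general) phenotype terms.
#' @slot modules list of per-module layouts (built by [simConfig()]).
#' @slot backgroundRate per-(patient, phenotype) background assignment rate.
#' @slot generalPhenotypes number of high-prevalence general terms.
#' @slot generalPrevalence their per-patient rate.
#' @slot noiseCnvRate probability a non-carrier patient gets a random CNV.
#' @slot noiseCnvLength length (bp) of noise CNVs.
#' @slot jitter maximum breakpoint jitter (bp) for carrier CNVs.
#' @slot chromLengths named chromosome lengths.
#' @slot decoySets,decoySetSize decoy functional systems (count and size).
#' @slot seed default seed used when none is passed to [generateCohort()].
#' @exportClass SimConfig
setClass("SimConfig",
         slots = c(nPatients = "integer", nPhenotypes = "integer",
                   modules = "list", backgroundRate = "numeric",
                   generalPhenotypes = "integer", generalPrevalence = "numeric",
                   noiseCnvRate = "numeric", noiseCnvLength = "integer",
                   jitter = "integer", chromLengths = "integer",
                   decoySets = "integer", decoySetSize = "integer",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  for (m in object@modules) {
    if (m$carrierCount + length(m$phenotypes) * m$perPhenotypeCarriers >
        object@nPatients)
      msg <- c(msg, "module carriers exceed the cohort size")
    if (m$penetrance <= 0 || m$penetrance > 1)
      msg <- c(msg, "penetrance must be in (0, 1]")
    lim <- object@chromLengths[[m$chrom]]
    loci <- rbind(m$commonLocus, do.call(rbind, m$subLoci))
    if (any(loci < 0) || any(loci > lim))
      msg <- c(msg, sprintf("module locus outside chromosome %s", m$chrom))
  }
  if (object@backgroundRate < 0 || object@backgroundRate > 1)
    msg <- c(msg, "backgroundRate must be a probability")
  if (length(msg)) unique(msg) else TRUE
})
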