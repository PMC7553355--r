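## Accessors and show methods.

#' @rdname PatientCohort-class
setMethod("nPatients", "PatientCohort", function(x) length(x@ids))

#' @rdname PatientCohort-class
setMethod("patientIds", "PatientCohort", function(x) x@ids)

#' @rdname PatientCohort-class
setMethod("phenotypeSets", "PatientCohort", function(x) x@phenotypes)

#' @rdname PatientCohort-class
setMethod("cnvRanges", "PatientCohort", function(x) x@cnvs)

#' @rdname PatientCohort-class
setMethod("phenotypeUniverse", "PatientCohort", function(x)
  sort(unique(unlist(x@phenotypes, use.names = FALSE))))

setMethod("show", "PatientCohort", function(object) {
  nCnv <- sum(vapply(object@cnvs, length, integer(1)))
  cat("PatientCohort with", length(object@ids), "patients,",
      length(phenotypeUniverse(object)), "distinct phenotype terms,",
      nCnv, "CNV intervals\n")
})

#' @rdname PhenOntology-class
setMethod("ontologyTerms", "PhenOntology", function(x) x@terms)

#' @rdname PhenOntology-class
setMethod("termAncestors", "PhenOntology", function(x, terms) {
  if (length(terms) == 1L) return(x@ancestors[[terms]])
  x@ancestors[terms]
})

#' @rdname PhenOntology-class
setMethod("termParents", "PhenOntology", function(x, terms) {
  if (length(terms) == 1L) return(x@parents[[terms]])
  x@parents[terms]
})

#' @rdname PhenOntology-class
setMethod("altIdMap", "PhenOntology", function(x) x@altIds)

setMethod("show", "PhenOntology", function(object) {
  cat("PhenOntology with", length(object@terms), "terms,",
      length(object@altIds), "alt ids,",
      length(object@obsolete), "obsolete\n")
})

#' @rdname FunSysCollection-class
setMethod("funsysSets", "FunSysCollection", function(x) x@sets)

#' @rdname FunSysCollection-class
setMethod("funsysLabels", "FunSysCollection", function(x) x@labels)

#' @rdname FunSysCollection-class
setMethod("geneUniverse", "FunSysCollection", function(x)
  sort(unique(unlist(x@sets, use.names = FALSE))))

setMethod("show", "FunSysCollection", function(object) {
  cat("FunSysCollection with", length(object@sets), "gene sets over",
      length(geneUniverse(object)), "genes\n")
})

#' @rdname DiseaseAnnotations-class
setMethod("diseasePhenotypes", "DiseaseAnnotations", function(x) x@annotations)

setMethod("show", "DiseaseAnnotations", function(object) {
  cat("DiseaseAnnotations (", object@source, "): ",
      length(object@annotations), " diseases\n", sep = "")
})

#' @rdname LiteratureCorpus-class
setMethod("corpusIndex", "LiteratureCorpus", function(x) x@index)

#' @rdname LiteratureCorpus-class
setMethod("corpusUniverseSize", "LiteratureCorpus", function(x) x@universeSize)

setMethod("show", "LiteratureCorpus", function(object) {
  cat("LiteratureCorpus:", length(object@index), "terms over",
      object@universeSize, "abstracts\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: index threshold", object@indexThreshold,
      "| alpha", object@enrichmentAlpha,
      "| coherence", object@coherenceTheta,
      "| replicates", object@replicates,
      "| SOR randomisations", object@sorRandomizationReps,
      "| seed", object@seed, "\n")
})

#' @rdname LinkCommunitySolution-class
setMethod("communities", "LinkCommunitySolution", function(x)
  split(seq_len(nrow(x@edges)), x@membership))

#' @rdname LinkCommunitySolution-class
setMethod("partitionDensity", "LinkCommunitySolution", function(x) x@D)

#' @rdname LinkCommunitySolution-class
setMethod("communityNodeSets", "LinkCommunitySolution",
          function(x, dropTrivial = FALSE) {
  comm <- communities(x)
  sets <- lapply(comm, function(idx)
    sort(unique(as.vector(x@edges[idx, , drop = FALSE]))))
  if (dropTrivial) sets <- sets[vapply(comm, length, integer(1)) > 1L]
  sets
})

setMethod("show", "LinkCommunitySolution", function(object) {
  k <- length(unique(object@membership))
  cat("LinkCommunitySolution:", object@M, "edges in", k,
      "communities | partition density", round(object@D, 4),
      "at cut height", round(object@cutHeight, 4), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPatients, "patients,",
      object@nPhenotypes, "background phenotypes,",
      length(object@modules), "planted modules,",
      object@decoySets, "decoy gene sets\n")
})
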