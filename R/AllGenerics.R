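#' @import methods
NULL

#' @rdname PatientCohort-class
#' @param x a `PatientCohort`.
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname PatientCohort-class
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname PatientCohort-class
#' @export
setGeneric("phenotypeSets", function(x) standardGeneric("phenotypeSets"))

#' @rdname PatientCohort-class
#' @export
setGeneric("cnvRanges", function(x) standardGeneric("cnvRanges"))

#' @rdname PatientCohort-class
#' @export
setGeneric("phenotypeUniverse", function(x) standardGeneric("phenotypeUniverse"))

#' @rdname PhenOntology-class
#' @param x object.
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname PhenOntology-class
#' @param terms character vector of term ids.
#' @export
setGeneric("termAncestors", function(x, terms) standardGeneric("termAncestors"))

#' @rdname PhenOntology-class
#' @export
setGeneric("termParents", function(x, terms) standardGeneric("termParents"))

#' @rdname PhenOntology-class
#' @export
setGeneric("altIdMap", function(x) standardGeneric("altIdMap"))

#' @rdname FunSysCollection-class
#' @param x object.
#' @export
setGeneric("funsysSets", function(x) standardGeneric("funsysSets"))

#' @rdname FunSysCollection-class
#' @export
setGeneric("funsysLabels", function(x) standardGeneric("funsysLabels"))

#' @rdname FunSysCollection-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname DiseaseAnnotations-class
#' @param x object.
#' @export
setGeneric("diseasePhenotypes", function(x) standardGeneric("diseasePhenotypes"))

#' @rdname LiteratureCorpus-class
#' @param x object.
#' @export
setGeneric("corpusIndex", function(x) standardGeneric("corpusIndex"))

#' @rdname LiteratureCorpus-class
#' @export
setGeneric("corpusUniverseSize", function(x) standardGeneric("corpusUniverseSize"))

#' @rdname LinkCommunitySolution-class
#' @param x a `LinkCommunitySolution`.
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' @rdname LinkCommunitySolution-class
#' @export
setGeneric("partitionDensity", function(x) standardGeneric("partitionDensity"))

#' @rdname LinkCommunitySolution-class
#' @param dropTrivial drop single-edge communities.
#' @export
setGeneric("communityNodeSets", function(x, dropTrivial = FALSE)
  standardGeneric("communityNodeSets"))
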