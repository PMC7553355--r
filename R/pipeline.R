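## End-to-end orchestration: pairs -> sor -> enrich -> cluster -> validate ->
## report, with all randomness flowing from the configuration seed.

.stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  .msg("stage ", name, " done in ",
       sprintf("%.1fs", proc.time()[["elapsed"]] - t0))
  manifest$stages[[name]] <- list(
    name = name, seconds = proc.time()[["elapsed"]] - t0)
  list(manifest = manifest, value = res)
}

## Cluster a labelled pair list: unique labelled edges -> link communities ->
## coherence (+ optional disease overlap). Returns an empty summary for
## graphs with fewer than 2 edges.
.clusterLabelled <- function(labelled, config, diseases = NULL) {
  empty <- list(solution = NULL,
                clusters = data.frame(cluster_id = character(),
                                      n_nodes = integer(),
                                      n_edges = integer(),
                                      trivial = logical(),
                                      coherent = logical()),
                diseaseOverlap = list())
  edges <- unique(labelled$labels[c("term_a", "term_b")])
  if (nrow(edges) < 2L) return(empty)
  sol <- linkCommunities(edges)
  cl <- coherentClusters(sol, labelled$phenotypeEnrichment, labelled$labels,
                         theta = config@coherenceTheta)
  dis <- list()
  if (!is.null(diseases) && nrow(cl)) {
    dis <- lapply(cl$phenotypes, clusterDiseaseOverlap, diseases = diseases,
                  allowedMissing = config@clusterAllowedMissing)
    names(dis) <- cl$cluster_id
  }
  cl$disease_overlap <- if (length(dis))
    vapply(dis, nrow, integer(1)) > 0L else FALSE
  list(solution = sol, clusters = cl, diseaseOverlap = dis)
}

.clusterCounts <- function(clusterTable) {
  keep <- !clusterTable$trivial
  c(total = sum(keep),
    coherent = sum(keep & clusterTable$coherent),
    disease = sum(keep & clusterTable$disease_overlap),
    both = sum(keep & clusterTable$coherent & clusterTable$disease_overlap))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the [pipelineConfig()] arguments
#' (`indexThreshold`, `enrichmentAlpha`, `coherenceTheta`, `replicates`,
#' `sorRandomizationReps`, `pairDiseaseThresholds`, `clusterAllowedMissing`,
#' `seed`); absent keys take the defaults. CLI flags override file values.
#'
#' @param path YAML file path.
#' @param overrides named list of values taking precedence over the file.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' Run the comorbidity workflow end to end
#'
#' Executes the full analysis on a cohort: (1) pair network construction,
#' specificity split, sampled less-specific/unconnected replicates and
#' links/nodes random models; (2) SOR decomposition and phenotype-gene
#' mapping; (3) over-representation, consistent/emergent labelling of the
#' more- and less-specific lists and of the links-random replicates, plus the
#' SOR gene-content randomisation; (4) link-community clustering with
#' coherence and disease-overlap filters for the real lists and the
#' links-random replicates; (5) validation statistics (disease overlap at the
#' configured thresholds, literature co-mention, semantic similarity, patient
#' cluster support); (6) optional report writing. Any stage failure aborts
#' with the stage name. Reruns with identical inputs and configuration give
#' identical outputs.
#'
#' @param cohort a [PatientCohort-class].
#' @param geneModels `GRanges` gene models.
#' @param funsys a [FunSysCollection-class].
#' @param config a [pipelineConfig()].
#' @param ontology optional [PhenOntology-class] (needed for semantic
#'   similarity).
#' @param diseases optional [DiseaseAnnotations-class].
#' @param corpus optional [LiteratureCorpus-class].
#' @param outDir optional directory for [writeReports()].
#' @return list of stage results (see elements `pairTable`, `moreSpecific`,
#'   `lessSpecific`, `sors`, `map`, `labels`, `phenotypeEnrichment`,
#'   `clusters`, `validation`, `randomModels`, `sorRandomization`,
#'   `manifest`).
#' @export
runPipeline <- function(cohort, geneModels, funsys,
                        config = pipelineConfig(), ontology = NULL,
                        diseases = NULL, corpus = NULL, outDir = NULL) {
  manifest <- list(version = as.character(utils::packageVersion("comorbidNet")),
                   configHash = .configHash(config), seed = config@seed,
                   stages = list())
  seed <- config@seed
  R <- config@replicates

  st <- .stage(manifest, "pairs", {
    pairTable <- buildPairTable(cohort)
    split <- splitPairs(pairTable, config@indexThreshold)
    unconnected <- unconnectedUniverse(cohort, pairTable)
    size <- nrow(split$more_specific)
    lessSamples <- if (size > 0L && nrow(split$less_specific) > 0L)
      samplePairs(split$less_specific, min(size, nrow(split$less_specific)),
                  R, .childSeed(seed, 11L)) else list()
    unconnSamples <- if (size > 0L && nrow(unconnected) > 0L)
      samplePairs(unconnected, min(size, nrow(unconnected)),
                  R, .childSeed(seed, 12L)) else list()
    rnd <- function(pairs, base)
      lapply(seq_len(R), function(r)
        randomizeLinks(pairs, .childSeed(seed, base + r)))
    rndN <- function(pairs, base)
      lapply(seq_len(R), function(r)
        randomizeNodes(pairs, .childSeed(seed, base + r)))
    list(pairTable = pairTable, moreSpecific = split$more_specific,
         lessSpecific = split$less_specific, unconnected = unconnected,
         lessSamples = lessSamples, unconnSamples = unconnSamples,
         linksRandomMore = if (size >= 2L)
           rnd(split$more_specific, 1000L) else list(),
         linksRandomLess = if (nrow(split$less_specific) >= 2L)
           rnd(split$less_specific, 2000L) else list(),
         nodesRandomMore = if (size >= 1L)
           rndN(split$more_specific, 3000L) else list(),
         nodesRandomLess = if (nrow(split$less_specific) >= 1L)
           rndN(split$less_specific, 4000L) else list())
  })
  manifest <- st$manifest; pairs <- st$value

  st <- .stage(manifest, "sor", {
    sors <- decomposeToSors(cohort)
    sors <- addSorGenes(sors, geneModels)
    assoc <- associatePhenotypesToSors(cohort, sors,
                                       config@indexThreshold)
    map <- mapSorsToGenes(assoc, sors)
    list(sors = sors, assoc = assoc, map = map)
  })
  manifest <- st$manifest; sor <- st$value

  st <- .stage(manifest, "enrich", {
    alpha <- config@enrichmentAlpha
    labMore <- labelPairs(pairs$moreSpecific, sor$map, funsys, alpha = alpha)
    labLess <- labelPairs(pairs$lessSpecific, sor$map, funsys, alpha = alpha)
    labLinksMore <- lapply(pairs$linksRandomMore, labelPairs, map = sor$map,
                           collection = funsys, alpha = alpha)
    labLinksLess <- lapply(pairs$linksRandomLess, labelPairs, map = sor$map,
                           collection = funsys, alpha = alpha)
    ## SOR gene-content randomisation: association-count null
    realAssoc <- sum(labMore$phenotypeEnrichment$significant)
    realPheno <- length(unique(
      labMore$phenotypeEnrichment$subject[
        labMore$phenotypeEnrichment$significant]))
    nullAssoc <- vapply(seq_len(config@sorRandomizationReps), function(r) {
      rmap <- randomizeSorGenes(sor$sors, sor$assoc,
                                seed = .childSeed(seed, 5000L + r))
      enr <- lapply(names(rmap), function(ph)
        overrepresentation(rmap[[ph]], funsys, alpha = alpha, subject = ph))
      enr <- do.call(rbind, enr)
      c(assoc = if (is.null(enr)) 0L else sum(enr$significant),
        pheno = if (is.null(enr)) 0L else
          length(unique(enr$subject[enr$significant])))
    }, numeric(2))
    list(more = labMore, less = labLess, linksMore = labLinksMore,
         linksLess = labLinksLess,
         sorRandomization = list(
           realAssociations = realAssoc, realPhenotypes = realPheno,
           nullAssociations = nullAssoc["assoc", ],
           nullPhenotypes = nullAssoc["pheno", ]))
  })
  manifest <- st$manifest; enr <- st$value

  st <- .stage(manifest, "cluster", {
    clMore <- .clusterLabelled(enr$more, config, diseases)
    clLess <- .clusterLabelled(enr$less, config, diseases)
    cnt <- function(labs) vapply(labs, function(l)
      .clusterCounts(.clusterLabelled(l, config, diseases)$clusters),
      numeric(4))
    linksMoreCounts <- if (length(enr$linksMore)) cnt(enr$linksMore) else NULL
    linksLessCounts <- if (length(enr$linksLess)) cnt(enr$linksLess) else NULL
    list(more = clMore, less = clLess,
         linksMoreCounts = linksMoreCounts,
         linksLessCounts = linksLessCounts)
  })
  manifest <- st$manifest; clu <- st$value

  st <- .stage(manifest, "validate", {
    val <- list()
    if (!is.null(diseases)) {
      ## per-pair disease counts once per dataset; thresholds applied after
      fixedCounts <- list(
        more_specific = pairDiseaseCounts(pairs$moreSpecific, diseases),
        less_specific = pairDiseaseCounts(pairs$lessSpecific, diseases))
      repCounts <- lapply(
        list(less_sampled = pairs$lessSamples,
             unconnected_sampled = pairs$unconnSamples,
             links_random_more = pairs$linksRandomMore,
             links_random_less = pairs$linksRandomLess,
             nodes_random_more = pairs$nodesRandomMore,
             nodes_random_less = pairs$nodesRandomLess),
        function(lst) lapply(lst, pairDiseaseCounts, diseases = diseases))
      overlap <- lapply(config@pairDiseaseThresholds, function(thr) {
        fixed <- vapply(fixedCounts, function(cnt) sum(cnt >= thr),
                        numeric(1))
        reps <- vapply(repCounts, function(lst) if (length(lst))
          mean(vapply(lst, function(cnt) sum(cnt >= thr), numeric(1)))
          else NA_real_, numeric(1))
        c(fixed, reps)
      })
      names(overlap) <- paste0("min", config@pairDiseaseThresholds)
      val$pairDiseaseOverlap <- overlap
    }
    if (!is.null(corpus)) {
      pvec <- function(df) vapply(seq_len(nrow(df)), function(i)
        comentionTest(corpus, df$term_a[i], df$term_b[i])$p, numeric(1))
      val$comention <- list(
        more_specific = if (nrow(pairs$moreSpecific))
          pvec(pairs$moreSpecific) else numeric(),
        links_random_more = if (length(pairs$linksRandomMore))
          pvec(pairs$linksRandomMore[[1]]) else numeric())
      val$geneComention <- geneComentionCount(
        corpus, sor$map, nRandomizations = config@sorRandomizationReps,
        seed = .childSeed(seed, 21L))
    }
    nodeSets <- clu$more$clusters
    bigClusters <- if (nrow(nodeSets))
      nodeSets$phenotypes[!nodeSets$trivial & nodeSets$coherent &
                            lengths(nodeSets$phenotypes) >= 2L] else list()
    if (!is.null(ontology) && !is.null(diseases) && length(bigClusters)) {
       icTable <- buildInformationContent(ontology, diseases)
      val$semantic <- clusterSemanticScore(
        bigClusters, ontology, icTable, nRandomizations = 1000L,
        seed = .childSeed(seed, 22L))
    }
    if (length(bigClusters)) {
      val$patientSupport <- patientClusterSupport(
        cohort, bigClusters, nRandomizations = config@sorRandomizationReps,
        seed = .childSeed(seed, 23L))
      val$membership <- clusterMembershipSummary(cohort, bigClusters)
    }
    val
  })
  manifest <- st$manifest; val <- st$value

  results <- list(
    pairTable = pairs$pairTable, moreSpecific = pairs$moreSpecific,
    lessSpecific = pairs$lessSpecific, unconnected = pairs$unconnected,
    randomModels = pairs[c("lessSamples", "unconnSamples", "linksRandomMore",
                           "linksRandomLess", "nodesRandomMore",
                           "nodesRandomLess")],
    sors = sor$sors, sorAssociations = sor$assoc, map = sor$map,
    labels = enr$more$labels,
    labelsLess = enr$less$labels,
    phenotypeEnrichment = enr$more$phenotypeEnrichment,
    sorRandomization = enr$sorRandomization,
    clusterSolution = clu$more$solution,
    clusters = clu$more$clusters,
    clusterDiseases = clu$more$diseaseOverlap,
    clustersLess = clu$less$clusters,
    linksRandomClusterCounts = list(more = clu$linksMoreCounts,
                                    less = clu$linksLessCounts),
    validation = val, config = config, cohort = cohort)
  if (!is.null(outDir)) {
    st <- .stage(manifest, "report", writeReports(results, outDir))
    manifest <- st$manifest
    manifest$reports <- st$value
  }
  results$manifest <- manifest
  results
}
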