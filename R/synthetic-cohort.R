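## Synthetic cohort generator with planted comorbidity/genotype modules.
##
## Each planted module emulates the structure the workflow is designed to
## detect: a group of "comorbid carriers" shares a common CNV locus and the
## full module phenotype set, so the phenotypes co-occur strongly; the common
## locus carries background ("housekeeping") genes split across a few large
## gene sets, so every module phenotype maps to the same broad gene context.
## In addition, each module phenotype has a small private carrier group whose
## CNV covers a phenotype-specific slice of the module's planted functional
## system. Phenotypes therefore carry complementary slices of that system:
## no phenotype is individually enriched for it, but the union of a pair's
## genes is, which is exactly the emergent-pair configuration. Background
## phenotype noise, high-prevalence general phenotypes, breakpoint jitter and
## random noise CNVs make every pipeline stage non-trivial.

.moduleLayout <- function(m, size, phenotypes, carrierCount,
                          perPhenotypeCarriers, penetrance,
                          nBackgroundSets = 4L, backgroundSetSize = 25L,
                          genesPerPhenotype = 3L) {
  chrom <- paste0("chr", m)
  nBg <- nBackgroundSets * backgroundSetSize
  bgStarts <- 106000 + (seq_len(nBg) - 1L) * 1800
  subBlock <- function(i) 350000 + (i - 1L) * 30000
  list(
    id = m, chrom = chrom, phenotypes = phenotypes,
    funsysId = sprintf("FS_M%d", m),
    carrierCount = as.integer(carrierCount),
    perPhenotypeCarriers = as.integer(perPhenotypeCarriers),
    penetrance = penetrance,
    kind = if (m %% 2L == 1L) "deletion" else "duplication",
    commonLocus = c(100000, 300000),
    backgroundGenes = data.frame(
      gene = sprintf("BG%d_%03d", m, seq_len(nBg)),
      start = bgStarts, end = bgStarts + 1000,
      set = sprintf("FS_BG%d_%d", m,
                    rep(seq_len(nBackgroundSets), each = backgroundSetSize)),
      stringsAsFactors = FALSE),
    subLoci = lapply(seq_len(size), function(i)
      c(subBlock(i), subBlock(i) + 28000)),
    sliceGenes = lapply(seq_len(size), function(i) data.frame(
      gene = sprintf("MG%d_%d_%d", m, i, seq_len(genesPerPhenotype)),
      start = subBlock(i) + 10000 + (seq_len(genesPerPhenotype) - 1L) * 4000,
      end = subBlock(i) + 11000 + (seq_len(genesPerPhenotype) - 1L) * 4000,
      stringsAsFactors = FALSE)))
}

#' Configure a synthetic cohort scenario
#'
#' Builds a [SimConfig-class] describing the default study conditions:
#' 500 patients, 200 background phenotype terms, 5 planted modules of 3-5
#' phenotypes each (20 comorbid carriers plus 5 private carriers per module
#' phenotype, penetrance 0.9), background phenotype rate 0.02, 5
#' high-prevalence general phenotypes (rate 0.3), noise CNVs on 20% of
#' non-carrier patients, breakpoint jitter of 3 kb, and 50 decoy gene sets.
#' Each module occupies its own chromosome: a 200 kb common locus with 100
#' background genes in 4 gene sets of 25, and one 28 kb sub-locus per
#' phenotype carrying 3 genes of the module's planted functional system.
#'
#' @param nPatients cohort size.
#' @param nPhenotypes background phenotype terms.
#' @param nModules planted modules.
#' @param moduleSizes phenotypes per module (recycled over modules).
#' @param carrierCount comorbid carriers per module.
#' @param perPhenotypeCarriers private carriers per module phenotype.
#' @param penetrance probability a carrier expresses a module phenotype.
#' @param backgroundRate per-(patient, phenotype) background rate.
#' @param generalPhenotypes,generalPrevalence the high-prevalence layer.
#' @param noiseCnvRate,noiseCnvLength random CNVs on non-carriers.
#' @param jitter carrier CNV breakpoint jitter (bp).
#' @param decoySets,decoySetSize decoy functional systems.
#' @param seed default generation seed.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(nPatients = 500L, nPhenotypes = 200L, nModules = 5L,
                      moduleSizes = c(3L, 4L, 5L), carrierCount = 20L,
                      perPhenotypeCarriers = 5L, penetrance = 0.9,
                      backgroundRate = 0.02, generalPhenotypes = 5L,
                      generalPrevalence = 0.3, noiseCnvRate = 0.2,
                      noiseCnvLength = 40000L, jitter = 3000L,
                      decoySets = 50L, decoySetSize = 5L, seed = 1L) {
  sizes <- rep_len(as.integer(moduleSizes), nModules)
  allTerms <- sprintf("HP:S%04d", seq_len(nPhenotypes))
  offsets <- c(0L, cumsum(sizes))
  modules <- lapply(seq_len(nModules), function(m)
    .moduleLayout(m, sizes[m],
                  allTerms[(offsets[m] + 1L):offsets[m + 1L]],
                  carrierCount, perPhenotypeCarriers, penetrance))
  chromLengths <- setNames(rep(2000000L, nModules),
                           paste0("chr", seq_len(nModules)))
  chromLengths["chrD"] <- as.integer(decoySets * decoySetSize * 2000 + 200000)
  new("SimConfig", nPatients = as.integer(nPatients),
      nPhenotypes = as.integer(nPhenotypes), modules = modules,
      backgroundRate = backgroundRate,
      generalPhenotypes = as.integer(generalPhenotypes),
      generalPrevalence = generalPrevalence,
      noiseCnvRate = noiseCnvRate,
      noiseCnvLength = as.integer(noiseCnvLength),
      jitter = as.integer(jitter), chromLengths = chromLengths,
      decoySets = as.integer(decoySets),
      decoySetSize = as.integer(decoySetSize), seed = as.integer(seed))
}

.backgroundTerms <- function(config) sprintf("HP:S%04d", seq_len(config@nPhenotypes))
.generalTerms <- function(config)
  if (config@generalPhenotypes > 0L)
    sprintf("HP:G%03d", seq_len(config@generalPhenotypes)) else character()
.decoyGeneTable <- function(config) {
  n <- config@decoySets * config@decoySetSize
  starts <- 10000 + (seq_len(n) - 1L) * 2000
  data.frame(gene = sprintf("DG%03d", seq_len(n)),
             start = starts, end = starts + 1000,
             set = sprintf("FS_D%03d",
                           rep(seq_len(config@decoySets),
                               each = config@decoySetSize)),
             stringsAsFactors = FALSE)
}

.syntheticGeneModels <- function(config) {
  tabs <- lapply(config@modules, function(mod) {
    slices <- do.call(rbind, mod$sliceGenes)
    rbind(data.frame(chrom = mod$chrom,
                     mod$backgroundGenes[c("gene", "start", "end")]),
          data.frame(chrom = mod$chrom, slices))
  })
  dec <- .decoyGeneTable(config)
  tab <- rbind(do.call(rbind, tabs),
               data.frame(chrom = "chrD", dec[c("gene", "start", "end")]))
  gr <- GRanges(tab$chrom, IRanges(tab$start + 1, tab$end))
  names(gr) <- tab$gene
  gr$name <- tab$gene
  sort(gr)
}

.syntheticFunsys <- function(config) {
  sets <- list()
  for (mod in config@modules) {
    sets[[mod$funsysId]] <-
      unlist(lapply(mod$sliceGenes, `[[`, "gene"), use.names = FALSE)
    bgSplit <- split(mod$backgroundGenes$gene, mod$backgroundGenes$set)
    sets[names(bgSplit)] <- bgSplit
  }
  dec <- .decoyGeneTable(config)
  decSplit <- split(dec$gene, dec$set)
  sets[names(decSplit)] <- decSplit
  FunSysCollection(sets)
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a cohort under a [simConfig()] scenario: comorbid carrier groups
#' receive the module's common-locus CNV (breakpoints jittered) and each
#' module phenotype with the configured penetrance; private carrier groups
#' receive their phenotype's sub-locus CNV and that phenotype; non-carriers
#' receive random noise CNVs at the configured rate; every patient receives
#' background phenotypes at the background rate and general phenotypes at
#' their prevalence (a patient left without phenotypes gets one background
#' term so cohort invariants hold). Gene models and the functional-system
#' collection (planted + background + decoy sets) are deterministic given the
#' configuration.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed (default `config@seed`); the same seed yields a
#'   byte-identical cohort.
#' @return list with `cohort` ([PatientCohort-class]), `geneModels`
#'   (`GRanges`), `funsys` ([FunSysCollection-class]) and `truth` (list:
#'   `pairs` data.frame of planted comorbid pairs, `phenotypeGenes` expected
#'   phenotype-gene map, `clusters` planted phenotype sets, `funsysIds`
#'   planted system per module, `carriers` patient assignment).
#' @export
generateCohort <- function(config, seed = config@seed) {
  validObject(config)
  geneModels <- .syntheticGeneModels(config)
  funsys <- .syntheticFunsys(config)
  nP <- config@nPatients
  ids <- sprintf("PT%04d", seq_len(nP))
  bgTerms <- .backgroundTerms(config)
  genTerms <- .generalTerms(config)
  phen <- vector("list", nP)
  ## CNVs are accumulated as flat vectors and turned into GRanges once
  cnvPatient <- integer(); cnvChrom <- character()
  cnvStart <- numeric(); cnvEnd <- numeric(); cnvKind <- character()
  carriers <- list()
  .withSeed(seed, {
    cursor <- 0L
    take <- function(n) {
      if (cursor + n > nP) stop("infeasible layout: not enough patients")
      out <- (cursor + 1L):(cursor + n)
      cursor <<- cursor + n
      out
    }
    jit <- function(n) sample(-config@jitter:config@jitter, n, replace = TRUE)
    addCnvs <- function(patients, chrom, start0, end0, kind) {
      cnvPatient <<- c(cnvPatient, patients)
      cnvChrom <<- c(cnvChrom, rep(chrom, length(patients)))
      cnvStart <<- c(cnvStart, start0)
      cnvEnd <<- c(cnvEnd, end0)
      cnvKind <<- c(cnvKind, rep(kind, length.out = length(patients)))
    }
    for (mod in config@modules) {
      common <- take(mod$carrierCount)
      carriers[[mod$funsysId]] <- list(common = ids[common], private = list())
      addCnvs(common, mod$chrom,
              mod$commonLocus[1] + jit(length(common)),
              mod$commonLocus[2] + jit(length(common)), mod$kind)
      for (p in common)
        phen[[p]] <- mod$phenotypes[runif(length(mod$phenotypes)) <=
                                      mod$penetrance]
      for (i in seq_along(mod$phenotypes)) {
        grp <- take(mod$perPhenotypeCarriers)
        carriers[[mod$funsysId]]$private[[mod$phenotypes[i]]] <- ids[grp]
        addCnvs(grp, mod$chrom,
                mod$subLoci[[i]][1] + jit(length(grp)),
                mod$subLoci[[i]][2] + jit(length(grp)), mod$kind)
        expressed <- grp[runif(length(grp)) <= mod$penetrance]
        for (p in expressed) phen[[p]] <- mod$phenotypes[i]
      }
    }
    ## noise CNVs on the remaining (non-carrier) patients
    if (cursor < nP) {
      rest <- (cursor + 1L):nP
      noisy <- rest[runif(length(rest)) <= config@noiseCnvRate]
      for (p in noisy) {
        chrom <- sample(names(config@chromLengths), 1L)
        maxStart <- config@chromLengths[[chrom]] - config@noiseCnvLength
        s <- sample.int(maxStart, 1L)
        addCnvs(p, chrom, s, s + config@noiseCnvLength,
                sample(.CNV_KINDS, 1L))
      }
    }
    ## background and general phenotype layers for everyone
    for (p in seq_len(nP)) {
      bg <- bgTerms[runif(length(bgTerms)) <= config@backgroundRate]
      gen <- genTerms[runif(length(genTerms)) <= config@generalPrevalence]
      phen[[p]] <- unique(c(phen[[p]], bg, gen))
      if (!length(phen[[p]]))
        phen[[p]] <- sample(bgTerms, 1L)
    }
  })
  allCnv <- GRanges(cnvChrom, IRanges(cnvStart + 1, cnvEnd), kind = cnvKind)
  cnvs <- rep(list(GRanges(kind = character())), nP)
  for (grp in split(seq_along(cnvPatient), cnvPatient))
    cnvs[[cnvPatient[grp[1]]]] <- allCnv[grp]
  names(phen) <- ids
  names(cnvs) <- ids
  cohort <- PatientCohort(ids, phen, cnvs)
  truth <- .groundTruth(config, carriers)
  list(cohort = cohort, geneModels = geneModels, funsys = funsys,
       truth = truth)
}

.groundTruth <- function(config, carriers) {
  pairRows <- list(); genes <- list(); clusters <- list(); fs <- character()
  for (mod in config@modules) {
    ph <- sort(mod$phenotypes)
    clusters[[mod$funsysId]] <- ph
    fs[mod$funsysId] <- mod$funsysId
    if (length(ph) >= 2L) {
      cmb <- utils::combn(ph, 2L)
      pairRows[[mod$funsysId]] <- data.frame(
        term_a = cmb[1, ], term_b = cmb[2, ], module = mod$funsysId,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(mod$phenotypes))
      genes[[mod$phenotypes[i]]] <-
        sort(c(mod$backgroundGenes$gene, mod$sliceGenes[[i]]$gene))
  }
  list(pairs = do.call(rbind, pairRows),
       phenotypeGenes = genes[order(names(genes))],
       clusters = clusters, funsysIds = fs, carriers = carriers)
}

#' Synthetic ontology matching a scenario
#'
#' A small is-a DAG for the scenario's phenotype terms: one branch term per
#' planted module (its phenotypes underneath), one branch for the general
#' terms, and all background terms directly under the root. Supports the
#' semantic-similarity stages on synthetic data.
#'
#' @param config a [SimConfig-class].
#' @return A [PhenOntology-class].
#' @export
syntheticOntology <- function(config) {
  root <- "HP:ROOT"
  terms <- root; parents <- list(); parents[[root]] <- character()
  addTerm <- function(id, parent) {
    terms <<- c(terms, id)
    parents[[id]] <<- parent
  }
  for (mod in config@modules) {
    br <- sprintf("HP:BRANCH%d", mod$id)
    addTerm(br, root)
    for (ph in mod$phenotypes) addTerm(ph, br)
  }
  gen <- .generalTerms(config)
  if (length(gen)) {
    addTerm("HP:BRANCHG", root)
    for (g in gen) addTerm(g, "HP:BRANCHG")
  }
  planted <- unlist(lapply(config@modules, `[[`, "phenotypes"))
  for (t in setdiff(.backgroundTerms(config), planted)) addTerm(t, root)
  anc <- .ancestorClosure(terms, parents)
  new("PhenOntology", terms = terms,
      termNames = setNames(terms, terms), parents = parents,
      ancestors = anc, altIds = character(), obsolete = character())
}

#' Synthetic disease annotations matching a scenario
#'
#' One disease per planted module annotated with the full module phenotype
#' set, one variant disease per module missing one phenotype and adding a
#' background term, `nRandom` random diseases of `randomSize` background
#' terms each, and coverage diseases chunking the remaining background and
#' general terms so that every term of the scenario is annotated somewhere
#' (and therefore has a defined information content). Provides
#' disease-overlap evidence for planted clusters and the annotation corpus
#' for semantic similarity.
#'
#' @param config a [SimConfig-class].
#' @param nRandom,randomSize random background diseases.
#' @param seed integer seed.
#' @return A [DiseaseAnnotations-class].
#' @export
syntheticDiseases <- function(config, nRandom = 30L, randomSize = 4L,
                              seed = 1L) {
  ann <- list()
  bg <- .backgroundTerms(config)
  .withSeed(seed, {
    for (mod in config@modules) {
      ann[[sprintf("DIS:M%d", mod$id)]] <- mod$phenotypes
      ann[[sprintf("DIS:M%dV", mod$id)]] <-
        c(mod$phenotypes[-1], sample(bg, 1L))
    }
    for (i in seq_len(nRandom))
      ann[[sprintf("DIS:R%03d", i)]] <- sample(bg, randomSize)
    leftovers <- c(bg, .generalTerms(config))
    chunks <- split(leftovers,
                    ceiling(seq_along(leftovers) / max(randomSize, 2L)))
    for (i in seq_along(chunks))
      ann[[sprintf("DIS:C%03d", i)]] <- chunks[[i]]
  })
  DiseaseAnnotations(ann, source = "synthetic")
}

#' Synthetic literature corpus matching a scenario
#'
#' Module phenotypes and module genes share per-module abstract blocks (so
#' planted phenotype pairs and phenotype-gene assignments are co-mentioned);
#' background phenotypes, general phenotypes and decoy genes receive random
#' abstracts from a shared pool.
#'
#' @param config a [SimConfig-class].
#' @param abstractsPerModule shared abstracts per module.
#' @param poolSize random abstract pool size.
#' @param seed integer seed.
#' @return A [LiteratureCorpus-class].
#' @export
syntheticCorpus <- function(config, abstractsPerModule = 20L,
                            poolSize = 500L, seed = 1L) {
  pool <- sprintf("AB_R%04d", seq_len(poolSize))
  idx <- list()
  addRandom <- function(term, n)
    idx[[term]] <<- unique(c(idx[[term]], sample(pool, n)))
  .withSeed(seed, {
    for (mod in config@modules) {
      shared <- sprintf("AB_M%d_%03d", mod$id, seq_len(abstractsPerModule))
      modGenes <- c(mod$backgroundGenes$gene,
                    unlist(lapply(mod$sliceGenes, `[[`, "gene"),
                           use.names = FALSE))
      for (t in c(mod$phenotypes, modGenes)) {
        idx[[t]] <- shared
        addRandom(t, 3L)
      }
    }
    for (t in setdiff(.backgroundTerms(config),
                      unlist(lapply(config@modules, `[[`, "phenotypes"))))
      addRandom(t, 10L)
    for (t in .generalTerms(config)) addRandom(t, 50L)
    for (g in .decoyGeneTable(config)$gene) addRandom(g, 5L)
  })
  LiteratureCorpus(idx)
}

#' Recovery of planted structure from pipeline outputs
#'
#' Set-overlap precision/recall of the planted comorbid pairs (against the
#' more-specific list), phenotype-gene assignments (against the inferred
#' map), and planted clusters (against the coherent non-trivial clusters;
#' a planted cluster counts as recovered when some coherent cluster has
#' exactly its phenotype set), plus the fraction of modules whose planted
#' functional system is labelled emergent for at least one within-module
#' pair. Empty outputs give recall 0 and precision reported as 0 with the
#' `undefined` flag set.
#'
#' @param results pipeline outputs: a list with `moreSpecific` (pair table),
#'   `map` (phenotype-gene map), `labels` (pair labels) and `clusters`
#'   (a [coherentClusters()] table), e.g. as produced by [runPipeline()].
#' @param truth ground truth from [generateCohort()].
#' @return list of per-layer lists with `precision`, `recall`, `undefined`.
#' @export
evaluateRecovery <- function(results, truth) {
  pr <- function(found, wanted) {
    tp <- length(intersect(found, wanted))
    list(precision = if (length(found)) tp / length(found) else 0,
         recall = if (length(wanted)) tp / length(wanted) else NA_real_,
         undefined = length(found) == 0L)
  }
  pairsFound <- if (!is.null(results$moreSpecific) &&
                    nrow(results$moreSpecific))
    .pairKey(results$moreSpecific$term_a, results$moreSpecific$term_b)
  else character()
  pairsWanted <- .pairKey(truth$pairs$term_a, truth$pairs$term_b)
  geneFound <- unlist(lapply(names(results$map %||% list()), function(p)
    paste(p, results$map[[p]])), use.names = FALSE)
  geneWanted <- unlist(lapply(names(truth$phenotypeGenes), function(p)
    paste(p, truth$phenotypeGenes[[p]])), use.names = FALSE)
  foundSets <- list()
  if (!is.null(results$clusters) && nrow(results$clusters)) {
    keep <- results$clusters$coherent & !results$clusters$trivial
    foundSets <- results$clusters$phenotypes[keep]
  }
  ## a planted cluster is recovered when a coherent cluster contains it
  ## (occasional hitchhiker phenotypes that genuinely co-occur with the
  ## module carriers legitimately extend the planted set); a returned
  ## cluster is a true positive when it contains some planted set
  containedIn <- function(w, s) all(w %in% s)
  clusterRecall <- if (length(truth$clusters))
    mean(vapply(truth$clusters, function(w)
      any(vapply(foundSets, containedIn, logical(1), w = w)), logical(1)))
  else NA_real_
  clusterPrecision <- if (length(foundSets))
    mean(vapply(foundSets, function(s)
      any(vapply(truth$clusters, containedIn, logical(1), s = s)),
      logical(1))) else 0
  emergentOk <- vapply(seq_along(truth$clusters), function(m) {
    fsId <- truth$funsysIds[[m]]
    lab <- results$labels
    if (is.null(lab) || !nrow(lab)) return(FALSE)
    hit <- lab$funsys == fsId & lab$status == "emergent" &
      lab$term_a %in% truth$clusters[[m]] &
      lab$term_b %in% truth$clusters[[m]]
    any(hit)
  }, logical(1))
  list(pairs = pr(pairsFound, pairsWanted),
       genes = pr(geneFound, geneWanted),
       clusters = list(precision = clusterPrecision, recall = clusterRecall,
                       undefined = length(foundSets) == 0L),
       emergentModules = mean(emergentOk))
}
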