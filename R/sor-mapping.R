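## Small overlapping regions (SORs): atomic genomic segments obtained by
## breaking every patient CNV at every breakpoint, kept when covered by at
## least two distinct patients. SORs connect phenotypes to genes through the
## patients that carry them.

#' Decompose patient CNVs into small overlapping regions
#'
#' Per chromosome, the union of all CNV breakpoints defines atomic segments
#' (`GenomicRanges::disjoin`); every segment covered by two or more distinct
#' patients becomes a SOR carrying that patient set. Deletions and
#' duplications are pooled; a patient covering a segment with several CNVs
#' counts once. Adjacent segments are kept atomic even when their patient
#' sets coincide. The result is invariant to patient and CNV input order.
#'
#' @param cohort a [PatientCohort-class]; patients without CNVs are skipped.
#' @return `GRanges` of SORs, sorted, with metadata columns `sor_id`,
#'   `patients` (`CharacterList`) and `kinds` (CNV kinds seen among the
#'   covering CNVs). Empty when no segment is shared.
#' @export
decomposeToSors <- function(cohort) {
  cnvs <- cnvRanges(cohort)
  cnvs <- cnvs[vapply(cnvs, length, integer(1)) > 0L]
  empty <- GRanges(sor_id = character(),
                   patients = IRanges::CharacterList(),
                   kinds = IRanges::CharacterList())
  if (length(cnvs) < 2L) return(empty)
  ## per-patient reduction (a patient counts once per base), vectorised over
  ## the whole cohort via GRangesList
  grl <- GenomicRanges::GRangesList(lapply(cnvs, function(g) {
    GenomicRanges::strand(g) <- "*"
    g
  }))
  red <- reduce(grl)
  all <- unlist(red, use.names = TRUE)
  all$patient <- names(all)
  names(all) <- NULL
  ## per-patient reduction drops the kind; keep raw intervals for kind lookup
  raw <- unlist(grl, use.names = FALSE)
  seg <- disjoin(all, ignore.strand = TRUE)
  hits <- findOverlaps(seg, all, ignore.strand = TRUE)
  pat <- split(all$patient[subjectHits(hits)], queryHits(hits))
  nPat <- vapply(pat, function(p) length(unique(p)), integer(1))
  keep <- as.integer(names(pat))[nPat >= 2L]
  if (!length(keep)) return(empty)
  sors <- seg[keep]
  ord <- order(sors)
  sors <- sors[ord]
  patients <- IRanges::CharacterList(
    lapply(pat[as.character(keep)], function(p) sort(unique(p))))[ord]
  kh <- findOverlaps(sors, raw, ignore.strand = TRUE)
  kinds <- IRanges::CharacterList(
    lapply(split(raw$kind[subjectHits(kh)], factor(queryHits(kh),
                                                   levels = seq_along(sors))),
           function(k) sort(unique(k))))
  sors$sor_id <- sprintf("SOR%05d", seq_along(sors))
  sors$patients <- patients
  sors$kinds <- kinds
  names(sors) <- sors$sor_id
  sors
}

#' Associate phenotypes with SORs through shared patients
#'
#' Builds the tripartite SOR-patient-phenotype network as a bipartite network
#' with (SORs + phenotypes) on one layer and patients on the other, and
#' scores every (phenotype, SOR) pair with the hypergeometric index on
#' shared patients; records at or above the threshold are retained.
#'
#' @param cohort a [PatientCohort-class] (N is the full cohort size).
#' @param sors output of [decomposeToSors()].
#' @param threshold minimum index to retain (default 2).
#' @return data.frame with `phenotype`, `sor_id`, `k`, `n_pheno`, `n_sor`,
#'   `N`, `index`.
#' @export
associatePhenotypesToSors <- function(cohort, sors, threshold = 2) {
  if (!length(sors))
    return(data.frame(phenotype = character(), sor_id = character(),
                      k = integer(), n_pheno = integer(), n_sor = integer(),
                      N = integer(), index = numeric()))
  inc <- .phenotypeIncidence(cohort)
  pats <- patientIds(cohort)
  sorPat <- sors$patients
  j <- rep(seq_along(sors), lengths(sorPat))
  i <- match(unlist(sorPat, use.names = FALSE), pats)
  sorInc <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(pats), length(sors)),
                                 dimnames = list(pats, sors$sor_id))
  co <- Matrix::crossprod(inc, sorInc)   # phenotype x SOR shared patients
  idx <- Matrix::which(co > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(phenotype = character(), sor_id = character(),
                      k = integer(), n_pheno = integer(), n_sor = integer(),
                      N = integer(), index = numeric()))
  df <- data.frame(phenotype = rownames(co)[idx[, 1]],
                   sor_id = colnames(co)[idx[, 2]],
                   k = as.integer(co[idx]),
                   n_pheno = as.integer(Matrix::colSums(inc))[idx[, 1]],
                   n_sor = as.integer(Matrix::colSums(sorInc))[idx[, 2]],
                   N = nPatients(cohort), stringsAsFactors = FALSE)
  df$index <- hypergeometricIndex(df$k, df$n_pheno, df$n_sor, df$N)
  df <- df[df$index >= threshold, , drop = FALSE]
  df[order(df$phenotype, df$sor_id), , drop = FALSE]
}

#' Annotate SORs with overlapping genes
#'
#' A gene overlaps a SOR iff their intervals intersect in at least one base
#' on the same chromosome; strand is ignored.
#'
#' @param sors `GRanges` from [decomposeToSors()].
#' @param geneModels `GRanges` of gene models named by gene id
#'   (see [readGeneModels()]).
#' @return `sors` with an added `genes` `CharacterList` column.
#' @export
addSorGenes <- function(sors, geneModels) {
  hits <- findOverlaps(sors, geneModels, ignore.strand = TRUE)
  genes <- split(names(geneModels)[subjectHits(hits)],
                 factor(queryHits(hits), levels = seq_along(sors)))
  sors$genes <- IRanges::CharacterList(lapply(genes, function(g)
    sort(unique(g))))
  sors
}

#' Map phenotype-SOR associations to phenotype-gene assignments
#'
#' Replaces each retained (phenotype, SOR) association by the (phenotype,
#' gene) pairs for the genes overlapping that SOR; a phenotype's gene set is
#' the union over its SORs. SORs overlapping no gene contribute nothing.
#'
#' @param associations data.frame from [associatePhenotypesToSors()].
#' @param sors SORs annotated by [addSorGenes()] (or raw SORs plus
#'   `geneModels`).
#' @param geneModels optional `GRanges`; required when `sors` lacks a `genes`
#'   column.
#' @return named list: phenotype id -> character vector of gene ids, with
#'   attribute `provenance = "real"`. Phenotypes whose SORs carry no genes
#'   are absent.
#' @export
mapSorsToGenes <- function(associations, sors, geneModels = NULL) {
  if (is.null(sors$genes)) {
    if (is.null(geneModels))
      stop("sors carry no gene annotation; supply geneModels")
    sors <- addSorGenes(sors, geneModels)
  }
  geneSets <- setNames(as.list(sors$genes), sors$sor_id)
  .genesFromEdges(associations, geneSets)
}

.genesFromEdges <- function(associations, geneSets) {
  out <- lapply(split(associations$sor_id, associations$phenotype),
                function(sids)
                  sort(unique(unlist(geneSets[sids], use.names = FALSE))))
  out <- out[lengths(out) > 0L]
  out <- out[order(names(out))]
  attr(out, "provenance") <- "real"
  out
}

#' SOR gene-content randomisation
#'
#' Null model for the phenotype-gene map: every SOR keeps its phenotype
#' associations and its gene count, but its gene content is redrawn without
#' replacement (within each SOR) from the pool of genes appearing in any SOR.
#' Repeating this (typically 100 times) yields the null distribution of
#' phenotype/functional-system association counts against which the real map
#' is compared.
#'
#' @param sors gene-annotated SORs ([addSorGenes()]).
#' @param associations data.frame from [associatePhenotypesToSors()].
#' @param seed integer seed for this replicate.
#' @return named list phenotype -> genes, attribute
#'   `provenance = "sor_randomized"`, attribute `seed`.
#' @export
randomizeSorGenes <- function(sors, associations, seed = 1L) {
  if (is.null(sors$genes)) stop("sors must be gene-annotated (addSorGenes)")
  pool <- sort(unique(unlist(sors$genes, use.names = FALSE)))
  sizes <- lengths(sors$genes)
  randomSets <- .withSeed(seed, lapply(sizes, function(s)
    if (s > 0L) sample(pool, s) else character()))
  names(randomSets) <- sors$sor_id
  out <- .genesFromEdges(associations, randomSets)
  attr(out, "provenance") <- "sor_randomized"
  attr(out, "seed") <- seed
  attr(out, "sorGenes") <- randomSets
  out
}
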