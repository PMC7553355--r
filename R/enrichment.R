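## Over-representation analysis of phenotype (and phenotype-pair) gene sets
## against a functional-system collection, and the consistent/emergent
## classification of pair-level results.

#' Over-representation analysis of a gene list
#'
#' For each functional system S, tests the overlap between the query gene
#' list and S against the hypergeometric null: `p_raw = P(X >= |query & S|)`
#' with `X ~ Hypergeometric(|universe|, |S & universe|, |query|)`.
#' Benjamini-Hochberg adjustment is applied across all sets tested for this
#' one subject; sets with zero overlap are omitted. Query genes outside the
#' universe are dropped (count reported via message).
#'
#' @param query character vector of gene ids.
#' @param collection a [FunSysCollection-class].
#' @param universe gene universe; default all genes in the collection.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param subject identifier recorded in the result rows.
#' @return data.frame with columns `subject`, `funsys`, `overlap`,
#'   `query_size`, `set_size`, `universe_size`, `p_raw`, `p_adj`,
#'   `significant`. Zero rows for an empty query.
#' @export
overrepresentation <- function(query, collection,
                               universe = geneUniverse(collection),
                               alpha = 0.05, subject = NA_character_) {
  emptyRes <- data.frame(subject = character(), funsys = character(),
                         overlap = integer(), query_size = integer(),
                         set_size = integer(), universe_size = integer(),
                         p_raw = numeric(), p_adj = numeric(),
                         significant = logical())
  query <- unique(as.character(query))
  dropped <- sum(!(query %in% universe))
  if (dropped > 0L)
    .msg("overrepresentation: dropped ", dropped,
         " query genes outside the universe")
  query <- intersect(query, universe)
  if (!length(query)) {
    .msg("overrepresentation: empty query for subject ", subject)
    return(emptyRes)
  }
  U <- length(universe)
  q <- length(query)
  sets <- funsysSets(collection)
  setInU <- lapply(sets, function(s) intersect(s, universe))
  sSize <- lengths(setInU)
  ov <- vapply(setInU, function(s) length(intersect(query, s)), integer(1))
  keep <- which(ov >= 1L & sSize >= 1L)
  if (!length(keep)) return(emptyRes)
  p <- hyperTailP(ov[keep], sSize[keep], q, U)
  padj <- p.adjust(p, method = "BH")
  data.frame(subject = subject, funsys = names(sets)[keep],
             overlap = ov[keep], query_size = q,
             set_size = unname(sSize[keep]), universe_size = U,
             p_raw = unname(p), p_adj = unname(padj),
             significant = unname(padj < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-set union for a phenotype pair
#'
#' Union of the two phenotypes' assigned gene sets; a phenotype absent from
#' the map contributes the empty set.
#'
#' @param map phenotype-gene map ([mapSorsToGenes()]).
#' @param termA,termB phenotype ids.
#' @return character vector of gene ids.
#' @export
pairGeneUnion <- function(map, termA, termB) {
  sort(unique(c(map[[termA]], map[[termB]])))
}

#' Classify pair-level functional systems as consistent or emergent
#'
#' Given significance-flagged enrichment records for the two phenotypes of a
#' pair and for their gene union, labels each functional system:
#' significant in both phenotypes and in the union -> `consistent`;
#' significant in neither phenotype but in the union -> `emergent`;
#' all other combinations receive no label. A functional system absent from
#' a record set counts as not significant there.
#'
#' @param enrA,enrB,enrUnion data.frames from [overrepresentation()].
#' @param pair identifier recorded in the result (default from subjects).
#' @return data.frame with columns `pair`, `funsys`,
#'   `status` (`"consistent"` or `"emergent"`); statuses are mutually
#'   exclusive per (pair, funsys).
#' @export
classifyPairTerms <- function(enrA, enrB, enrUnion, pair = NULL) {
  if (is.null(pair)) {
    a <- if (nrow(enrA)) enrA$subject[1] else "a"
    b <- if (nrow(enrB)) enrB$subject[1] else "b"
    pair <- .pairKey(a, b)
  }
  sigIn <- function(enr) enr$funsys[enr$significant]
  sa <- sigIn(enrA); sb <- sigIn(enrB); su <- sigIn(enrUnion)
  consistent <- intersect(su, intersect(sa, sb))
  emergent <- setdiff(su, union(sa, sb))
  stopifnot(length(intersect(consistent, emergent)) == 0L)
  out <- data.frame(
    pair = rep(pair, length(consistent) + length(emergent)),
    funsys = c(consistent, emergent),
    status = rep(c("consistent", "emergent"),
                 c(length(consistent), length(emergent))),
    stringsAsFactors = FALSE)
  out[order(out$funsys), , drop = FALSE]
}

#' Enrich and label a list of phenotype pairs
#'
#' Orchestrates [overrepresentation()] and [classifyPairTerms()] over a pair
#' table: each phenotype's gene list is tested once (cached), each pair's
#' gene union is tested, and consistent/emergent labels are collected.
#'
#' @param pairs data.frame with `term_a`, `term_b`.
#' @param map phenotype-gene map.
#' @param collection a [FunSysCollection-class].
#' @param universe gene universe (default: collection genes).
#' @param alpha BH-adjusted significance level.
#' @return list with `labels` (data.frame `pair`, `term_a`, `term_b`,
#'   `funsys`, `status`) and `phenotypeEnrichment` (row-bound per-phenotype
#'   ORA records).
#' @export
labelPairs <- function(pairs, map, collection,
                       universe = geneUniverse(collection), alpha = 0.05) {
  cache <- new.env(parent = emptyenv())       # per-phenotype records
  setCache <- new.env(parent = emptyenv())    # ORA keyed by gene-set content
  oraBySet <- function(genes, subject) {
    key <- paste0("k:", paste(genes, collapse = "\r"))
    if (!exists(key, envir = setCache))
      assign(key, overrepresentation(genes, collection, universe, alpha,
                                     subject = subject), envir = setCache)
    res <- get(key, envir = setCache)
    if (nrow(res)) res$subject <- subject
    res
  }
  phenoEnr <- function(term) {
    if (!exists(term, envir = cache))
      assign(term, oraBySet(map[[term]], term), envir = cache)
    get(term, envir = cache)
  }
  mapped <- names(map)
  ## pairs where neither phenotype is mapped have empty unions: skip early
  candidates <- which(pairs$term_a %in% mapped | pairs$term_b %in% mapped)
  labs <- vector("list", length(candidates))
  for (ci in seq_along(candidates)) {
    i <- candidates[ci]
    a <- pairs$term_a[i]; b <- pairs$term_b[i]
    u <- pairGeneUnion(map, a, b)
    if (!length(u)) next
    enrU <- oraBySet(u, .pairKey(a, b))
    lab <- classifyPairTerms(phenoEnr(a), phenoEnr(b), enrU,
                             pair = .pairKey(a, b))
    if (nrow(lab)) {
      lab$term_a <- a; lab$term_b <- b
      labs[[ci]] <- lab
    }
  }
  labels <- do.call(rbind, labs[!vapply(labs, is.null, logical(1))])
  if (is.null(labels))
    labels <- data.frame(pair = character(), funsys = character(),
                         status = character(), term_a = character(),
                         term_b = character(), stringsAsFactors = FALSE)
  phenotypeEnrichment <- do.call(rbind, as.list(cache, sorted = TRUE))
  if (is.null(phenotypeEnrichment) || !nrow(phenotypeEnrichment))
    phenotypeEnrichment <- data.frame(subject = character(),
                                      funsys = character(),
                                      significant = logical())
  rownames(phenotypeEnrichment) <- NULL
  list(labels = labels[, c("pair", "term_a", "term_b", "funsys", "status")],
       phenotypeEnrichment = phenotypeEnrichment)
}
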