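## Shared fixtures and independent oracles, built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

## ---- oracles ---------------------------------------------------------

## Hypergeometric upper tail by direct pmf summation (independent of the
## package's log-sum-exp path).
oracleTailP <- function(k, nA, nB, N) {
  m <- min(nA, nB)
  if (k <= 0) return(1)
  sum(stats::dhyper(k:m, nA, N - nA, nB))
}

## Exact enumeration for small N where binomial coefficients are exactly
## representable in doubles.
oracleTailExact <- function(k, nA, nB, N) {
  m <- min(nA, nB)
  if (k <= 0) return(1)
  i <- k:m
  sum(choose(nA, i) * choose(N - nA, nB - i)) / choose(N, nB)
}

## Benjamini-Hochberg step-up, written out directly.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## Per-base CNV pileup depth >= 2 regions (brute force, coordinates < 1e4).
oracleDepth2 <- function(cohort) {
  out <- list()
  cn <- cnvRanges(cohort)
  chroms <- unique(unlist(lapply(cn, function(g)
    as.character(seqnames(g)))))
  for (ch in chroms) {
    depth <- integer(10000)
    for (id in names(cn)) {
      gr <- reduce(cn[[id]][as.character(seqnames(cn[[id]])) == ch],
                   ignore.strand = TRUE)
      for (i in seq_along(gr))
        depth[start(gr)[i]:end(gr)[i]] <- depth[start(gr)[i]:end(gr)[i]] + 1L
    }
    covered <- which(depth >= 2L)
    if (length(covered)) out[[ch]] <- covered
  }
  out
}

## Partition density written out directly from the formula.
oracleD <- function(edges, membership) {
  M <- nrow(edges)
  total <- 0
  for (cid in unique(membership)) {
    idx <- membership == cid
    mc <- sum(idx)
    nc <- length(unique(as.vector(edges[idx, , drop = FALSE])))
    if (nc > 2) total <- total + mc * (mc - (nc - 1)) / ((nc - 2) * (nc - 1))
  }
  2 * total / M
}

## ---- small builders --------------------------------------------------

makeCohort <- function(phenotypes, cnvs = NULL) {
  PatientCohort(names(phenotypes), phenotypes, cnvs)
}

grCnv <- function(chrom, start0, end0, kind = "deletion") {
  GRanges(chrom, IRanges::IRanges(start0 + 1, end0), kind = kind)
}

## tiny ontology: root R; A, B under R; A1, A2 under A; B1 under B
tinyOntology <- function() {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: R", "name: root", "",
           "[Term]", "id: A", "name: a", "is_a: R ! root", "",
           "[Term]", "id: B", "name: b", "is_a: R", "",
           "[Term]", "id: A1", "name: a1", "is_a: A", "alt_id: A1x", "",
           "[Term]", "id: A2", "name: a2", "is_a: A", "",
           "[Term]", "id: B1", "name: b1", "is_a: B", "")
  f <- tempfile(fileext = ".obo")
  writeLines(obo, f)
  suppressMessages(readOntology(f))
}

tinyIcTable <- function(ont = tinyOntology()) {
  ann <- DiseaseAnnotations(list(d1 = "A1", d2 = "A2",
                                 d3 = c("A1", "B1"), d4 = "B1"))
  buildInformationContent(ont, ann)
}

## small scenario for fast pipeline tests (not the default study conditions)
tinySimConfig <- function() {
  simConfig(nPatients = 150L, nPhenotypes = 40L, nModules = 2L,
            moduleSizes = c(3L, 4L), carrierCount = 12L,
            perPhenotypeCarriers = 4L, decoySets = 10L, seed = 99L)
}

## canonical simple-graph edge list from a 2 x n matrix of endpoints
.canonPairsForTest <- function(m) {
  a <- pmin(m[1, ], m[2, ]); b <- pmax(m[1, ], m[2, ])
  keep <- a != b & !duplicated(paste(a, b))
  df <- data.frame(term_a = a[keep], term_b = b[keep],
                   stringsAsFactors = FALSE)
  df[order(df$term_a, df$term_b), , drop = FALSE]
}

## random simple graph with nEdges edges over the given nodes
randomGraph <- function(nodes, nEdges) {
  all <- t(utils::combn(nodes, 2))
  sel <- sample.int(nrow(all), min(nEdges, nrow(all)))
  data.frame(term_a = all[sel, 1], term_b = all[sel, 2],
             stringsAsFactors = FALSE)
}

## write a small cohort TSV and return the path
writeCohortFile <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\thpo_terms\tcnvs", lines), f)
  f
}
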