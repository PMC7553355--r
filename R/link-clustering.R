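## Link communities: hierarchical clustering of network edges on the
## inclusive-neighbourhood Jaccard similarity, cut at the height maximising
## the partition density. Edge communities partition the edge set; the node
## sets they induce (phenotype clusters) may overlap.

.edgeMatrix <- function(pairs) {
  if (is.data.frame(pairs))
    pairs <- cbind(pairs$term_a, pairs$term_b)
  m <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (any(m[, 1] == m[, 2])) stop("self-loops are not allowed")
  keys <- paste(m[, 1], m[, 2])
  if (anyDuplicated(keys)) stop("parallel edges: a simple graph is required")
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

.inclusiveNeighborhoods <- function(edges) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(setNames(nodes, nodes), function(n) n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' Inclusive-neighbourhood Jaccard similarity of two adjacent edges
#'
#' For edges e1 = (i, k) and e2 = (j, k) sharing exactly node k, the
#' similarity is `|n+(i) & n+(j)| / |n+(i) | n+(j)|` where `n+(x)` is node x
#' together with its neighbours. Edge pairs sharing no node have similarity 0
#' by convention; edges sharing both endpoints (parallel edges) are an error.
#'
#' @param pairs edge list (data.frame with `term_a`/`term_b` or two-column
#'   matrix) defining the graph.
#' @param e1,e2 character vectors of length 2, the two edges.
#' @return similarity in `[0, 1]`.
#' @export
edgeSimilarity <- function(pairs, e1, e2) {
  edges <- .edgeMatrix(pairs)
  nbr <- .inclusiveNeighborhoods(edges)
  shared <- intersect(e1, e2)
  if (length(shared) >= 2L) stop("edges share both endpoints")
  if (length(shared) == 0L) return(0)
  i <- setdiff(e1, shared); j <- setdiff(e2, shared)
  length(intersect(nbr[[i]], nbr[[j]])) / length(union(nbr[[i]], nbr[[j]]))
}

## Partition density of an edge-community membership vector.
.partitionDensity <- function(edges, membership) {
  M <- nrow(edges)
  terms <- vapply(split(seq_len(M), membership), function(idx) {
    mc <- length(idx)
    nc <- length(unique(as.vector(edges[idx, , drop = FALSE])))
    if (nc <= 2L) return(0)
    mc * (mc - (nc - 1)) / ((nc - 2) * (nc - 1))
  }, numeric(1))
  (2 / M) * sum(terms)
}

#' Detect link communities by partition-density maximisation
#'
#' Computes pairwise edge similarities (inclusive-neighbourhood Jaccard for
#' edges sharing a node, 0 otherwise), hierarchically clusters the edges on
#' distance 1 - S (average linkage by default; single linkage available),
#' evaluates the partition density
#' \deqn{D = \frac{2}{M} \sum_c \frac{m_c\,(m_c - (n_c - 1))}{(n_c - 2)(n_c - 1)}}
#' (a community with \eqn{n_c = 2} nodes contributes 0) at every candidate
#' dendrogram cut, and returns the cut with maximal density; ties go to the
#' lower height (finer clustering). Single-edge communities are retained and
#' can be dropped via [communityNodeSets()].
#'
#' @param pairs edge list (data.frame with `term_a`/`term_b` columns or a
#'   two-column matrix); at least 2 edges.
#' @param linkage `"average"` (default) or `"single"`.
#' @return A [LinkCommunitySolution-class].
#' @export
linkCommunities <- function(pairs, linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  edges <- .edgeMatrix(pairs)
  M <- nrow(edges)
  if (M < 2L) stop("link community detection requires at least 2 edges")
  nbr <- .inclusiveNeighborhoods(edges)
  d <- matrix(1, M, M)
  ## similarity only defined for edge pairs sharing a node: iterate nodes
  incident <- split(rep(seq_len(M), 2L), as.vector(edges))
  for (node in names(incident)) {
    es <- incident[[node]]
    if (length(es) < 2L) next
    for (x in seq_len(length(es) - 1L)) {
      for (y in seq.int(x + 1L, length(es))) {
        i <- es[x]; j <- es[y]
        other <- c(setdiff(edges[i, ], node), setdiff(edges[j, ], node))
        s <- if (other[1] == other[2]) 1 else
          length(intersect(nbr[[other[1]]], nbr[[other[2]]])) /
          length(union(nbr[[other[1]]], nbr[[other[2]]]))
        d[i, j] <- d[j, i] <- min(d[i, j], 1 - s)
      }
    }
  }
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = linkage)
  ## average linkage is monotone up to floating-point noise; cutree insists
  ## on sorted heights
  hc$height <- cummax(hc$height)
  heights <- sort(unique(hc$height))
  ## include a cut below the first merge (all singleton edges, D = 0)
  cuts <- c(if (heights[1] > 0) heights[1] / 2, heights)
  dens <- vapply(cuts, function(h)
    .partitionDensity(edges, cutree(hc, h = h)), numeric(1))
  best <- which(dens >= max(dens) - 1e-12)[1]  # tie -> lower height
  membership <- cutree(hc, h = cuts[best])
  ## deterministic relabelling by first appearance in canonical edge order
  membership <- as.integer(factor(membership, levels = unique(membership)))
  new("LinkCommunitySolution", edges = edges, membership = membership,
      M = as.integer(M), D = dens[best], cutHeight = cuts[best],
      heights = cuts, densities = dens)
}

#' Filter link communities for functional coherence
#'
#' For every community (phenotype cluster) and functional system F, the
#' coverage is the fraction of the cluster's phenotypes that either show
#' individual over-representation for F or are an endpoint of an in-cluster
#' pair labelled consistent or emergent for F. The cluster is functionally
#' coherent when its best coverage reaches `theta` (default 0.70); all
#' qualifying systems are listed.
#'
#' @param solution a [LinkCommunitySolution-class].
#' @param phenotypeEnrichment per-phenotype ORA records (from
#'   [labelPairs()]`$phenotypeEnrichment`), with `subject`, `funsys`,
#'   `significant`.
#' @param pairLabels pair labels (from [labelPairs()]`$labels`).
#' @param theta coherence threshold in (0, 1].
#' @return data.frame with one row per community: `cluster_id`, `n_nodes`
#'   (`n_c`), `n_edges` (`m_c`), `trivial` (single edge), `coherent`,
#'   and list columns `phenotypes`, `coherent_funsys` (named coverage
#'   vectors).
#' @export
coherentClusters <- function(solution, phenotypeEnrichment, pairLabels,
                             theta = 0.70) {
  comm <- communities(solution)
  edges <- solution@edges
  sigPheno <- phenotypeEnrichment[phenotypeEnrichment$significant, ,
                                  drop = FALSE]
  rows <- lapply(seq_along(comm), function(ci) {
    idx <- comm[[ci]]
    nodeSet <- sort(unique(as.vector(edges[idx, , drop = FALSE])))
    edgeKeys <- .pairKey(edges[idx, 1], edges[idx, 2])
    ## evidence per funsys: individually significant phenotypes ...
    ev <- split(sigPheno$subject[sigPheno$subject %in% nodeSet],
                sigPheno$funsys[sigPheno$subject %in% nodeSet])
    ## ... plus endpoints of in-cluster labelled pairs
    inLab <- pairLabels[pairLabels$pair %in% edgeKeys, , drop = FALSE]
    if (nrow(inLab)) {
      ev2 <- split(c(inLab$term_a, inLab$term_b),
                   c(inLab$funsys, inLab$funsys))
      for (f in names(ev2)) ev[[f]] <- c(ev[[f]], ev2[[f]])
    }
    coverage <- vapply(ev, function(ph)
      length(intersect(unique(ph), nodeSet)) / length(nodeSet), numeric(1))
    qual <- sort(coverage[coverage >= theta], decreasing = TRUE)
    data.frame(cluster_id = sprintf("C%03d", ci),
               n_nodes = length(nodeSet), n_edges = length(idx),
               trivial = length(idx) == 1L,
               coherent = length(qual) > 0L,
               phenotypes = I(list(nodeSet)),
               coherent_funsys = I(list(qual)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Disease overlap of a phenotype cluster
#'
#' Diseases whose annotation misses at most `allowedMissing` of the cluster's
#' phenotypes (default 1: all phenotypes, or all but one, found within the
#' disease).
#'
#' @param clusterPhenotypes character vector of the cluster's phenotype ids.
#' @param diseases a [DiseaseAnnotations-class].
#' @param allowedMissing maximum number of cluster phenotypes absent from the
#'   disease annotation.
#' @return data.frame with `disease_id`, `n_missing`, sorted by `n_missing`.
#' @export
clusterDiseaseOverlap <- function(clusterPhenotypes, diseases,
                                  allowedMissing = 1L) {
  ann <- diseasePhenotypes(diseases)
  missing <- vapply(ann, function(ph)
    length(setdiff(clusterPhenotypes, ph)), integer(1))
  keep <- missing <= allowedMissing
  out <- data.frame(disease_id = names(ann)[keep],
                    n_missing = unname(missing[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$n_missing, out$disease_id), , drop = FALSE]
}
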