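test_that("edge similarity follows the inclusive-neighbourhood Jaccard", {
  path <- data.frame(term_a = c("a", "b"), term_b = c("b", "c"))
  expect_equal(edgeSimilarity(path, c("a", "b"), c("b", "c")), 1 / 3)
  tri <- data.frame(term_a = c("a", "a", "b"), term_b = c("b", "c", "c"))
  expect_equal(edgeSimilarity(tri, c("a", "b"), c("b", "c")), 1)
  disj <- data.frame(term_a = c("a", "c"), term_b = c("b", "d"))
  expect_equal(edgeSimilarity(disj, c("a", "b"), c("c", "d")), 0)
  expect_error(edgeSimilarity(path, c("a", "b"), c("b", "a")),
               "both endpoints")
})

test_that("partition density of canonical fixtures", {
  tri <- data.frame(term_a = c("a", "a", "b"), term_b = c("b", "c", "c"))
  sol <- linkCommunities(tri)
  expect_equal(partitionDensity(sol), 1.0)
  expect_equal(length(unique(sol@membership)), 1L)

  twoTri <- data.frame(term_a = c("a", "a", "b", "x", "x", "y"),
                       term_b = c("b", "c", "c", "y", "z", "z"))
  sol2 <- linkCommunities(twoTri)
  expect_equal(partitionDensity(sol2), 1.0)
  expect_equal(length(unique(sol2@membership)), 2L)
  expect_setequal(vapply(communityNodeSets(sol2), paste, "", collapse = ","),
                  c("a,b,c", "x,y,z"))

  ## a community with two nodes (single edge) contributes 0
  edges <- data.frame(term_a = c("a", "a", "b", "p"),
                      term_b = c("b", "c", "c", "q"))
  sol3 <- linkCommunities(edges)
  expect_equal(partitionDensity(sol3), (2 / 4) * (3 / 2))
  expect_true(any(table(sol3@membership) == 1L))
})

test_that("returned cut maximises density over every dendrogram cut", {
  set.seed(77)
  for (rep in 1:60) {
    nodes <- paste0("n", 1:sample(4:7, 1))
    g <- randomGraph(nodes, sample(3:7, 1))
    if (nrow(g) < 2) next
    sol <- linkCommunities(g)
    edges <- sol@edges
    ## independent oracle: rebuild distances from the exported similarity,
    ## cut the dendrogram at every height, score with the direct formula
    M <- nrow(edges)
    d <- matrix(1, M, M); diag(d) <- 0
    for (i in seq_len(M - 1)) for (j in (i + 1):M) {
      if (length(intersect(edges[i, ], edges[j, ])) == 1L) {
        s <- edgeSimilarity(g, edges[i, ], edges[j, ])
        d[i, j] <- d[j, i] <- 1 - s
      }
    }
    hc <- hclust(as.dist(d), method = "average")
    hc$height <- cummax(hc$height)   # guard floating-point inversions
    hts <- c(min(hc$height) / 2, sort(unique(hc$height)))
    best <- max(vapply(hts, function(h)
      oracleD(edges, cutree(hc, h = h)), numeric(1)))
    expect_equal(partitionDensity(sol), best, tolerance = 1e-10)
    ## reported D is consistent with its own membership
    expect_equal(partitionDensity(sol), oracleD(edges, sol@membership))
    ## edge communities partition E
    expect_equal(sum(lengths(communities(sol))), M)
  }
})

test_that("coherence thresholds follow the coverage rule", {
  ## 4-phenotype cluster, 3 with evidence -> 0.75 >= 0.70 passes
  edges <- data.frame(term_a = c("p1", "p1", "p1", "p2", "p2", "p3"),
                      term_b = c("p2", "p3", "p4", "p3", "p4", "p4"))
  sol <- linkCommunities(edges)
  enr <- data.frame(subject = c("p1", "p2", "p3"), funsys = "F",
                    significant = TRUE, stringsAsFactors = FALSE)
  noLab <- data.frame(pair = character(), term_a = character(),
                      term_b = character(), funsys = character(),
                      status = character())
  cl <- coherentClusters(sol, enr, noLab, theta = 0.70)
  expect_true(cl$coherent)
  expect_equal(unname(cl$coherent_funsys[[1]]["F"]), 0.75)

  ## 3-phenotype cluster, 2 with evidence -> 0.667 < 0.70 fails
  tri <- data.frame(term_a = c("a", "a", "b"), term_b = c("b", "c", "c"))
  solT <- linkCommunities(tri)
  enr2 <- data.frame(subject = c("a", "b"), funsys = "F",
                     significant = TRUE)
  clT <- coherentClusters(solT, enr2, noLab, theta = 0.70)
  expect_false(clT$coherent)
  ## theta = 0 is not allowed by config, but coverage >= tiny theta holds
  clT0 <- coherentClusters(solT, enr2, noLab, theta = 1e-9)
  expect_true(clT0$coherent)

  ## pair-label evidence covers both endpoints of an in-cluster edge
  lab <- data.frame(pair = "a|b", term_a = "a", term_b = "b",
                    funsys = "G", status = "emergent")
  clL <- coherentClusters(solT, enr2[0, ], lab, theta = 0.6)
  expect_true(clL$coherent)
  expect_equal(unname(clL$coherent_funsys[[1]]["G"]), 2 / 3)
})

test_that("coherence is monotone when adding an evidence phenotype", {
  ## a-b-c triangle coherent for F at 2/3; adding d with evidence keeps F
  quad <- data.frame(term_a = c("a", "a", "b", "c"),
                     term_b = c("b", "c", "c", "d"))
  sol <- linkCommunities(quad)
  noLab <- data.frame(pair = character(), term_a = character(),
                      term_b = character(), funsys = character(),
                      status = character())
  enr3 <- data.frame(subject = c("a", "b", "c", "d"), funsys = "F",
                     significant = TRUE)
  cl <- coherentClusters(sol, enr3, noLab, theta = 0.66)
  expect_true(all(cl$coherent))
})

test_that("cluster-disease overlap admits at most the allowed missing", {
  dis <- DiseaseAnnotations(list(D1 = c("p1", "p2", "p4"),
                                 D2 = c("p1", "p2"),
                                 D3 = c("p1", "p2", "p3", "p5")))
  ## D1 misses p3, D2 misses p3, D3 misses none -> all within one missing
  ov <- clusterDiseaseOverlap(c("p1", "p2", "p3"), dis, allowedMissing = 1)
  expect_setequal(ov$disease_id, c("D1", "D2", "D3"))
  expect_equal(ov$n_missing[ov$disease_id == "D3"], 0L)
  ov00 <- clusterDiseaseOverlap(c("p1", "p2", "p3"), dis,
                                allowedMissing = 0)
  expect_equal(ov00$disease_id, "D3")
  ov0 <- clusterDiseaseOverlap(c("p1", "p2", "p3", "p4"), dis,
                               allowedMissing = 1)
  expect_false("D2" %in% ov0$disease_id)  # missing 2
})
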