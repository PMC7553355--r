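test_that("pair-disease counting and thresholds", {
  dis <- DiseaseAnnotations(list(D1 = c("p1", "p2"),
                                 D2 = c("p1", "p2", "p3"),
                                 D3 = "p1"))
  pairs <- data.frame(term_a = "p1", term_b = "p2")
  expect_equal(pairDiseaseCounts(pairs, dis), 2L)
  expect_equal(pairDiseaseOverlap(pairs, dis, 1), 1L)
  expect_equal(pairDiseaseOverlap(pairs, dis, 2), 1L)
  expect_equal(pairDiseaseOverlap(pairs, dis, 3), 0L)
  empty <- DiseaseAnnotations(list())
  expect_equal(pairDiseaseOverlap(pairs, empty, 1), 0L)
  ## monotone non-increasing in the threshold on random data
  set.seed(9)
  terms <- paste0("p", 1:10)
  dis2 <- DiseaseAnnotations(setNames(lapply(1:15, function(i)
    sample(terms, sample(2:5, 1))), paste0("D", 1:15)))
  prs <- randomGraph(terms, 12)
  counts <- vapply(1:4, function(t)
    pairDiseaseOverlap(prs, dis2, t), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("co-mention Fisher test equals fixed-margin enumeration", {
  set.seed(14)
  for (rep in 1:40) {
    U <- sample(5:40, 1)
    absA <- sample(U, sample(1:U, 1))
    absB <- sample(U, sample(1:U, 1))
    idx <- list(A = paste0("ab", absA), B = paste0("ab", absB))
    corp <- LiteratureCorpus(idx, universeSize = U)
    res <- comentionTest(corp, "A", "B")
    expect_equal(res$n11 + res$n10 + res$n01 + res$n00, U)
    want <- oracleTailP(res$n11, length(absA), length(absB), U)
    expect_equal(res$p, want, tolerance = 1e-12)
    ## independent spot-check against fisher.test one-sided
    ft <- stats::fisher.test(matrix(c(res$n11, res$n01, res$n10, res$n00),
                                    2), alternative = "greater")
    expect_equal(res$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("co-mention degenerate margins give p = 1", {
  corp <- LiteratureCorpus(list(A = paste0("x", 1:20), B = paste0("x", 1:6)),
                           universeSize = 20)
  expect_equal(comentionTest(corp, "A", "B")$p, 1)  # A is the whole corpus
  corp2 <- LiteratureCorpus(list(A = paste0("x", 1:5),
                                 B = paste0("y", 1:5)))
  expect_equal(comentionTest(corp2, "A", "B")$p, 1)  # disjoint, n11 = 0
  miss <- comentionTest(corp2, "A", "Z")
  expect_equal(miss$missing, "Z")
  expect_true(is.na(miss$p))
})

test_that("gene co-mention statistic and permutation null", {
  corp <- LiteratureCorpus(list(P1 = c("a1", "a2"), P2 = c("a3"),
                                g1 = c("a1"), g2 = c("a9"), g3 = c("a3")))
  map <- list(P1 = c("g1", "g2"), P2 = c("g3", "gX"))
  res <- geneComentionCount(corp, map, nRandomizations = 50, seed = 3)
  expect_equal(res$observed, 2L)  # P1-g1 share a1; P2-g3 share a3
  ## genes with empty abstract sets -> observed 0
  map0 <- list(P1 = "gX", P2 = "gY")
  expect_equal(geneComentionCount(corp, map0, 10, 1)$observed, 0L)
  ## determinism
  expect_identical(res, geneComentionCount(corp, map, 50, 3))
})

test_that("Resnik similarity reproduces a hand-computed fixture", {
  ont <- tinyOntology()
  ic <- tinyIcTable(ont)
  ## propagated annotation counts: A1 2/4, A2 1/4, A 3/4, B1 2/4, B 2/4, R 1
  expect_equal(unname(ic$ic["A"]), -log(3 / 4))
  expect_equal(ic$icMax, log(4))
  expect_equal(resnikSimilarity(ont, ic, "A1", "A2"),
               log(4 / 3) / log(4))
  expect_equal(resnikSimilarity(ont, ic, "A1", "B1"), 0)  # MICA is the root
  expect_equal(resnikSimilarity(ont, ic, "A1", "A1"), log(2) / log(4))
  expect_equal(resnikSimilarity(ont, ic, "B1", "B"), log(2) / log(4))
  expect_error(resnikSimilarity(ont, ic, "A1", "ZZ"), "ZZ")
})

test_that("cluster semantic score: null invariants and planted signal", {
  ont <- tinyOntology()
  ic <- tinyIcTable(ont)
  ## all identical phenotypes: observed equals every null draw, z undefined/0
  same <- list(c("A1", "A1x"), c("A1", "A1x"))  # sizes kept, trivial pools
  res0 <- clusterSemanticScore(list(c("A1", "A1"), c("A1", "A1")),
                               ont, ic, nRandomizations = 20, seed = 1)
  expect_equal(res0$observed, res0$nullMean)
  expect_true(is.na(res0$z) || abs(res0$z) < 1e-9)
  ## semantically tight clusters beat the randomised assignment
  tight <- list(c("A1", "A2"), c("B1", "B1"))
  res <- clusterSemanticScore(tight, ont, ic, nRandomizations = 200,
                              seed = 2)
  expect_gt(res$observed, 0)
  expect_identical(res,
                   clusterSemanticScore(tight, ont, ic, 200, seed = 2))
  expect_error(clusterSemanticScore(list("A1"), ont, ic, 10, 1),
               "at least 2")
})

test_that("patient cluster support counts max co-located phenotypes", {
  co <- makeCohort(list(P1 = c("a", "b", "c"),       # whole cluster 1
                        P2 = c("a", "x"),            # split across clusters
                        P3 = c("zz")))               # touches nothing
  clusters <- list(c("a", "b", "c"), c("x", "y"))
  res <- patientClusterSupport(co, clusters, nRandomizations = 20, seed = 1)
  expect_equal(unname(res$real), c(1L, 1L))   # only P1 reaches >=2 and >=3
  pp <- res$perPatient
  expect_setequal(pp$patient_id, c("P1", "P2"))
  expect_equal(pp$max_in_cluster[pp$patient_id == "P1"], 3L)
  expect_equal(pp$max_in_cluster[pp$patient_id == "P2"], 1L)
  expect_equal(pp$clusters_touched[pp$patient_id == "P2"], 2L)
})

test_that("cluster membership summary is an exact contingency", {
  co <- makeCohort(list(P1 = c("a", "x"), P2 = c("a", "b"), P3 = "zz"))
  clusters <- list(c("a", "b"), c("x", "y"))
  mem <- clusterMembershipSummary(co, clusters)
  ## P1: 2 phenotypes, 2 clusters; P2: 2 phenotypes, 1 cluster; P3 excluded
  expect_equal(sum(mem$n_patients), 2L)
  expect_equal(mem$n_patients[mem$n_clusters == 2], 1L)
  expect_equal(mem$n_patients[mem$n_clusters == 1], 1L)
})
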