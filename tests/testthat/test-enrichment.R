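.toyCollection <- function() {
  FunSysCollection(list(S1 = paste0("g", 1:5),
                        S2 = paste0("g", 6:10),
                        S3 = paste0("g", 11:20)))
}

test_that("ORA p-values match tail enumeration", {
  coll <- .toyCollection()
  ## universe 20, |S|=5, |query|=5, overlap 3
  res <- suppressMessages(
    overrepresentation(c("g1", "g2", "g3", "g8", "g15"), coll,
                       subject = "q"))
  row <- res[res$funsys == "S1", ]
  expect_equal(row$overlap, 3L)
  want <- (choose(5, 3) * choose(15, 2) + choose(5, 4) * choose(15, 1) +
             choose(5, 5)) / choose(20, 5)
  expect_equal(row$p_raw, want)       # 1126/15504
  expect_equal(want, 1126 / 15504)
  ## zero-overlap sets are omitted
  expect_false("S2" %in% res$funsys[res$overlap == 0])
})

test_that("query saturating the universe gives p = 1 everywhere", {
  coll <- .toyCollection()
  res <- suppressMessages(
    overrepresentation(geneUniverse(coll), coll, subject = "all"))
  expect_true(all(res$p_raw == 1))
  expect_equal(res$overlap, res$set_size)
})

test_that("genes outside the universe are dropped; empty query is empty", {
  coll <- .toyCollection()
  expect_message(
    res <- overrepresentation(c("g1", "nope"), coll, subject = "q"),
    "dropped 1")
  expect_equal(unique(res$query_size), 1L)
  expect_message(r0 <- overrepresentation(character(), coll, subject = "q"),
                 "empty query")
  expect_equal(nrow(r0), 0L)
})

test_that("BH adjustment matches an independent step-up implementation", {
  coll <- .toyCollection()
  set.seed(42)
  for (rep in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(p.adjust(p, "BH"), oracleBH(p), tolerance = 1e-12)
  }
  ## worked example: [0.01, 0.02, 0.03, 0.04] -> all 0.04
  expect_equal(oracleBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("ORA p is monotone non-increasing in overlap at fixed sizes", {
  p <- hyperTailP(1:5, 5, 5, 20)
  expect_true(all(diff(p) < 0))
})

test_that("pair gene union is a plain set union", {
  map <- list(A = c("g1", "g2"), B = c("g2", "g3"))
  expect_equal(pairGeneUnion(map, "A", "B"), c("g1", "g2", "g3"))
  expect_equal(pairGeneUnion(map, "A", "missing"), c("g1", "g2"))
  expect_gte(length(pairGeneUnion(map, "A", "B")),
             max(lengths(map)))
})

test_that("consistent/emergent labels follow the truth table", {
  rec <- function(subject, funsys, sig) data.frame(
    subject = subject, funsys = funsys, significant = sig,
    stringsAsFactors = FALSE)
  both <- classifyPairTerms(rec("a", "F", TRUE), rec("b", "F", TRUE),
                            rec("a|b", "F", TRUE))
  expect_equal(both$status, "consistent")
  neither <- classifyPairTerms(rec("a", "F", FALSE), rec("b", "F", FALSE),
                               rec("a|b", "F", TRUE))
  expect_equal(neither$status, "emergent")
  ## absent from individual records counts as not significant
  absent <- classifyPairTerms(rec("a", "other", TRUE)[0, ],
                              rec("b", "other", TRUE)[0, ],
                              rec("a|b", "F", TRUE))
  expect_equal(absent$status, "emergent")
  mixed <- classifyPairTerms(rec("a", "F", TRUE), rec("b", "F", FALSE),
                             rec("a|b", "F", TRUE))
  expect_equal(nrow(mixed), 0L)
  noUnion <- classifyPairTerms(rec("a", "F", TRUE), rec("b", "F", TRUE),
                               rec("a|b", "F", FALSE))
  expect_equal(nrow(noUnion), 0L)
  ## statuses are disjoint per (pair, funsys) by construction
  multi <- classifyPairTerms(
    rec(c("a", "a"), c("F1", "F2"), c(TRUE, FALSE)),
    rec(c("b", "b"), c("F1", "F2"), c(TRUE, FALSE)),
    rec(c("a|b", "a|b"), c("F1", "F2"), c(TRUE, TRUE)))
  expect_equal(multi$status[multi$funsys == "F1"], "consistent")
  expect_equal(multi$status[multi$funsys == "F2"], "emergent")
  expect_false(any(duplicated(multi$funsys)))
})

test_that("labelPairs orchestrates enrichment over a pair table", {
  ## two phenotypes each carrying half of S3, plus a shared background set S1
  map <- list(A = c(paste0("g", 11:15), paste0("g", 1:5)),
              B = c(paste0("g", 16:20), paste0("g", 1:5)))
  coll <- FunSysCollection(list(S1 = paste0("g", 1:5),
                                S3 = paste0("g", 11:20),
                                D1 = paste0("d", 1:30),
                                D2 = paste0("d", 31:60)))
  pairs <- data.frame(term_a = "A", term_b = "B")
  out <- suppressMessages(labelPairs(pairs, map, coll, alpha = 0.05))
  expect_true(all(c("pair", "funsys", "status") %in% names(out$labels)))
  s1 <- out$labels[out$labels$funsys == "S1", ]
  expect_equal(s1$status, "consistent")   # both halves carry S1 fully
  expect_true(all(out$phenotypeEnrichment$subject %in% c("A", "B")))
})
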