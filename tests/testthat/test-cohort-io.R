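test_that("cohort TSV parsing and round trip", {
  f <- writeCohortFile(c("P1\tHP:A,HP:B\tchr1:100-200:deletion",
                         "P2\tHP:B\t"))
  co <- suppressMessages(readCohort(f))
  expect_s4_class(co, "PatientCohort")
  expect_equal(nPatients(co), 2L)
  expect_equal(phenotypeUniverse(co), c("HP:A", "HP:B"))
  gr <- cnvRanges(co)$P1
  expect_equal(start(gr), 101L)   # 0-based half-open in, 1-based closed held
  expect_equal(end(gr), 200L)
  out <- tempfile()
  writeCohort(co, out)
  co2 <- suppressMessages(readCohort(out))
  expect_equal(phenotypeSets(co2), phenotypeSets(co))
  expect_equal(unname(vapply(patientIds(co), function(id)
    identical(cnvRanges(co2)[[id]], cnvRanges(co)[[id]]), logical(1))),
    rep(TRUE, 2))
})

test_that("cohort parse errors name the offending line", {
  f <- writeCohortFile("P1\tHP:A\tchr1:200-100:deletion")
  expect_error(readCohort(f), "line 2.*start must be")
  f2 <- writeCohortFile("P1\tHP:A\tchr1:100-200:inversion")
  expect_error(readCohort(f2), "unknown kind")
  f3 <- writeCohortFile(c("P1\tHP:A\t", "P1\tHP:B\t"))
  expect_error(readCohort(f3), "duplicate patient id")
  f4 <- writeCohortFile("P1\t\t")
  expect_error(readCohort(f4), "without phenotypes")
})

test_that("duplicate phenotype entries are deduplicated", {
  f <- writeCohortFile("P1\tHP:A,HP:A,HP:B\t")
  co <- suppressMessages(readCohort(f))
  expect_equal(phenotypeSets(co)$P1, c("HP:A", "HP:B"))
})

test_that("OBO parsing builds ancestor closure over a DAG", {
  ont <- tinyOntology()
  expect_setequal(termAncestors(ont, "A1"), c("A1", "A", "R"))
  expect_setequal(termAncestors(ont, "R"), "R")
  ## multi-parent union
  obo <- c("[Term]", "id: r", "",
           "[Term]", "id: p1", "is_a: r", "",
           "[Term]", "id: p2", "is_a: r", "",
           "[Term]", "id: c", "is_a: p1", "is_a: p2")
  f <- tempfile(); writeLines(obo, f)
  ont2 <- suppressMessages(readOntology(f))
  expect_setequal(termAncestors(ont2, "c"), c("c", "p1", "p2", "r"))
})

test_that("OBO errors: undeclared parent and cycles", {
  f <- tempfile()
  writeLines(c("[Term]", "id: a", "is_a: ghost"), f)
  expect_error(readOntology(f), "undeclared")
  writeLines(c("[Term]", "id: a", "is_a: b", "",
               "[Term]", "id: b", "is_a: a"), f)
  expect_error(readOntology(f), "cycle")
})

test_that("alt ids resolve in cohorts and disease annotations", {
  ont <- tinyOntology()
  f <- writeCohortFile("P1\tA1x,ZZZ\t")
  expect_warning(co <- suppressMessages(readCohort(f, ont)),
                 "not resolvable")
  expect_equal(phenotypeSets(co)$P1, "A1")
  ad <- tempfile()
  writeLines(c("disease_id\tphenotype_id", "D1\tA1x", "D1\tB1"), ad)
  ann <- suppressMessages(readDiseaseAnnotations(ad, ont, source = "x"))
  expect_equal(diseasePhenotypes(ann)$D1, c("A1", "B1"))
})

test_that("BED, GMT and corpus readers parse standard dialects", {
  bed <- tempfile()
  writeLines("chr1\t100\t160\tG1\t0\t+", bed)
  gm <- readGeneModels(bed)
  expect_equal(names(gm), "G1")
  expect_equal(start(gm), 101L)  # BED is 0-based half-open
  expect_equal(end(gm), 160L)

  gmt <- tempfile()
  writeLines(c("F1\tdesc\tg1\tg2", "F2\tother\tg2\tg3\tg4"), gmt)
  fs <- readGmt(gmt)
  expect_equal(funsysSets(fs)$F1, c("g1", "g2"))
  expect_equal(geneUniverse(fs), c("g1", "g2", "g3", "g4"))
  writeLines(c("F1\tdesc"), gmt)
  expect_error(readGmt(gmt), "empty gene set")

  cf <- tempfile()
  writeLines(c("term_id\tabstract_id", "HP:A\tpm1", "HP:A\tpm2",
               "g1\tpm2"), cf)
  corp <- readCorpus(cf)
  expect_equal(corpusUniverseSize(corp), 2L)
  expect_equal(corpusIndex(corp)[["HP:A"]], c("pm1", "pm2"))
})

test_that("loading order does not change the cohort", {
  ph <- list(P2 = c("HP:B"), P1 = c("HP:B", "HP:A"))
  a <- PatientCohort(names(ph), ph)
  b <- PatientCohort(rev(names(ph)), rev(ph))
  expect_identical(patientIds(a), patientIds(b))
  expect_identical(phenotypeSets(a), phenotypeSets(b))
})
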