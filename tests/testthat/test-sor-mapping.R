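test_that("two overlapping CNVs yield the shared segment only", {
  co <- makeCohort(list(A = "HP:1", B = "HP:2"),
                   list(A = grCnv("chr1", 100, 200),
                        B = grCnv("chr1", 150, 250)))
  sors <- decomposeToSors(co)
  expect_equal(length(sors), 1L)
  expect_equal(start(sors), 151L)  # [150, 200) 0-based
  expect_equal(end(sors), 200L)
  expect_setequal(unlist(sors$patients), c("A", "B"))
})

test_that("three staggered CNVs segment at every breakpoint", {
  co <- makeCohort(list(A = "HP:1", B = "HP:2", C = "HP:3"),
                   list(A = grCnv("chr1", 0, 300),
                        B = grCnv("chr1", 100, 200),
                        C = grCnv("chr1", 150, 250)))
  sors <- decomposeToSors(co)
  seg <- data.frame(start0 = start(sors) - 1L, end0 = end(sors),
                    patients = vapply(sors$patients, paste, "",
                                      collapse = ","))
  expect_equal(seg$start0, c(100, 150, 200))
  expect_equal(seg$end0, c(150, 200, 250))
  expect_equal(seg$patients, c("A,B", "A,B,C", "A,C"))
})

test_that("a single patient produces no SORs", {
  co <- makeCohort(list(A = "HP:1", B = "HP:2"),
                   list(A = grCnv("chr1", 0, 100),
                        B = GRanges(kind = character())))
  expect_length(decomposeToSors(co), 0L)
})

test_that("SOR union equals the depth>=2 pileup on random fixtures", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    ids <- paste0("P", seq_len(n))
    cnvs <- lapply(ids, function(id) {
      k <- sample(1:3, 1)
      s <- sample(0:8000, k)
      w <- sample(200:1500, k, replace = TRUE)
      suppressWarnings(do.call(c, lapply(seq_len(k), function(i)
        grCnv(sample(c("chr1", "chr2"), 1), s[i], s[i] + w[i]))))
    })
    names(cnvs) <- ids
    co <- makeCohort(setNames(as.list(paste0("HP:", seq_len(n))), ids), cnvs)
    sors <- decomposeToSors(co)
    ## per-base oracle
    want <- oracleDepth2(co)
    got <- list()
    for (ch in unique(as.character(seqnames(sors)))) {
      s <- sors[as.character(seqnames(sors)) == ch]
      got[[ch]] <- sort(unlist(lapply(seq_along(s), function(i)
        start(s)[i]:end(s)[i])))
    }
    expect_identical(got[order(names(got))], want[order(names(want))])
    ## disjointness and >= 2 patients on every run
    expect_true(all(lengths(sors$patients) >= 2L))
    for (ch in unique(as.character(seqnames(sors)))) {
      s <- sors[as.character(seqnames(sors)) == ch]
      if (length(s) > 1L)
        expect_true(all(start(s)[-1] > end(s)[-length(s)]))
    }
  }
})

test_that("decomposition is invariant to patient and CNV order", {
  cnvs <- list(A = suppressWarnings(c(grCnv("chr1", 0, 300),
                                      grCnv("chr1", 500, 700))),
               B = grCnv("chr1", 100, 600),
               C = grCnv("chr1", 250, 550))
  ph <- list(A = "HP:1", B = "HP:2", C = "HP:3")
  s1 <- decomposeToSors(makeCohort(ph, cnvs))
  s2 <- decomposeToSors(makeCohort(rev(ph), rev(cnvs)))
  expect_equal(start(s1), start(s2))
  expect_equal(end(s1), end(s2))
  expect_identical(as.list(s1$patients), as.list(s2$patients))
})

test_that("phenotype-SOR association applies the index filter", {
  ## N=20, n_pheno=5, n_sor=4, k=4 -> tail C(5,4)/C(20,4) -> retained
  ph <- c(lapply(1:5, function(i) "HP:X"),
          lapply(6:20, function(i) paste0("HP:bg", i)))
  names(ph) <- sprintf("P%02d", 1:20)
  cnvs <- rep(list(GRanges(kind = character())), 20)
  names(cnvs) <- names(ph)
  for (i in 1:4) cnvs[[i]] <- grCnv("chr1", 100, 200)
  co <- makeCohort(ph, cnvs)
  sors <- decomposeToSors(co)
  expect_equal(length(sors), 1L)
  assoc <- associatePhenotypesToSors(co, sors, threshold = 2)
  row <- assoc[assoc$phenotype == "HP:X", ]
  expect_equal(row$k, 4L)
  expect_equal(row$index, -log10(5 / choose(20, 4)))
  expect_gte(row$index, 2)
  ## below threshold is filtered: same geometry in a 10-patient cohort
  ph2 <- c(lapply(1:4, function(i) "HP:Y"),
           lapply(5:10, function(i) paste0("HP:bg", i)))
  names(ph2) <- sprintf("Q%02d", 1:10)
  cnvs2 <- rep(list(GRanges(kind = character())), 10)
  names(cnvs2) <- names(ph2)
  for (i in 1:3) cnvs2[[i]] <- grCnv("chr2", 0, 50)
  co2 <- makeCohort(ph2, cnvs2)
  assoc2 <- associatePhenotypesToSors(co2, decomposeToSors(co2),
                                      threshold = 2)
  ## k=3, n_pheno=4, n_sor=3: tail = 4/120 -> index ~ 1.477 < 2
  expect_false("HP:Y" %in% assoc2$phenotype)
})

test_that("gene mapping uses >= 1 bp same-chromosome intersection", {
  gm <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges::IRanges(c(101, 301, 151), c(160, 400, 200)))
  names(gm) <- gm$name <- c("G1", "G2", "G3")
  sors <- GRanges("chr1", IRanges::IRanges(151, 200))
  sors$sor_id <- "SOR1"
  sors$patients <- IRanges::CharacterList(list(c("A", "B")))
  sors <- addSorGenes(sors, gm)
  expect_equal(unname(unlist(sors$genes)), "G1")  # G2 out, G3 wrong chrom
  assoc <- data.frame(phenotype = "HP:X", sor_id = "SOR1")
  map <- mapSorsToGenes(assoc, sors)
  expect_equal(map$`HP:X`, "G1")
})

test_that("SOR gene randomisation preserves structure", {
  set.seed(2)
  sors <- GRanges("chr1", IRanges::IRanges(c(1, 100, 200), c(50, 150, 250)))
  sors$sor_id <- paste0("S", 1:3)
  sors$genes <- IRanges::CharacterList(list(c("g1", "g2"), "g3",
                                            c("g4", "g5", "g6")))
  assoc <- data.frame(phenotype = c("HP:A", "HP:A", "HP:B"),
                      sor_id = c("S1", "S2", "S3"))
  pool <- c("g1", "g2", "g3", "g4", "g5", "g6")
  for (seed in 1:50) {
    r <- randomizeSorGenes(sors, assoc, seed)
    expect_setequal(names(r), c("HP:A", "HP:B"))
    expect_true(all(unlist(r) %in% pool))
    expect_equal(length(r$`HP:B`), 3L)   # |genes| per SOR preserved
    expect_lte(length(r$`HP:A`), 3L)     # union of 2+1 with possible overlap
    expect_gte(length(r$`HP:A`), 2L)
  }
  expect_identical(randomizeSorGenes(sors, assoc, 9),
                   randomizeSorGenes(sors, assoc, 9))
})
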