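## Readers and writers for the external formats the workflow touches.
##
## Cohort TSV dialect: header columns patient_id, hpo_terms, cnvs.
##   hpo_terms: comma-separated ontology term ids.
##   cnvs:      semicolon-separated "chrom:start-end:kind" with 0-based
##              half-open coordinates and kind in {deletion, duplication};
##              may be empty.
## Coordinates are converted to the 1-based closed GRanges convention on
## read and back on write, so BED gene models, CNVs and SORs share one
## internal convention.

#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   reduce disjoin findOverlaps sort.GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

.parseCnvField <- function(field, line) {
  if (is.na(field) || !nzchar(field))
    return(GRanges(kind = character()))
  parts <- strsplit(strsplit(field, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- function(why) stop(sprintf("line %d: malformed cnv '%s' (%s)",
                                    line, field, why), call. = FALSE)
  if (any(lengths(parts) != 3L)) bad("expected chrom:start-end:kind")
  chrom <- vapply(parts, `[`, "", 1L)
  coord <- strsplit(vapply(parts, `[`, "", 2L), "-", fixed = TRUE)
  if (any(lengths(coord) != 2L)) bad("expected start-end")
  s <- suppressWarnings(as.numeric(vapply(coord, `[`, "", 1L)))
  e <- suppressWarnings(as.numeric(vapply(coord, `[`, "", 2L)))
  kind <- vapply(parts, `[`, "", 3L)
  if (anyNA(s) || anyNA(e)) bad("non-numeric coordinate")
  if (any(s >= e)) bad("start must be < end (0-based half-open)")
  if (any(!nzchar(chrom))) bad("empty chromosome name")
  if (!all(kind %in% .CNV_KINDS)) bad("unknown kind")
  GRanges(chrom, IRanges(s + 1, e), kind = kind)
}

#' Read a patient cohort from TSV
#'
#' Parses the cohort dialect documented in this page's Details: columns
#' `patient_id`, `hpo_terms` (comma-separated) and `cnvs`
#' (`chrom:start-end:kind`, semicolon-separated, 0-based half-open).
#' Duplicate (patient, phenotype) entries are deduplicated; duplicate patient
#' ids and malformed CNV fields are errors naming the offending line. When an
#' ontology is supplied, phenotype ids are resolved through its alt-id map
#' and ids unknown to the ontology are dropped with a warning count;
#' patients left without phenotypes are rejected.
#'
#' @param path cohort TSV path.
#' @param ontology optional [PhenOntology-class] for term resolution.
#' @return A [PatientCohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path, ontology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  need <- c("patient_id", "hpo_terms", "cnvs")
  if (!all(need %in% names(df)))
    stop("cohort file must declare columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient id: ",
         df$patient_id[duplicated(df$patient_id)][1])
  phen <- lapply(strsplit(df$hpo_terms, ",", fixed = TRUE), function(p)
    unique(trimws(p[nzchar(trimws(p))])))
  if (any(lengths(phen) == 0L))
    stop("line ", which(lengths(phen) == 0L)[1] + 1L,
         ": patient without phenotypes rejected at load")
  cnvs <- lapply(seq_len(nrow(df)), function(i)
    .parseCnvField(df$cnvs[i], i + 1L))
  if (!is.null(ontology)) {
    res <- .resolveTerms(phen, ontology)
    phen <- res$terms
    if (res$dropped > 0L)
      warning(res$dropped, " phenotype entries not resolvable in the ",
              "ontology were dropped")
    if (any(lengths(phen) == 0L))
      stop("patient ", df$patient_id[which(lengths(phen) == 0L)[1]],
           " has no resolvable phenotypes")
  }
  cohort <- PatientCohort(df$patient_id, phen, cnvs)
  .msg("read cohort: ", nPatients(cohort), " patients, ",
       length(phenotypeUniverse(cohort)), " distinct phenotype terms")
  cohort
}

## Map a list of term vectors to primary ids; count the unresolvable ones.
.resolveTerms <- function(termSets, ontology) {
  alt <- altIdMap(ontology)
  known <- ontologyTerms(ontology)
  dropped <- 0L
  out <- lapply(termSets, function(p) {
    hit <- p %in% known
    mapped <- ifelse(hit, p, unname(alt[p]))
    lost <- is.na(mapped)
    dropped <<- dropped + sum(lost)
    unique(mapped[!lost])
  })
  list(terms = out, dropped = dropped)
}

#' Write a patient cohort as TSV
#'
#' Inverse of [readCohort()]; CNV coordinates are emitted 0-based half-open.
#' The first line is a `#` provenance header.
#'
#' @param cohort a [PatientCohort-class].
#' @param path output path.
#' @param config optional object hashed into the header.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, config = NULL) {
  rows <- vapply(patientIds(cohort), function(id) {
    gr <- cnvRanges(cohort)[[id]]
    cnv <- if (length(gr))
      paste(sprintf("%s:%d-%d:%s", as.character(seqnames(gr)),
                    start(gr) - 1L, end(gr), gr$kind), collapse = ";")
    else ""
    paste(id, paste(phenotypeSets(cohort)[[id]], collapse = ","), cnv,
          sep = "\t")
  }, character(1))
  writeLines(c(.headerLine(config), "patient_id\thpo_terms\tcnvs", rows), path)
  invisible(path)
}

#' Read an OBO ontology
#'
#' Minimal OBO stanza parser retaining ids, names, `is_a` parents, `alt_id`
#' mappings and obsolete flags. The term graph must be acyclic; a cycle is an
#' error reporting one offending cycle. The reflexive-transitive ancestor
#' closure is precomputed.
#'
#' @param path OBO file path.
#' @return A [PhenOntology-class].
#' @export
readOntology <- function(path) {
  lines <- readLines(path)
  terms <- character(); nm <- character(); parents <- list()
  alt <- character(); obs <- character()
  cur <- NULL; inTerm <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      terms <<- c(terms, cur$id)
      nm[cur$id] <<- cur$name %||% cur$id
      parents[[cur$id]] <<- cur$is_a %||% character()
      if (!is.null(cur$alt)) alt[cur$alt] <<- cur$id
      if (isTRUE(cur$obsolete)) obs <<- c(obs, cur$id)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(); inTerm <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm || !nzchar(ln)) next
    kv <- regmatches(ln, regexpr(":", ln, fixed = TRUE), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- kv[1]; val <- trimws(kv[2])
    val <- sub("\\s*!.*$", "", val)  # strip trailing OBO comment
    switch(key,
           id = { cur$id <- val },
           name = { cur$name <- val },
           is_a = { cur$is_a <- c(cur$is_a, val) },
           alt_id = { cur$alt <- c(cur$alt, val) },
           is_obsolete = { cur$obsolete <- identical(val, "true") })
  }
  flush()
  if (anyDuplicated(terms)) stop("duplicate term id in OBO file")
  undeclared <- setdiff(unlist(parents, use.names = FALSE), terms)
  if (length(undeclared))
    stop("is_a reference to undeclared id(s): ",
         paste(head(undeclared, 3), collapse = ", "))
  ancestors <- .ancestorClosure(terms, parents)
  ont <- new("PhenOntology", terms = terms, termNames = nm, parents = parents,
             ancestors = ancestors, altIds = alt, obsolete = obs)
  .msg("read ontology: ", length(terms), " terms")
  ont
}

## Topological ancestor closure; reports one cycle on failure.
.ancestorClosure <- function(terms, parents) {
  anc <- vector("list", length(terms))
  names(anc) <- terms
  state <- setNames(integer(length(terms)), terms)  # 0 new, 1 active, 2 done
  stackTrace <- character()
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) {
      cyc <- c(stackTrace[which(stackTrace == t)[1]:length(stackTrace)], t)
      stop("cycle detected in ontology: ", paste(cyc, collapse = " -> "))
    }
    state[[t]] <<- 1L
    stackTrace <<- c(stackTrace, t)
    res <- t
    for (p in parents[[t]]) res <- union(res, visit(p))
    stackTrace <<- stackTrace[-length(stackTrace)]
    state[[t]] <<- 2L
    anc[[t]] <<- sort(res)
    anc[[t]]
  }
  for (t in terms) visit(t)
  anc
}

#' Read gene models from BED
#'
#' Standard BED (0-based half-open) via `rtracklayer`; returns a `GRanges`
#' named by the BED name column. Strand is stored but ignored by all overlap
#' logic in this package.
#'
#' @param path BED file path.
#' @return `GRanges` of gene models, named by gene id.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED gene models require a name column")
  names(gr) <- gr$name
  if (any(width(gr) < 1L)) stop("gene model with start >= end")
  gr
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set id, description, then one gene per field. An empty
#' gene set is an error.
#'
#' @param path GMT file path.
#' @return A [FunSysCollection-class].
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with empty gene set: line ",
         which(lengths(fields) < 3L)[1])
  ids <- vapply(fields, `[`, "", 1L)
  labels <- setNames(vapply(fields, `[`, "", 2L), ids)
  sets <- setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  FunSysCollection(sets, labels)
}

#' Read disease-to-phenotype annotations
#'
#' TSV with columns `disease_id` and `phenotype_id`. With an ontology,
#' phenotype ids are mapped through `alt_id` to primary ids; unresolvable
#' ids are dropped with a logged count.
#'
#' @param path TSV path.
#' @param ontology optional [PhenOntology-class].
#' @param source label stored on the result (e.g. `"OMIM"`).
#' @return A [DiseaseAnnotations-class].
#' @export
readDiseaseAnnotations <- function(path, ontology = NULL,
                                   source = "disease_db") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("disease_id", "phenotype_id") %in% names(df)))
    stop("disease annotation file must declare disease_id and phenotype_id")
  ann <- split(df$phenotype_id, df$disease_id)
  if (!is.null(ontology)) {
    res <- .resolveTerms(ann, ontology)
    ann <- res$terms
    if (res$dropped > 0L)
      .msg("dropped ", res$dropped, " unresolvable disease-annotation terms")
    ann <- ann[lengths(ann) > 0L]
  }
  DiseaseAnnotations(ann, source = source)
}

#' Read a literature co-mention corpus
#'
#' TSV with columns `term_id` and `abstract_id`; terms are phenotype ids and
#' gene symbols in one namespace. The corpus universe is the number of
#' distinct abstract ids in the file.
#'
#' @param path TSV path.
#' @return A [LiteratureCorpus-class].
#' @export
readCorpus <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("term_id", "abstract_id") %in% names(df)))
    stop("corpus file must declare term_id and abstract_id")
  LiteratureCorpus(split(df$abstract_id, df$term_id))
}
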