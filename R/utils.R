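## Internal helpers shared across modules.

#' @importFrom utils packageVersion write.table read.table head tail
#' @importFrom methods new validObject is slotNames
#' @importFrom stats p.adjust hclust cutree as.dist sd setNames runif
NULL

.msg <- function(...) {
  message("[comorbidNet] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stable log(exp(a) + exp(b)); both may be -Inf.
.logaddexp <- function(a, b) {
  if (is.infinite(a) && a < 0) return(b)
  if (is.infinite(b) && b < 0) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

## Deterministic child seed for replicate streams; kept below 2^31.
.childSeed <- function(seed, r) {
  as.integer(((as.double(seed) %% 2147483647) * 69069 +
                101 * as.double(r)) %% 2147483647)
}

## Evaluate expr under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Canonical unordered pair key "a|b" with a < b.
.pairKey <- function(a, b) {
  swap <- a > b
  ta <- ifelse(swap, b, a)
  tb <- ifelse(swap, a, b)
  paste(ta, tb, sep = "|")
}

## Canonicalise a two-column pair structure: a < b within rows, rows sorted.
.canonPairs <- function(term_a, term_b) {
  swap <- term_a > term_b
  ta <- ifelse(swap, term_b, term_a)
  tb <- ifelse(swap, term_a, term_b)
  ord <- order(ta, tb)
  data.frame(term_a = ta[ord], term_b = tb[ord], stringsAsFactors = FALSE)
}

## Short content hash used in writer headers (md5 of the serialised object).
.configHash <- function(x) {
  if (is.null(x)) return("none")
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  substr(unname(tools::md5sum(f)), 1, 8)
}

.headerLine <- function(config = NULL) {
  sprintf("# comorbidNet %s config=%s",
          as.character(utils::packageVersion("comorbidNet")),
          .configHash(config))
}

#' Write a result table as TSV with a provenance header line
#'
#' All tabular outputs of the workflow share one dialect: tab-separated,
#' one `#`-prefixed header line recording the package version and a hash of
#' the configuration, then a column header row.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config optional object (typically a [pipelineConfig()]) hashed into
#'   the header line.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLine(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [writeResultTable()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
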