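## Tabular and graphical report surfaces. Every figure is written as SVG and
## has a TSV twin holding exactly the plotted numbers, so reports are pure
## functions of the stage outputs.

#' @importFrom ggplot2 ggplot aes geom_histogram geom_col geom_boxplot labs
#'   theme_bw ggsave position_dodge
NULL

.writeFigure <- function(plot, df, stem, dir, config) {
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  writeResultTable(df, tsv, config)
  svg <- file.path(dir, paste0(stem, ".svg"))
  ok <- tryCatch({
    ggplot2::ggsave(svg, plot = plot, width = 7, height = 5,
                    device = grDevices::svg)
    TRUE
  }, error = function(e) {
    .msg("figure ", stem, " skipped: ", conditionMessage(e))
    FALSE
  })
  c(tsv, if (ok) svg)
}

.sortClusterReport <- function(cl) {
  ## clusters showing both coherence and disease overlap first, then
  ## coherent-only, then disease-only, then neither
  rank <- with(cl, ifelse(coherent & disease_overlap, 1L,
                   ifelse(coherent, 2L, ifelse(disease_overlap, 3L, 4L))))
  cl[order(rank, -cl$n_nodes, cl$cluster_id), , drop = FALSE]
}

#' Write workflow reports
#'
#' Emits the tabular and graphical summaries of a [runPipeline()] result:
#' a pairs report (dataset sizes, index and prevalence distributions,
#' disease-overlap counts, co-mention p-value summary), a clustering report
#' (cluster counts per dataset: total, coherent, disease-overlapping, both),
#' per-cluster details (phenotypes, coherent systems with coverage, diseases,
#' supporting patients; ordered so clusters showing both coherence and
#' disease overlap come first), a per-patient report, and SVG figures with
#' TSV twins. Regeneration from identical inputs is bit-stable.
#'
#' @param results a [runPipeline()] result list.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeReports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- results$config
  written <- character()
  put <- function(df, name) {
    p <- writeResultTable(df, file.path(dir, name), cfg)
    written <<- c(written, p)
  }

  ## ---- pairs report -------------------------------------------------
  counts <- data.frame(
    dataset = c("all_pairs", "more_specific", "less_specific", "unconnected"),
    n_pairs = c(nrow(results$pairTable), nrow(results$moreSpecific),
                nrow(results$lessSpecific), nrow(results$unconnected)))
  put(counts, "pairs_report.tsv")

  idxDf <- rbind(
    data.frame(dataset = "more_specific",
               index = results$moreSpecific$index),
    data.frame(dataset = "less_specific",
               index = results$lessSpecific$index))
  if (nrow(idxDf)) {
    p <- ggplot(idxDf, aes(x = index, fill = dataset)) +
      geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
      labs(x = "hypergeometric index", y = "pairs") + theme_bw()
    written <- c(written, .writeFigure(p, idxDf, "index_distribution",
                                       dir, cfg))
  }

  prev <- phenotypePrevalence(results$cohort)
  put(prev, "phenotype_prevalence.tsv")
  prevPairs <- rbind(
    data.frame(dataset = "more_specific",
               prevalence = pairPrevalence(results$moreSpecific, prev)),
    data.frame(dataset = "less_specific",
               prevalence = pairPrevalence(results$lessSpecific, prev)))
  if (nrow(prevPairs)) {
    p <- ggplot(prevPairs, aes(x = dataset, y = prevalence)) +
      geom_boxplot() + labs(y = "mean pair prevalence (%)") + theme_bw()
    written <- c(written, .writeFigure(p, prevPairs, "pair_prevalence",
                                       dir, cfg))
  }

  ov <- results$validation$pairDiseaseOverlap
  if (!is.null(ov)) {
    ovDf <- do.call(rbind, lapply(names(ov), function(thr)
      data.frame(threshold = thr, dataset = names(ov[[thr]]),
                 n_pairs = unname(ov[[thr]]))))
    p <- ggplot(ovDf, aes(x = dataset, y = n_pairs, fill = threshold)) +
      geom_col(position = position_dodge()) + theme_bw() +
      labs(y = "pairs overlapping diseases") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    written <- c(written, .writeFigure(p, ovDf, "pair_disease_overlap",
                                       dir, cfg))
  }

  cm <- results$validation$comention
  if (!is.null(cm)) {
    cmDf <- rbind(
      data.frame(dataset = "more_specific", p = cm$more_specific),
      data.frame(dataset = "links_random_more", p = cm$links_random_more))
    cmDf <- cmDf[!is.na(cmDf$p), , drop = FALSE]
    if (nrow(cmDf)) {
      p <- ggplot(cmDf, aes(x = dataset, y = p)) + geom_boxplot() +
        labs(y = "co-mention p-value") + theme_bw()
      written <- c(written, .writeFigure(p, cmDf, "comention_pvalues",
                                         dir, cfg))
    }
  }

  ## ---- clustering report --------------------------------------------
  cnt <- function(tab) if (!is.null(tab) && nrow(tab))
    .clusterCounts(tab) else c(total = 0, coherent = 0, disease = 0, both = 0)
  rndMean <- function(m) if (!is.null(m)) rowMeans(m) else
    c(total = NA, coherent = NA, disease = NA, both = NA)
  clRep <- rbind(
    data.frame(dataset = "more_specific", t(cnt(results$clusters))),
    data.frame(dataset = "less_specific", t(cnt(results$clustersLess))),
    data.frame(dataset = "links_random_more",
               t(rndMean(results$linksRandomClusterCounts$more))),
    data.frame(dataset = "links_random_less",
               t(rndMean(results$linksRandomClusterCounts$less))))
  put(clRep, "clustering_report.tsv")
  clLong <- stats::reshape(clRep, direction = "long",
                           varying = c("total", "coherent", "disease", "both"),
                           v.names = "n", times = c("total", "coherent",
                                                    "disease", "both"),
                           timevar = "measure")
  p <- ggplot(clLong, aes(x = dataset, y = n, fill = measure)) +
    geom_col(position = position_dodge()) + theme_bw() +
    labs(y = "clusters") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  written <- c(written, .writeFigure(p, clRep, "cluster_counts", dir, cfg))

  ## ---- cluster details ----------------------------------------------
  cl <- results$clusters
  if (!is.null(cl) && nrow(cl)) {
    det <- .sortClusterReport(cl)
    diseases <- results$clusterDiseases
    det$phenotypes <- vapply(det$phenotypes, paste, "", collapse = ";")
    det$coherent_funsys <- vapply(det$coherent_funsys, function(q)
      paste(sprintf("%s(%.2f)", names(q), q), collapse = ";"), "")
    det$diseases <- vapply(det$cluster_id, function(id) {
      d <- diseases[[id]]
      if (is.null(d) || !nrow(d)) "" else
        paste(sprintf("%s(missing=%d)", d$disease_id, d$n_missing),
              collapse = ";")
    }, "")
    det$supporting_patients <- vapply(strsplit(det$phenotypes, ";"),
                                      function(ph) {
      sum(vapply(phenotypeSets(results$cohort), function(s)
        length(intersect(s, ph)) > 0L, logical(1)))
    }, integer(1))
    put(det, "cluster_details.tsv")
  } else {
    put(data.frame(cluster_id = character(), n_nodes = integer(),
                   n_edges = integer(), trivial = logical(),
                   coherent = logical(), disease_overlap = logical(),
                   phenotypes = character(), coherent_funsys = character(),
                   diseases = character(),
                   supporting_patients = integer()),
        "cluster_details.tsv")
  }

  ## ---- patient report -----------------------------------------------
  ps <- results$validation$patientSupport
  if (!is.null(ps)) {
    put(ps$perPatient, "patient_report.tsv")
    put(data.frame(statistic = c("patients_ge2", "patients_ge3"),
                   real = unname(ps$real),
                   null_mean = unname(ps$nullMean),
                   null_sd = unname(ps$nullSd)),
        "patient_support_summary.tsv")
  }
  mem <- results$validation$membership
  if (!is.null(mem) && nrow(mem)) {
    put(mem, "cluster_membership.tsv")
    p <- ggplot(mem, aes(x = n_phenotypes, y = n_clusters,
                         size = n_patients)) +
      ggplot2::geom_point(alpha = 0.7) + theme_bw() +
      labs(x = "phenotypes per patient", y = "clusters touched")
    written <- c(written, .writeFigure(p, mem, "cluster_membership_fig",
                                       dir, cfg))
  }

  sr <- results$sorRandomization
  if (!is.null(sr)) {
    put(data.frame(
      statistic = c("phenotype_funsys_associations", "distinct_phenotypes"),
      real = c(sr$realAssociations, sr$realPhenotypes),
      null_mean = c(mean(sr$nullAssociations), mean(sr$nullPhenotypes)),
      null_sd = c(sd(sr$nullAssociations), sd(sr$nullPhenotypes)),
      null_max = c(max(sr$nullAssociations), max(sr$nullPhenotypes))),
      "sor_randomization.tsv")
  }
  invisible(written)
}
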