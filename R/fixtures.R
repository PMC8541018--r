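# Packaged reference tables for cannabidiol (CBD) in the neuropathic
# component of osteoarthritis, the pipeline's worked example.

#' Path to a packaged data file
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
netpharm_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "netpharm")))
  }
  path <- system.file("extdata", file, package = "netpharm")
  if (path == "") stop("no packaged data file '", file, "'")
  path
}

#' Published degree ranking of the CBD common targets
#'
#' The ten CBD targets associated with both osteoarthritis and neuropathic
#' pain, with their vertex degree in the dual-disease PPI network, the most
#' potent reported activity (nM) and the pharmacodynamic interaction mode,
#' as published. `source_ref` carries the reference tag of the activity
#' report.
#'
#' @return Data frame `symbol`, `vertex_degree`, `activity_nM`,
#'   `interaction_mode`, `source_ref`, in the published (degree-ranked)
#'   row order.
#' @examples
#' load_table2_fixture()
#' @export
load_table2_fixture <- function() {
  df <- utils::read.table(netpharm_extdata("cbd_common_target_degrees.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric",
                                         "character", "character"))
  df
}

#' Published biological-process enrichment of the CBD common targets
#'
#' The gene-ontology biological processes reported as over-represented among
#' the ten common targets (whole-genome background), with the published
#' p-values and false discovery rates. Shipped for schema reference and for
#' the gene lists; the numeric values depend on an annotation snapshot and
#' are not recomputed by this package.
#'
#' @return Data frame `term_name`, `members` (list column of symbol
#'   vectors), `p_value`, `fdr`.
#' @export
load_table1_fixture <- function() {
  df <- utils::read.table(netpharm_extdata("cbd_common_target_enrichment.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$members <- strsplit(df$members, ",", fixed = TRUE)
  df
}

#' Path to the synthetic 66-target curation stand-in
#'
#' A synthetic drug-target curation table (66 targets, mixed nM/uM units and
#' Ki/EC50/IC50 measures) constructed to mirror the summary structure of the
#' published CBD curation: exactly 30 targets have a most-potent activity
#' below 2 uM, and the ten common targets keep their published activities.
#' The remaining rows are invented; the file is a stand-in for the deposited
#' supplementary table, not a transcription of it.
#'
#' @return Path to the CSV, readable with [read_affinity_table()].
#' @export
synthetic_curation_path <- function() {
  netpharm_extdata("synthetic_cbd_curation_66targets.csv")
}
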