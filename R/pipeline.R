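#' Pipeline configuration
#'
#' Validates paths and parameters for a full end-to-end run. All input paths
#' must exist at validation time; numeric parameters are range-checked.
#'
#' @param affinity Path to the drug-target affinity table.
#' @param disease_a,disease_b Paths to the two disease-association tables.
#' @param edges Path to the scored PPI edge list.
#' @param gmt Path to the GMT gene-set collection.
#' @param out_dir Output directory for stage files and the report.
#' @param disease_a_label,disease_b_label Disease labels.
#' @param threshold_nM Potency ceiling (strict `<`).
#' @param min_combined_score Inclusive PPI confidence threshold (0-1000).
#' @param min_association_score Minimum disease-association score in \[0,1\].
#' @param background_size Enrichment background size (genome size); `NULL`
#'   uses the union of the GMT members.
#' @param min_term_size Smallest testable gene set.
#' @param inflation,expansion,tolerance,max_iterations MCL parameters.
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(affinity, disease_a, disease_b, edges, gmt,
                            out_dir,
                            disease_a_label = "disease A",
                            disease_b_label = "disease B",
                            threshold_nM = 2000,
                            min_combined_score = 400,
                            min_association_score = 0,
                            background_size = 20000,
                            min_term_size = 2,
                            inflation = 2, expansion = 2L,
                            tolerance = 1e-6, max_iterations = 100L,
                            seed = 1L) {
  paths <- c(affinity = affinity, disease_a = disease_a,
             disease_b = disease_b, edges = edges, gmt = gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input path does not exist: ", missing[1L], " (", names(missing)[1L], ")")
  }
  stopifnot(threshold_nM > 0,
            min_combined_score >= 0, min_combined_score <= 1000,
            min_association_score >= 0, min_association_score <= 1,
            is.null(background_size) || background_size >= 1,
            min_term_size >= 1, inflation > 1, expansion >= 2,
            tolerance > 0, max_iterations >= 1)
  structure(list(affinity = affinity, disease_a = disease_a,
                 disease_b = disease_b, edges = edges, gmt = gmt,
                 out_dir = out_dir,
                 disease_a_label = disease_a_label,
                 disease_b_label = disease_b_label,
                 threshold_nM = threshold_nM,
                 min_combined_score = min_combined_score,
                 min_association_score = min_association_score,
                 background_size = background_size,
                 min_term_size = min_term_size,
                 inflation = inflation, expansion = as.integer(expansion),
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p) && file.exists(file.path(base, p))) file.path(base, p) else p
  }
  args <- raw
  for (key in c("affinity", "disease_a", "disease_b", "edges", "gmt")) {
    args[[key]] <- resolve(raw[[key]])
  }
  do.call(pipeline_config, args)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: ingest and validation of all inputs; potency
#' filtering of the drug-target table; three-way Venn partition of the
#' retained drug targets against the two disease sets; construction of the
#' scored PPI network restricted to the dual-disease context; drug-anchored
#' vertex degrees and degree ranking of the common targets; Markov
#' clustering of the common-target subnetwork; and over-representation
#' analysis of the common targets against the GMT collection. All stage
#' outputs are written as plain TSV/JSON under `out_dir` together with a
#' consolidated `report.json`; an identical configuration over identical
#' inputs yields byte-identical report bodies (no timestamps are recorded).
#'
#' @param config A `pipeline_config`.
#' @return An object of class `netpharm_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  log_msg("stage 1/6: ingest")
  records <- read_affinity_table(config$affinity)
  assoc_a <- read_association_table(config$disease_a, config$disease_a_label,
                                    min_score = config$min_association_score)
  assoc_b <- read_association_table(config$disease_b, config$disease_b_label,
                                    min_score = config$min_association_score)
  edges <- read_edge_list(config$edges)
  collection <- read_gmt(config$gmt)

  log_msg("stage 2/6: potency filter (< ", config$threshold_nM, " nM)")
  filt <- filter_by_potency(records, config$threshold_nM)
  write_potency_filter(filt, file.path(config$out_dir, "retained.tsv"))
  log_msg("  retained ", nrow(filt$retained), " of ", filt$n_input_symbols, " targets")

  log_msg("stage 3/6: Venn partition")
  set_a <- association_symbols(assoc_a)
  set_b <- association_symbols(assoc_b)
  venn <- venn_partition(retained_symbols(filt), set_a, set_b,
                         labels = c("drug", config$disease_a_label,
                                    config$disease_b_label))
  write_venn(venn, file.path(config$out_dir, "venn.json"))
  common <- common_targets(retained_symbols(filt), set_a, set_b)
  log_msg("  ", length(common), " common targets")

  log_msg("stage 4/6: context network (combined_score >= ",
          config$min_combined_score, ")")
  network <- build_network(edges, config$min_combined_score)
  dual <- intersect(set_a, set_b)
  context <- restrict_to_context(network, dual)
  log_msg("  ", length(context$nodes), " nodes, ", nrow(context$edges),
          " edges in the dual-disease context")
  degrees <- drug_anchored_degrees(context, common, affinity = filt$retained)
  ranked <- rank_targets(degrees)
  utils::write.table(
    data.frame(symbol = ranked$symbol, vertex_degree = ranked$vertex_degree,
               activity_nM = ranked$activity_nM,
               interaction_mode = ranked$interaction_mode),
    file.path(config$out_dir, "ranked.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  export_graph(context, degrees, file.path(config$out_dir, "context.graphml"))

  log_msg("stage 5/6: Markov clustering of the common-target subnetwork")
  subnet <- restrict_to_context(context, common)
  subnet$nodes <- sort(unique(c(subnet$nodes, common)))  # keep degree-0 targets
  clusters <- if (length(subnet$nodes) > 0L) {
    cl <- mcl_cluster(subnet, inflation = config$inflation,
                      expansion = config$expansion,
                      tolerance = config$tolerance,
                      max_iterations = config$max_iterations)
    write_clusters(cl, file.path(config$out_dir, "clusters.tsv"))
    cl
  } else {
    warning("empty common-target subnetwork; clustering skipped")
    NULL
  }

  log_msg("stage 6/6: over-representation analysis")
  enrichment <- if (length(common) > 0L) {
    en <- enrich(common, collection, background = config$background_size,
                 min_term_size = config$min_term_size)
    write_enrichment(en, file.path(config$out_dir, "enrichment.tsv"))
    en
  } else {
    warning("empty common-target list; enrichment skipped")
    NULL
  }

  provenance <- list(
    inputs = lapply(
      stats::setNames(nm = c("affinity", "disease_a", "disease_b", "edges", "gmt")),
      function(k) list(path = config[[k]],
                       md5 = unname(tools::md5sum(config[[k]])))),
    parameters = unclass(config)[setdiff(names(config),
                                c("affinity", "disease_a", "disease_b",
                                  "edges", "gmt", "out_dir"))],
    package_version = as.character(utils::packageVersion("netpharm")))

  report <- structure(list(
    venn = list(labels = venn$labels,
                region_counts = as.list(venn$region_counts)),
    retained_count = nrow(filt$retained),
    common_targets = common,
    ranked_targets = ranked,
    clusters = if (is.null(clusters)) NULL else as.list(clusters$clusters),
    enrichment = enrichment,
    provenance = provenance
  ), class = "netpharm_report")

  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  report
}

#' @export
print.netpharm_report <- function(x, ...) {
  cat("netpharm pipeline report\n")
  cat("  retained drug targets: ", x$retained_count, "\n", sep = "")
  rc <- x$venn$region_counts
  cat("  Venn regions (", paste(x$venn$labels, collapse = "/"), "): ",
      paste(sprintf("%s=%d", names(rc), unlist(rc)), collapse = " "), "\n", sep = "")
  cat("  common targets (", length(x$common_targets), "): ",
      paste(x$common_targets, collapse = ", "), "\n", sep = "")
  if (!is.null(x$ranked_targets) && nrow(x$ranked_targets) > 0L) {
    cat("  top-ranked target: ", x$ranked_targets$symbol[1L], " (degree ",
        x$ranked_targets$vertex_degree[1L], ")\n", sep = "")
  }
  if (!is.null(x$enrichment) && nrow(x$enrichment) > 0L) {
    cat("  top enriched term: ", x$enrichment$term_id[1L], " (p = ",
        format(x$enrichment$p_value[1L], digits = 3), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.netpharm_report <- function(object, ...) {
  print(object)
  if (!is.null(object$ranked_targets)) {
    cat("\nRanked targets:\n")
    print(object$ranked_targets)
  }
  if (!is.null(object$enrichment)) {
    cat("\nEnrichment (top 10):\n")
    print(utils::head(object$enrichment, 10L))
  }
  invisible(object)
}
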