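#' Specification for the synthetic fixture suite
#'
#' Defines the statistical structure of a full set of synthetic pipeline
#' inputs: a drug-target curation table, two disease-association exports, a
#' scored PPI edge list with planted hubs and a GMT collection with one
#' planted over-represented term. The defaults emulate the worked example's
#' study conditions: 66 curated drug targets of which 30 fall below the 2 uM
#' potency ceiling, disease sets of 2473 and 970 targets sharing 475, and 10
#' drug targets common to both diseases. Every generator draws from its own
#' named pseudo-random stream derived from `seed`, so adding a generator
#' never perturbs fixtures produced by another, and each generator emits a
#' sidecar `*.truth.json` with its planted ground truth.
#'
#' @param seed Integer master seed.
#' @param universe_size Number of gene symbols in the synthetic genome.
#' @param n_drug_targets Rows in the curation table (one per symbol).
#' @param frac_below_threshold Fraction of drug targets planted below
#'   `threshold_nM`; exactly `round(frac * n)` symbols end up below.
#' @param threshold_nM Potency ceiling the plant is calibrated against.
#' @param disease_sizes Sizes of the two disease-association sets.
#' @param disease_labels Labels for the two diseases.
#' @param n_dual Number of symbols associated with both diseases.
#' @param n_common Drug targets (below threshold) planted in both diseases.
#' @param n_drug_a_only,n_drug_b_only Below-threshold drug targets planted
#'   in exactly one disease.
#' @param ppi_n_nodes Non-drug dual-disease proteins in the PPI graph (the
#'   common drug targets are always included).
#' @param ppi_edge_prob Erdos-Renyi edge probability of the base graph.
#' @param n_planted_hubs Number of common drug targets given guaranteed
#'   extra edges.
#' @param planted_hub_extra_degree Guaranteed extra edges per planted hub.
#' @param gmt_n_terms Number of gene sets (first one is the planted term).
#' @param term_size_range Inclusive range of gene-set sizes.
#' @param planted_term_overlap Common targets planted into the first term.
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1,
                           universe_size = 3500,
                           n_drug_targets = 66,
                           frac_below_threshold = 30 / 66,
                           threshold_nM = 2000,
                           disease_sizes = c(2473, 970),
                           disease_labels = c("osteoarthritis", "neuropathic pain"),
                           n_dual = 475,
                           n_common = 10,
                           n_drug_a_only = 12,
                           n_drug_b_only = 3,
                           ppi_n_nodes = 200,
                           ppi_edge_prob = 0.05,
                           n_planted_hubs = 1,
                           planted_hub_extra_degree = 50,
                           gmt_n_terms = 50,
                           term_size_range = c(10, 40),
                           planted_term_overlap = 8) {
  spec <- list(seed = as.integer(seed), universe_size = as.integer(universe_size),
               n_drug_targets = as.integer(n_drug_targets),
               frac_below_threshold = frac_below_threshold,
               threshold_nM = threshold_nM,
               disease_sizes = as.integer(disease_sizes),
               disease_labels = as.character(disease_labels),
               n_dual = as.integer(n_dual), n_common = as.integer(n_common),
               n_drug_a_only = as.integer(n_drug_a_only),
               n_drug_b_only = as.integer(n_drug_b_only),
               ppi_n_nodes = as.integer(ppi_n_nodes),
               ppi_edge_prob = ppi_edge_prob,
               n_planted_hubs = as.integer(n_planted_hubs),
               planted_hub_extra_degree = as.integer(planted_hub_extra_degree),
               gmt_n_terms = as.integer(gmt_n_terms),
               term_size_range = as.integer(term_size_range),
               planted_term_overlap = as.integer(planted_term_overlap))

  if (spec$frac_below_threshold < 0 || spec$frac_below_threshold > 1) {
    stop("frac_below_threshold must be in [0, 1]")
  }
  if (spec$ppi_edge_prob < 0 || spec$ppi_edge_prob > 1) {
    stop("ppi_edge_prob must be in [0, 1]")
  }
  sizes <- c(spec$universe_size, spec$n_drug_targets, spec$disease_sizes,
             spec$n_dual, spec$n_common, spec$n_drug_a_only, spec$n_drug_b_only,
             spec$ppi_n_nodes, spec$gmt_n_terms)
  if (any(sizes < 0)) stop("all sizes must be non-negative")
  spec$n_below <- as.integer(round(spec$frac_below_threshold * spec$n_drug_targets))

  if (spec$n_common + spec$n_drug_a_only + spec$n_drug_b_only > spec$n_below) {
    stop("infeasible overlap request: planted disease overlaps exceed the ",
         "number of below-threshold drug targets")
  }
  if (spec$n_common > spec$n_dual || spec$n_dual > min(spec$disease_sizes)) {
    stop("infeasible overlap request: n_common <= n_dual <= min(disease_sizes) violated")
  }
  a_only_nd <- spec$disease_sizes[1L] - spec$n_dual - spec$n_drug_a_only
  b_only_nd <- spec$disease_sizes[2L] - spec$n_dual - spec$n_drug_b_only
  if (a_only_nd < 0 || b_only_nd < 0) {
    stop("infeasible overlap request: disease set smaller than its planted overlaps")
  }
  pool_needed <- (spec$n_dual - spec$n_common) + a_only_nd + b_only_nd
  if (pool_needed > spec$universe_size - spec$n_drug_targets) {
    stop("infeasible overlap request: universe too small for the requested sets")
  }
  if (spec$ppi_n_nodes > spec$n_dual - spec$n_common) {
    stop("ppi_n_nodes cannot exceed the number of non-drug dual-disease symbols")
  }
  if (spec$planted_hub_extra_degree > spec$ppi_n_nodes + spec$n_common - 1L) {
    stop("planted_hub_extra_degree cannot exceed n_nodes - 1")
  }
  if (spec$n_planted_hubs > spec$n_common) {
    stop("cannot plant more hubs than common drug targets")
  }
  if (length(spec$term_size_range) != 2L ||
      spec$term_size_range[1L] > spec$term_size_range[2L]) {
    stop("term_size_range must be an increasing pair")
  }
  if (spec$planted_term_overlap > spec$n_common ||
      spec$planted_term_overlap > spec$term_size_range[1L]) {
    stop("planted_term_overlap must fit inside n_common and the smallest term")
  }
  structure(spec, class = "synthetic_spec")
}

# Deterministic planted set structure shared by all generators (own stream).
plant_sets <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_stream(spec$seed, "sets", {
    universe <- sprintf("G%05d", seq_len(spec$universe_size))
    drug <- sort(sample(universe, spec$n_drug_targets))
    below <- sort(sample(drug, spec$n_below))
    common <- sort(sample(below, spec$n_common))
    rest <- setdiff(below, common)
    a_only_drug <- sort(sample(rest, spec$n_drug_a_only))
    rest <- setdiff(rest, a_only_drug)
    b_only_drug <- sort(sample(rest, spec$n_drug_b_only))

    pool <- setdiff(universe, drug)
    dual_nondrug <- sort(sample(pool, spec$n_dual - spec$n_common))
    pool <- setdiff(pool, dual_nondrug)
    n_a_only <- spec$disease_sizes[1L] - spec$n_dual - spec$n_drug_a_only
    a_only_nd <- sort(sample(pool, n_a_only))
    pool <- setdiff(pool, a_only_nd)
    n_b_only <- spec$disease_sizes[2L] - spec$n_dual - spec$n_drug_b_only
    b_only_nd <- sort(sample(pool, n_b_only))

    disease_a <- sort(c(common, a_only_drug, dual_nondrug, a_only_nd))
    disease_b <- sort(c(common, b_only_drug, dual_nondrug, b_only_nd))

    region_counts <- c(
      "100" = spec$n_below - spec$n_common - spec$n_drug_a_only - spec$n_drug_b_only,
      "010" = n_a_only,
      "001" = n_b_only,
      "110" = spec$n_drug_a_only,
      "101" = spec$n_drug_b_only,
      "011" = spec$n_dual - spec$n_common,
      "111" = spec$n_common)

    list(universe = universe, drug = drug, below = below, common = common,
         disease_a = disease_a, disease_b = disease_b,
         dual_nondrug = dual_nondrug, region_counts = region_counts)
  })
}

.write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic drug-target affinity table
#'
#' One row per drug target with log-uniform activities, mixed units (pM, nM,
#' uM) and mixed Ki/EC50/IC50 measures; exactly `round(frac_below_threshold *
#' n_drug_targets)` symbols have activity below `threshold_nM`. Writes
#' `affinity.csv` plus `affinity.truth.json` (retained symbols).
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if missing).
#' @return List with `path`, `truth_path`, `truth`.
#' @export
gen_affinity_table <- function(spec, dir) {
  sets <- plant_sets(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_drug_targets
  with_stream(spec$seed, "affinity", {
    below <- sets$drug %in% sets$below
    act <- numeric(n)
    act[below] <- exp(stats::runif(sum(below), log(10), log(spec$threshold_nM - 10)))
    act[!below] <- exp(stats::runif(sum(!below), log(spec$threshold_nM + 10), log(1e5)))
    act <- round(act, 1)
    unit <- sample(c("nM", "uM", "pM"), n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    shown <- ifelse(unit == "uM", act / 1000, ifelse(unit == "pM", act * 1000, act))
    measure <- sample(.activity_measures, n, replace = TRUE)
    mode <- sample(.interaction_modes, n, replace = TRUE)
    df <- data.frame(target = sets$drug, activity = shown, unit = unit,
                     measure = measure, mode = mode,
                     source = sprintf("synthetic-seed%d", spec$seed),
                     stringsAsFactors = FALSE)
    path <- file.path(dir, "affinity.csv")
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    truth <- list(n_targets = n, threshold_nM = spec$threshold_nM,
                  n_retained = spec$n_below, retained = sets$below)
    truth_path <- file.path(dir, "affinity.truth.json")
    .write_truth(truth, truth_path)
    list(path = path, truth_path = truth_path, truth = truth)
  })
}

#' Generate synthetic disease-association tables
#'
#' Two association exports (`disease_a.tsv`, `disease_b.tsv`) with uniform
#' scores, planted so that the three-way Venn partition of (below-threshold
#' drug targets, disease A, disease B) has exactly the region counts recorded
#' in the sidecar `diseases.truth.json`.
#'
#' @inheritParams gen_affinity_table
#' @return List with `path_a`, `path_b`, `truth_path`, `truth`.
#' @export
gen_disease_tables <- function(spec, dir) {
  sets <- plant_sets(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_stream(spec$seed, "diseases", {
    write_disease <- function(symbols, file) {
      df <- data.frame(symbol = symbols,
                       overall_score = round(stats::runif(length(symbols), 0.01, 0.999), 3),
                       stringsAsFactors = FALSE)
      utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    path_a <- file.path(dir, "disease_a.tsv")
    path_b <- file.path(dir, "disease_b.tsv")
    write_disease(sets$disease_a, path_a)
    write_disease(sets$disease_b, path_b)
    truth <- list(labels = c("drug", spec$disease_labels),
                  region_counts = as.list(sets$region_counts),
                  common = sets$common,
                  n_dual = spec$n_dual)
    truth_path <- file.path(dir, "diseases.truth.json")
    .write_truth(truth, truth_path)
    list(path_a = path_a, path_b = path_b, truth_path = truth_path, truth = truth)
  })
}

#' Generate a synthetic scored PPI edge list
#'
#' An Erdos-Renyi base graph over the common drug targets plus a sample of
#' the non-drug dual-disease proteins, with guaranteed extra edges added to
#' the planted hub(s) and combined scores uniform on \[400, 1000\]. Writes
#' the STRING-dialect `ppi_edges.tsv` (space-separated) plus
#' `ppi.truth.json` with the exact per-common-target incident-edge counts
#' (tabulated directly from the emitted edges) and the expected top-ranked
#' target.
#'
#' @inheritParams gen_affinity_table
#' @return List with `path`, `truth_path`, `truth`.
#' @export
gen_ppi_network <- function(spec, dir) {
  sets <- plant_sets(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_stream(spec$seed, "ppi", {
    nodes <- sort(c(sets$common, sample(sets$dual_nondrug, spec$ppi_n_nodes)))
    n <- length(nodes)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    draw <- stats::runif(nrow(idx)) < spec$ppi_edge_prob
    ea <- nodes[idx[draw, 1L]]
    eb <- nodes[idx[draw, 2L]]

    hubs <- if (spec$n_planted_hubs > 0L) {
      sort(sample(sets$common, spec$n_planted_hubs))
    } else character()
    for (h in hubs) {
      nb <- unique(c(eb[ea == h], ea[eb == h]))
      cand <- setdiff(nodes, c(h, nb))
      extra <- sample(cand, min(spec$planted_hub_extra_degree, length(cand)))
      ea <- c(ea, pmin(h, extra))
      eb <- c(eb, pmax(h, extra))
    }
    ord <- order(ea, eb)
    ea <- ea[ord]; eb <- eb[ord]
    score <- sample(400:1000, length(ea), replace = TRUE)
    df <- data.frame(protein1 = ea, protein2 = eb, combined_score = score,
                     stringsAsFactors = FALSE)
    path <- file.path(dir, "ppi_edges.tsv")
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)

    # Independent tabulation of planted drug-anchored degrees.
    degrees <- vapply(sets$common, function(s) sum(ea == s) + sum(eb == s), 0L)
    ordr <- order(-degrees, names(degrees))
    truth <- list(n_nodes = n, n_edges = length(ea),
                  hubs = hubs,
                  degrees = as.list(degrees),
                  top_target = names(degrees)[ordr][1L])
    truth_path <- file.path(dir, "ppi.truth.json")
    .write_truth(truth, truth_path)
    list(path = path, truth_path = truth_path, truth = truth)
  })
}

#' Generate a synthetic GMT gene-set collection
#'
#' `gmt_n_terms` gene sets over the synthetic genome: the first term is
#' planted to contain `planted_term_overlap` of the common drug targets;
#' the remaining terms are uniform draws from the genome, so their overlap
#' with any fixed query follows the hypergeometric null. Writes
#' `collection.gmt` plus `gmt.truth.json`.
#'
#' @inheritParams gen_affinity_table
#' @return List with `path`, `truth_path`, `truth`.
#' @export
gen_gmt <- function(spec, dir) {
  sets <- plant_sets(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_stream(spec$seed, "gmt", {
    sizes <- sample(seq.int(spec$term_size_range[1L], spec$term_size_range[2L]),
                    spec$gmt_n_terms, replace = TRUE)
    planted_in <- sort(sample(sets$common, spec$planted_term_overlap))
    filler <- sample(setdiff(sets$universe, sets$common),
                     sizes[1L] - spec$planted_term_overlap)
    terms <- vector("list", spec$gmt_n_terms)
    terms[[1L]] <- list(term_id = "SYN:0001", term_name = "planted process",
                        members = sort(c(planted_in, filler)))
    for (i in seq_len(spec$gmt_n_terms - 1L) + 1L) {
      terms[[i]] <- list(term_id = sprintf("SYN:%04d", i),
                         term_name = sprintf("background process %d", i),
                         members = sort(sample(sets$universe, sizes[i])))
    }
    names(terms) <- vapply(terms, `[[`, "", "term_id")
    collection <- structure(terms, class = "gene_set_collection")
    path <- file.path(dir, "collection.gmt")
    write_gmt(collection, path)
    truth <- list(planted_term_id = "SYN:0001",
                  planted_overlap = spec$planted_term_overlap,
                  planted_members = planted_in,
                  background_size = spec$universe_size,
                  n_terms = spec$gmt_n_terms)
    truth_path <- file.path(dir, "gmt.truth.json")
    .write_truth(truth, truth_path)
    list(path = path, truth_path = truth_path, truth = truth)
  })
}

#' Generate the full synthetic fixture suite
#'
#' Runs all four generators into one directory and returns their paths and
#' planted truths, ready to be fed to [pipeline_config()].
#'
#' @inheritParams gen_affinity_table
#' @return List with elements `affinity`, `diseases`, `ppi`, `gmt` (each a
#'   generator's return value) and `spec`.
#' @export
gen_fixture_suite <- function(spec, dir) {
  list(affinity = gen_affinity_table(spec, dir),
       diseases = gen_disease_tables(spec, dir),
       ppi = gen_ppi_network(spec, dir),
       gmt = gen_gmt(spec, dir),
       spec = spec)
}
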