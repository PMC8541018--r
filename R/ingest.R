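#' Normalize a gene symbol
#'
#' Canonicalizes identifiers so that drug-target tables, disease-association
#' exports and PPI edge lists can be compared symbol-for-symbol: whitespace is
#' stripped, the symbol is uppercased, and an optional alias map is applied
#' after casing (e.g. `CB2 -> CNR2`). Alias values are assumed to be canonical
#' symbols themselves, which makes the operation idempotent.
#'
#' @param raw Character vector of raw identifiers.
#' @param alias_map Optional named character vector mapping (uppercased)
#'   aliases to canonical symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbol("Trpv1")
#' normalize_symbol("CB2", alias_map = c(CB2 = "CNR2"))
#' @export
normalize_symbol <- function(raw, alias_map = NULL) {
  if (length(raw) == 0L) return(character())
  out <- toupper(trimws(as.character(raw)))
  bad <- which(is.na(out) | out == "")
  if (length(bad) > 0L) {
    stop("empty or missing gene symbol at position ", bad[1L])
  }
  if (!is.null(alias_map)) {
    names(alias_map) <- toupper(trimws(names(alias_map)))
    alias_map <- toupper(trimws(alias_map))
    hit <- out %in% names(alias_map)
    out[hit] <- unname(alias_map[out[hit]])
  }
  out
}

.activity_measures <- c("Ki", "EC50", "IC50")
.interaction_modes <- c("full agonist", "partial agonist", "antagonist",
                        "inhibitor", "positive allosteric modulator",
                        "negative allosteric modulator", "other")

.unit_to_nM <- function(unit) {
  u <- tolower(trimws(unit))
  u[u == "µm"] <- "um"
  factor <- c(pm = 1e-3, nm = 1, um = 1e3)[u]
  unname(factor)
}

#' Read a drug-target affinity table
#'
#' Parses a curated drug-target table (CSV or TSV, separator sniffed) with
#' columns `target`, `activity`, `unit`, `measure`, `mode` and optionally
#' `source`. Activities are converted to nanomolar (accepted units: pM, nM,
#' uM/µM). When the `unit` column is absent, a unit suffix inside the
#' activity field (e.g. `"2 µM"`) is honoured; a bare number is taken as nM.
#' Rows are preserved in input order; duplicate symbols are kept (aggregation
#' happens in [filter_by_potency()]).
#'
#' @param path Path to the table.
#' @param alias_map Optional alias map passed to [normalize_symbol()].
#' @return A data frame with columns `target_symbol`, `activity_value_nM`,
#'   `activity_measure`, `interaction_mode`, `source_ref`.
#' @export
read_affinity_table <- function(path, alias_map = NULL) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  names(df) <- tolower(trimws(names(df)))
  for (col in c("target", "activity", "measure", "mode")) {
    if (!col %in% names(df)) stop("affinity table is missing column '", col, "'")
  }
  n <- nrow(df)
  if (n == 0L) {
    log_msg("affinity table ", path, ": 0 data rows")
    return(data.frame(target_symbol = character(), activity_value_nM = numeric(),
                      activity_measure = character(), interaction_mode = character(),
                      source_ref = character(), stringsAsFactors = FALSE))
  }

  value_nM <- numeric(n)
  for (i in seq_len(n)) {
    raw <- trimws(df$activity[i])
    unit <- if ("unit" %in% names(df)) trimws(df$unit[i]) else ""
    if (is.na(unit) || unit == "") {
      m <- regmatches(raw, regexec("^([-+0-9.eE]+)\\s*([a-zA-Zµ]*)$", raw))[[1L]]
      if (length(m) == 3L && m[3L] != "") {
        raw <- m[2L]
        unit <- m[3L]
      } else {
        unit <- "nM"
      }
    }
    val <- suppressWarnings(as.numeric(raw))
    if (is.na(val)) {
      stop("non-numeric activity in row ", i, ", column 'activity': '", df$activity[i], "'")
    }
    fac <- .unit_to_nM(unit)
    if (is.na(fac)) {
      stop("unknown activity unit in row ", i, ", column 'unit': '", unit, "'")
    }
    val <- val * fac
    if (val <= 0) {
      stop("non-positive activity in row ", i, ", column 'activity'")
    }
    value_nM[i] <- val
  }

  measure <- trimws(df$measure)
  midx <- match(toupper(measure), toupper(.activity_measures))
  if (anyNA(midx)) {
    stop("unknown activity measure in row ", which(is.na(midx))[1L],
         ", column 'measure' (expected one of ", paste(.activity_measures, collapse = ", "), ")")
  }
  mode <- tolower(trimws(df$mode))
  bad <- which(!mode %in% .interaction_modes)
  if (length(bad) > 0L) {
    stop("unknown interaction mode in row ", bad[1L], ", column 'mode': '", df$mode[bad[1L]], "'")
  }

  out <- data.frame(
    target_symbol = normalize_symbol(df$target, alias_map),
    activity_value_nM = value_nM,
    activity_measure = .activity_measures[midx],
    interaction_mode = mode,
    source_ref = if ("source" %in% names(df)) as.character(df$source) else NA_character_,
    stringsAsFactors = FALSE
  )
  log_msg("affinity table ", path, ": ", n, " data rows")
  out
}

#' Write a drug-target affinity table
#'
#' Inverse of [read_affinity_table()]: activities are written in nM so that a
#' write/read round trip reproduces the in-memory value field by field.
#'
#' @param records Data frame as returned by [read_affinity_table()].
#' @param path Output path (TSV).
#' @export
write_affinity_table <- function(records, path) {
  out <- data.frame(target = records$target_symbol,
                    activity = records$activity_value_nM,
                    unit = "nM",
                    measure = records$activity_measure,
                    mode = records$interaction_mode,
                    source = records$source_ref,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease-association table
#'
#' Parses a disease-target export (TSV/CSV dialect of an Open Targets
#' download): a `symbol` column and an optional `overall_score` column with
#' association scores in \[0, 1\]. Duplicate symbols are collapsed keeping the
#' maximum score; entries with score below `min_score` are excluded.
#'
#' @param path Path to the table.
#' @param disease_label Free-text label for the disease.
#' @param min_score Minimum association score retained (default 0: any
#'   evidence counts).
#' @param alias_map Optional alias map passed to [normalize_symbol()].
#' @return An object of class `association_table`: a list with
#'   `disease_label` and `entries` (data frame `symbol`, `score`; `score` is
#'   `NA` for the scoreless dialect), entries sorted by symbol.
#' @export
read_association_table <- function(path, disease_label, min_score = 0,
                                   alias_map = NULL) {
  stopifnot(min_score >= 0, min_score <= 1)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  if (!"symbol" %in% names(df)) stop("association table is missing column 'symbol'")
  has_score <- "overall_score" %in% names(df)

  if (nrow(df) == 0L) {
    entries <- data.frame(symbol = character(), score = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    symbol <- normalize_symbol(df$symbol, alias_map)
    score <- if (has_score) as.numeric(df$overall_score) else rep(NA_real_, nrow(df))
    if (has_score) {
      bad <- which(is.na(score) | score < 0 | score > 1)
      if (length(bad) > 0L) {
        stop("association score outside [0,1] in row ", bad[1L])
      }
    }
    if (has_score) {
      agg <- tapply(score, symbol, max)
      entries <- data.frame(symbol = names(agg), score = unname(agg),
                            stringsAsFactors = FALSE)
      entries <- entries[entries$score >= min_score, , drop = FALSE]
    } else {
      entries <- data.frame(symbol = sort(unique(symbol)), score = NA_real_,
                            stringsAsFactors = FALSE)
    }
    entries <- entries[order(entries$symbol), , drop = FALSE]
    rownames(entries) <- NULL
  }
  log_msg("association table ", path, " (", disease_label, "): ",
          nrow(entries), " unique targets")
  structure(list(disease_label = disease_label, entries = entries),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat("Disease-association table:", x$disease_label, "\n")
  cat("  ", nrow(x$entries), " targets", sep = "")
  if (any(!is.na(x$entries$score))) {
    cat(", scores in [", format(min(x$entries$score, na.rm = TRUE)), ", ",
        format(max(x$entries$score, na.rm = TRUE)), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Extract the symbol set of an association table
#' @param x An `association_table`.
#' @return Character vector of symbols.
#' @export
association_symbols <- function(x) {
  stopifnot(inherits(x, "association_table"))
  x$entries$symbol
}

#' Write a disease-association table
#' @param x An `association_table`.
#' @param path Output path (TSV).
#' @export
write_association_table <- function(x, path) {
  stopifnot(inherits(x, "association_table"))
  out <- x$entries
  if (all(is.na(out$score))) {
    out <- out[, "symbol", drop = FALSE]
  } else {
    names(out) <- c("symbol", "overall_score")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style scored edge list
#'
#' Parses a protein-protein interaction edge list with columns `protein1`,
#' `protein2`, `combined_score` (space- or tab-separated, the STRING download
#' convention; scores are integers on the 0-1000 confidence scale). Endpoints
#' are normalized and put in canonical lexicographic order, self-loops are
#' dropped, and duplicate undirected pairs are collapsed keeping the maximum
#' combined score (the conservative merge for a confidence score).
#'
#' @param path Path to the edge list.
#' @param alias_map Optional alias map passed to [normalize_symbol()].
#' @return Data frame with columns `node_a`, `node_b`, `combined_score`
#'   (`node_a < node_b`), sorted by endpoints.
#' @export
read_edge_list <- function(path, alias_map = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "", check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  for (col in c("protein1", "protein2", "combined_score")) {
    if (!col %in% names(df)) stop("edge list is missing column '", col, "'")
  }
  if (nrow(df) == 0L) {
    log_msg("edge list ", path, ": 0 edges")
    return(data.frame(node_a = character(), node_b = character(),
                      combined_score = integer(), stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) | score < 0 | score > 1000 | score != round(score))
  if (length(bad) > 0L) {
    stop("combined_score must be an integer in [0, 1000]; offending row ", bad[1L])
  }
  a <- normalize_symbol(df$protein1, alias_map)
  b <- normalize_symbol(df$protein2, alias_map)
  self <- a == b
  n_self <- sum(self)
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  s2 <- as.integer(score[!self])
  key <- paste(a2, b2, sep = "\r")
  agg <- tapply(s2, key, max)
  n_dup <- length(key) - length(agg)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                    node_b = vapply(parts, `[`, "", 2L),
                    combined_score = as.integer(unname(agg)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  log_msg("edge list ", path, ": ", nrow(out), " unique edges (dropped ",
          n_self, " self-loops, collapsed ", n_dup, " duplicates)")
  out
}

#' Write a scored edge list
#' @param edges Data frame as returned by [read_edge_list()].
#' @param path Output path (TSV, STRING column names).
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(protein1 = edges$node_a, protein2 = edges$node_b,
                    combined_score = edges$combined_score,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Parses the standard tab-separated gene-set format: one set per line as
#' `term_id TAB description TAB member...`. Members are normalized and
#' deduplicated per term (first occurrence wins); lines with fewer than three
#' fields, empty member lists, or duplicate term ids are rejected with the
#' line number.
#'
#' @param path Path to the GMT file.
#' @param alias_map Optional alias map passed to [normalize_symbol()].
#' @return An object of class `gene_set_collection`: a list of terms, each a
#'   list with `term_id`, `term_name`, `members`.
#' @export
read_gmt <- function(path, alias_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  terms <- vector("list", length(lines))
  seen <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": expected at least 3 tab-separated fields, got ",
           length(fields))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(trimws(members))]
    if (length(members) == 0L) {
      stop("GMT line ", i, ": term '", fields[1L], "' has no members")
    }
    members <- unique(normalize_symbol(members, alias_map))
    id <- trimws(fields[1L])
    if (id %in% seen) stop("GMT line ", i, ": duplicate term id '", id, "'")
    seen <- c(seen, id)
    terms[[i]] <- list(term_id = id, term_name = fields[2L], members = members)
  }
  names(terms) <- seen
  structure(terms, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(t) length(t$members), 0L)
  cat("Gene-set collection: ", length(x), " terms, member counts ",
      if (length(x)) paste0(min(sizes), "-", max(sizes)) else "-", "\n", sep = "")
  invisible(x)
}

#' Write a GMT gene-set collection
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(t) {
    paste(c(t$term_id, t$term_name, t$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
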