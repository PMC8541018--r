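#' Filter drug targets by potency
#'
#' Reduces a drug-target affinity table to the targets engaged at
#' physiologically plausible concentrations. A symbol is retained iff the
#' minimum activity over all its records is strictly below `threshold_nM`
#' (the most potent measurement wins); Ki, EC50 and IC50 are treated
#' identically, and the filter is direction-agnostic (agonists, antagonists
#' and allosteric modulators all pass). The default ceiling of 2000 nM
#' (2 uM) corresponds to the highest plasma concentration attainable for a
#' typical orally dosed small molecule.
#'
#' @param records Data frame of affinity records (see
#'   [read_affinity_table()]).
#' @param threshold_nM Retention ceiling in nM; strict `<` at the boundary.
#' @return An object of class `potency_filter`: a list with
#'   \describe{
#'     \item{retained}{data frame `symbol`, `best_activity_nM`,
#'       `activity_measure`, `interaction_mode` (measure/mode of the most
#'       potent record), ordered by ascending best activity, ties
#'       alphabetical;}
#'     \item{records}{the supporting input records for retained symbols;}
#'     \item{threshold_nM}{the cutoff applied;}
#'     \item{n_input_symbols}{number of distinct symbols before filtering.}
#'   }
#' @examples
#' rec <- data.frame(target_symbol = c("PPARG", "FAAH"),
#'                   activity_value_nM = c(100, 2500),
#'                   activity_measure = c("EC50", "IC50"),
#'                   interaction_mode = c("full agonist", "inhibitor"),
#'                   source_ref = NA)
#' filter_by_potency(rec, 2000)$retained$symbol
#' @export
filter_by_potency <- function(records, threshold_nM = 2000) {
  stopifnot(is.numeric(threshold_nM), length(threshold_nM) == 1L, threshold_nM > 0)
  syms <- unique(records$target_symbol)
  if (nrow(records) == 0L) {
    retained <- data.frame(symbol = character(), best_activity_nM = numeric(),
                           activity_measure = character(),
                           interaction_mode = character(),
                           stringsAsFactors = FALSE)
    return(structure(list(retained = retained, records = records,
                          threshold_nM = threshold_nM, n_input_symbols = 0L),
                     class = "potency_filter"))
  }
  best_idx <- vapply(syms, function(s) {
    idx <- which(records$target_symbol == s)
    idx[which.min(records$activity_value_nM[idx])]
  }, 0L)
  best <- data.frame(symbol = syms,
                     best_activity_nM = records$activity_value_nM[best_idx],
                     activity_measure = records$activity_measure[best_idx],
                     interaction_mode = records$interaction_mode[best_idx],
                     stringsAsFactors = FALSE)
  best <- best[best$best_activity_nM < threshold_nM, , drop = FALSE]
  best <- best[order(best$best_activity_nM, best$symbol), , drop = FALSE]
  rownames(best) <- NULL
  structure(list(
    retained = best,
    records = records[records$target_symbol %in% best$symbol, , drop = FALSE],
    threshold_nM = threshold_nM,
    n_input_symbols = length(syms)
  ), class = "potency_filter")
}

#' @export
print.potency_filter <- function(x, ...) {
  cat("Potency filter (< ", format(x$threshold_nM), " nM): retained ",
      nrow(x$retained), " of ", x$n_input_symbols, " targets\n", sep = "")
  if (nrow(x$retained) > 0L) {
    print(utils::head(x$retained, 10L))
    if (nrow(x$retained) > 10L) cat("  ... and ", nrow(x$retained) - 10L, " more\n")
  }
  invisible(x)
}

#' Retained symbols of a potency filter
#' @param x A `potency_filter` object.
#' @return Character vector ordered by ascending best activity.
#' @export
retained_symbols <- function(x) {
  stopifnot(inherits(x, "potency_filter"))
  x$retained$symbol
}

#' Write the retained-target table of a potency filter
#' @param x A `potency_filter` object.
#' @param path Output path (TSV with columns
#'   `symbol`, `best_activity_nM`, `measure`, `mode`).
#' @export
write_potency_filter <- function(x, path) {
  stopifnot(inherits(x, "potency_filter"))
  out <- x$retained
  names(out) <- c("symbol", "best_activity_nM", "measure", "mode")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
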