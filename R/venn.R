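#' Three-way Venn partition of gene-symbol sets
#'
#' Computes the seven exclusive regions of a three-set Venn diagram over
#' normalized gene symbols. Regions are keyed by a three-bit membership
#' pattern in the order of `labels`: `"100"` = first set only, `"110"` =
#' first and second only, `"111"` = all three, etc. Members within each
#' region are sorted alphabetically.
#'
#' @param set_a,set_b,set_c Character vectors of normalized symbols
#'   (duplicates ignored); empty sets allowed.
#' @param labels Length-3 character vector naming the sets.
#' @return An object of class `venn_partition`: list with `labels`,
#'   `region_counts` (named integer vector over the 7 patterns) and
#'   `region_members` (named list of sorted character vectors).
#' @examples
#' venn_partition(c("A", "B"), c("B", "C"), c("C", "B"))$region_counts
#' @export
venn_partition <- function(set_a, set_b, set_c, labels = c("A", "B", "C")) {
  stopifnot(length(labels) == 3L)
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  c_ <- unique(as.character(set_c))
  universe <- sort(unique(c(a, b, c_)))
  pattern <- paste0(as.integer(universe %in% a),
                    as.integer(universe %in% b),
                    as.integer(universe %in% c_))
  keys <- c("100", "010", "001", "110", "101", "011", "111")
  members <- lapply(keys, function(k) universe[pattern == k])
  names(members) <- keys
  counts <- vapply(members, length, 0L)
  structure(list(labels = as.character(labels),
                 region_counts = counts,
                 region_members = members),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Three-way Venn partition (", paste(x$labels, collapse = " / "), ")\n", sep = "")
  for (k in names(x$region_counts)) {
    sets <- x$labels[strsplit(k, "")[[1L]] == "1"]
    cat(sprintf("  %s (%s): %d\n", k, paste(sets, collapse = " & "),
                x$region_counts[[k]]))
  }
  cat("  union:", sum(x$region_counts), "\n")
  invisible(x)
}

#' Common targets of a drug and two diseases
#'
#' The alphabetically sorted intersection of the drug-target set with both
#' disease-target sets; equal to region `111` of [venn_partition()].
#'
#' @param drug_set,disease_a,disease_b Character vectors of normalized
#'   symbols.
#' @return Sorted character vector.
#' @examples
#' common_targets(c("A", "B", "C"), c("B", "C", "D"), c("C", "B"))
#' @export
common_targets <- function(drug_set, disease_a, disease_b) {
  sort(intersect(intersect(unique(drug_set), unique(disease_a)),
                 unique(disease_b)))
}

#' Serialize a Venn partition to JSON
#' @param x A `venn_partition`.
#' @param path Output path.
#' @export
write_venn <- function(x, path) {
  stopifnot(inherits(x, "venn_partition"))
  jsonlite::write_json(
    list(labels = x$labels,
         region_counts = as.list(x$region_counts),
         region_members = x$region_members),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
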