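#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes without
#' replacement from a background of `N` genes of which `K` belong to the
#' term, the probability of seeing at least `k` term members. Computed by
#' summing the point masses in log space (log-binomials via `lchoose` and a
#' log-sum-exp reduction), which keeps the tail accurate for extreme
#' overlaps.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return A probability in (0, 1].
#' @examples
#' hypergeometric_upper_tail(2, 4, 3, 10)  # = 40/120
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (anyNA(c(k, K, n, N)) || any(c(k, K, n, N) < 0) ||
      any(c(k, K, n, N) != round(c(k, K, n, N)))) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (K > N || n > N) stop("K and n must not exceed the background size N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  p <- exp(m + log(sum(exp(logp - m))))
  min(p, 1)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH: with the p-values sorted ascending, `q_i = min_{j >= i}
#' (p_j * m / j)` capped at 1, returned in the original input order. The
#' Bonferroni alternative (`p * m`, capped at 1) is available for a stricter
#' family-wise control.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Numeric vector of adjusted values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  if (method == "bonferroni") return(pmin(p * m, 1))
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))          # step-up monotonization
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Over-representation analysis of a gene list
#'
#' Tests each gene set of a GMT collection for over-representation in a
#' query list by the one-sided (upper-tail) hypergeometric test, with
#' multiple-testing adjustment across all tested terms. The background is
#' the sampling frame of the test: either an explicit symbol set, an
#' explicit genome size (to honour a whole-genome background when the
#' collection covers only part of it), or, by default, the union of all
#' collection members.
#'
#' @param query Character vector of normalized symbols (deduplicated
#'   internally).
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param background Either `NULL` (union of all members), a character
#'   vector of symbols, or a single number giving the background size.
#' @param min_term_size Terms with fewer background members are excluded
#'   before testing.
#' @param method FDR procedure passed to [bh_adjust()].
#' @return Data frame with columns `term_id`, `term_name`, `overlap`
#'   (comma-joined sorted members), `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   sorted by ascending p-value with term_id tiebreak.
#' @export
enrich <- function(query, collection, background = NULL, min_term_size = 2,
                   method = "BH") {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("empty query")

  members <- lapply(collection, `[[`, "members")
  if (is.null(background)) background <- sort(unique(unlist(members)))

  if (is.numeric(background) && length(background) == 1L) {
    N <- as.integer(background)
    eff_query <- query
    K_of <- function(mem) length(mem)
  } else {
    background <- unique(as.character(background))
    N <- length(background)
    eff_query <- intersect(query, background)
    dropped <- setdiff(query, eff_query)
    if (length(dropped) > 0L) {
      warning(length(dropped), " query symbol(s) outside the background dropped: ",
              paste(dropped, collapse = ", "))
    }
    members <- lapply(members, intersect, background)
    K_of <- function(mem) length(mem)
  }
  n <- length(eff_query)
  if (n == 0L) stop("query is empty after intersection with the background")
  if (N < n) stop("background (N = ", N, ") smaller than the query (n = ", n, ")")

  keep <- vapply(members, K_of, 0L) >= min_term_size
  members <- members[keep]
  terms <- collection[keep]
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      overlap = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  }

  rows <- lapply(seq_along(terms), function(i) {
    mem <- members[[i]]
    ov <- sort(intersect(eff_query, mem))
    k <- length(ov)
    K <- length(mem)
    if (K > N) stop("term '", terms[[i]]$term_id,
                    "' is larger than the declared background")
    data.frame(term_id = terms[[i]]$term_id,
               term_name = terms[[i]]$term_name,
               overlap = paste(ov, collapse = ","),
               k = k, K = K, n = n, N = N,
               p_value = hypergeometric_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value, method = method)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table to TSV
#' @param x Data frame from [enrich()].
#' @param path Output path.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
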