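#' Upper-tail hypergeometric probability for over-representation
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of
#' drawing at least `k` members of a size-`K` gene set when `n` genes
#' are drawn without replacement from a universe of `N`. Evaluated
#' through the log-space distribution function for numerical
#' stability at large N.
#'
#' @param k observed hits in the set (0 <= k <= min(K, n)).
#' @param K set size within the universe.
#' @param n hit-list size within the universe.
#' @param N universe size.
#' @return the p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0) stop("all counts must be non-negative")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, m = K, n = N - K, k = n,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Gene-set over-representation analysis of a hit list
#'
#' Tests each gene set for enrichment of the hit list against the
#' universe with the upper-tail hypergeometric probability, after
#' intersecting every set with the universe and discarding sets whose
#' intersected size falls outside `[min_set_size, max_set_size]`.
#' Benjamini-Hochberg adjustment is applied over the tested sets
#' only; both raw and adjusted p-values are reported. Typical use:
#' hits = longevity-correlating genes of one dataset, universe = all
#' genes measured in that dataset.
#'
#' @param hits character vector of hit gene ids; must be a subset of
#'   `universe`.
#' @param universe character vector of background gene ids.
#' @param collection a [gene_set_collection()].
#' @param min_set_size,max_set_size bounds on the intersected set
#'   size (defaults 5 and 500, conventional ORA bounds).
#' @return data frame with one row per tested set: `set_id`,
#'   `set_name`, `k` (hits in set), `K` (set size in universe), `n`
#'   (hit-list size), `N` (universe size), `p_value`, `fdr`; sorted
#'   by p-value then set id.
#' @export
run_enrichment <- function(hits, universe, collection,
                           min_set_size = 5L, max_set_size = 500L) {
  hits <- unique(trimws(as.character(hits)))
  universe <- unique(trimws(as.character(universe)))
  stray <- setdiff(hits, universe)
  if (length(stray)) {
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) ", ..." else "")
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(seq_along(collection$set_id), function(i) {
    members <- intersect(collection$members[[i]], universe)
    K <- length(members)
    if (K < min_set_size || K > max_set_size) return(NULL)
    k <- length(intersect(members, hits))
    data.frame(set_id = collection$set_id[i],
               set_name = collection$set_name[i],
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(set_id = character(), set_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment result table as TSV
#' @param result output of [run_enrichment()].
#' @param path output path.
#' @export
write_enrichment_table <- function(result, path) {
  out <- result
  out$p_value <- .fmt_num(out$p_value)
  out$fdr <- .fmt_num(out$fdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
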