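## Cross-dataset merging of vetted hit sets: pairwise overlap, shared-gene
## presence ranking and signed correlation patterns. Tables are expected at
## gene level (collapse_features_to_genes); feature-level tables work too
## when feature ids already are gene ids, as in the synthetic panels.

.score_key <- function(tbl) {
  if ("gene_id" %in% names(tbl)) tbl$gene_id else tbl$feature_id
}

.table_ids <- function(tables) {
  ids <- vapply(tables, function(t) t$dataset_id[1L], character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset_id across score tables")
  ids
}

#' Pairwise overlap of hit sets across datasets
#'
#' For each ordered dataset pair, both hit sets (genes with defined
#' |r| >= `threshold`) are restricted to the shared measured universe
#' (genes quantified in both datasets) and the overlap fraction is the
#' Jaccard index |A intersect B| / |A union B|. Pairs with an empty
#' union get an undefined (`NA`) fraction. The pairs table also
#' reports `fraction_of_universe` = |A intersect B| / |shared
#' universe|, the share of commonly measured genes that are hits in
#' both datasets; unlike the Jaccard index, this percentage is
#' guaranteed non-increasing in the threshold because its denominator
#' does not shrink with the hit sets.
#'
#' @param score_tables list of gene-level score tables on a common
#'   gene id space.
#' @param threshold |r| cutoff defining a hit.
#' @return an `overlap_matrix`: list with the square `fraction`
#'   matrix, a long-form `pairs` data frame (hit sizes, intersection,
#'   union, fraction), and the threshold.
#' @export
overlap_matrix <- function(score_tables, threshold = 0.4) {
  if (length(score_tables) < 2L) stop("need at least 2 score tables")
  ids <- .table_ids(score_tables)
  measured <- lapply(score_tables, .score_key)
  hits <- lapply(score_tables, function(t) .score_key(vetted(t, threshold)))
  k <- length(ids)
  frac <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  pairs <- vector("list", k * k)
  p <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      shared <- intersect(measured[[i]], measured[[j]])
      a <- intersect(hits[[i]], shared)
      b <- intersect(hits[[j]], shared)
      ni <- length(intersect(a, b))
      nu <- length(union(a, b))
      f <- if (nu > 0L) ni / nu else NA_real_
      frac[i, j] <- f
      p <- p + 1L
      pairs[[p]] <- data.frame(dataset_a = ids[i], dataset_b = ids[j],
                               n_hits_a = length(a), n_hits_b = length(b),
                               n_shared_universe = length(shared),
                               n_intersection = ni, n_union = nu,
                               fraction = f,
                               fraction_of_universe =
                                 if (length(shared)) ni / length(shared)
                                 else NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(fraction = frac,
                 pairs = do.call(rbind, pairs),
                 threshold = threshold,
                 overlap_definition = "jaccard_over_shared_measured_universe"),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("overlap_matrix (|r| >= %g, Jaccard over shared universe):\n",
              x$threshold))
  print(round(x$fraction, 3))
  invisible(x)
}

#' Rank genes shared across datasets
#'
#' Merges per-dataset longevity scores and ranks each gene by (1) its
#' presence count -- the number of datasets where it is both measured
#' and passing the threshold -- descending, (2) its mean |r| over the
#' passing datasets, descending, (3) gene id, ascending. The signed r
#' per dataset is retained for the sign-pattern display; a gene
#' unmeasured (or failing) in a dataset carries an explicit `NA`
#' there, never a zero. Genes passing nowhere are omitted.
#'
#' @param score_tables list of gene-level score tables.
#' @param threshold |r| cutoff defining presence.
#' @return data frame of class `shared_gene_ranking`: `gene_id`,
#'   `presence_count`, `n_measured`, `mean_abs_r`, plus one signed
#'   `r_<dataset_id>` column per dataset.
#' @export
shared_gene_ranking <- function(score_tables, threshold = 0.4) {
  if (length(score_tables) < 1L) stop("need at least 1 score table")
  ids <- .table_ids(score_tables)
  genes <- sort(unique(unlist(lapply(score_tables, .score_key))))
  k <- length(ids)
  rmat <- matrix(NA_real_, length(genes), k, dimnames = list(genes, ids))
  meas <- matrix(FALSE, length(genes), k, dimnames = list(genes, ids))
  for (j in seq_len(k)) {
    t <- score_tables[[j]]
    key <- .score_key(t)
    meas[key, j] <- TRUE
    rmat[key, j] <- t$r
  }
  pass <- !is.na(rmat) & abs(rmat) >= threshold
  presence <- rowSums(pass)
  n_meas <- rowSums(meas)
  mean_abs <- ifelse(presence > 0,
                     rowSums(abs(rmat) * pass, na.rm = TRUE) / presence,
                     NA_real_)
  signed <- rmat
  signed[!pass] <- NA_real_

  keep <- presence > 0
  out <- data.frame(gene_id = genes[keep],
                    presence_count = as.integer(presence[keep]),
                    n_measured = as.integer(n_meas[keep]),
                    mean_abs_r = mean_abs[keep],
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("r_", ids[j])]] <- signed[keep, j]
  ord <- order(-out$presence_count, -out$mean_abs_r, out$gene_id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dataset_ids") <- ids
  attr(out, "n_datasets") <- k
  attr(out, "threshold") <- threshold
  class(out) <- c("shared_gene_ranking", "data.frame")
  out
}

#' Histogram of genes per presence count
#'
#' Exact counts of ranked genes at each presence count 0..n_datasets
#' (the "how many genes are shared among six, seven, all datasets"
#' summary).
#'
#' @param ranking a [shared_gene_ranking()].
#' @param n_datasets total number of datasets; taken from the ranking
#'   when omitted.
#' @return named integer vector over counts `0:n_datasets`.
#' @export
presence_histogram <- function(ranking, n_datasets = NULL) {
  if (is.null(n_datasets)) n_datasets <- attr(ranking, "n_datasets")
  if (is.null(n_datasets)) stop("n_datasets unknown; pass it explicitly")
  counts <- integer(n_datasets + 1L)
  names(counts) <- as.character(0:n_datasets)
  if (nrow(ranking) > 0L) {
    tab <- table(ranking$presence_count)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Signed correlation pattern of the top shared genes
#'
#' Gene x dataset matrix of signed r for the `top_n` highest-ranked
#' genes; entries are the signed correlation where the gene passes,
#' `NA` where it is unmeasured or fails. Tissue-specific sign flips
#' (the same gene positively correlated with lifespan in one tissue,
#' negatively in another) show up as mixed-sign rows.
#'
#' @param ranking a [shared_gene_ranking()].
#' @param top_n number of top-ranked genes to include (> 0).
#' @export
sign_pattern_matrix <- function(ranking, top_n = 10L) {
  if (top_n <= 0) stop("top_n must be positive")
  ids <- attr(ranking, "dataset_ids")
  n <- min(top_n, nrow(ranking))
  cols <- paste0("r_", ids)
  m <- as.matrix(ranking[seq_len(n), cols, drop = FALSE])
  dimnames(m) <- list(ranking$gene_id[seq_len(n)], ids)
  m
}

#' Write an overlap matrix (long form) as TSV
#' @param overlap an [overlap_matrix()].
#' @param path output path.
#' @export
write_overlap_table <- function(overlap, path) {
  out <- overlap$pairs
  out$fraction <- .fmt_num(out$fraction)
  out$fraction_of_universe <- .fmt_num(out$fraction_of_universe)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
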