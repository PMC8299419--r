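#' Pearson correlation with undefined-score handling
#'
#' Product-moment correlation over pairwise-complete observations.
#' Returns `NA` (the undefined-score marker) instead of raising when
#' fewer than `min_obs` complete pairs remain or either vector is
#' constant over them, so a single degenerate feature never aborts a
#' whole-dataset scan.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_obs minimum number of complete pairs (default 3).
#' @return correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearson_r <- function(x, y, min_obs = 3L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_obs) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Least-squares slope of lifespan on expression
#'
#' Slope of the univariate linear model with lifespan as the response
#' and expression as the predictor, in days per expression unit.
#' Its sign always equals the sign of the Pearson correlation.
#'
#' @param expression numeric predictor vector.
#' @param lifespan numeric response vector (days).
#' @param min_obs minimum complete pairs.
#' @return the slope, or `NA_real_` if undefined.
#' @export
univariate_slope <- function(expression, lifespan, min_obs = 3L) {
  if (length(expression) != length(lifespan)) {
    stop("expression and lifespan must have equal length")
  }
  ok <- is.finite(expression) & is.finite(lifespan)
  if (sum(ok) < min_obs) return(NA_real_)
  e <- expression[ok]; l <- lifespan[ok]
  ve <- stats::var(e)
  if (ve == 0) return(NA_real_)
  stats::cov(e, l) / ve
}

#' Critical Pearson correlation from the Student-t distribution
#'
#' The smallest |r| significant at the two-tailed level `alpha` for
#' sample size `n`, from the t-transform of the correlation
#' coefficient: r_crit = t / sqrt(t^2 + n - 2) with t the two-tailed
#' t quantile on n - 2 degrees of freedom. Provided as a diagnostic
#' for choosing an |r| vetting threshold; e.g. n = 32 at alpha = 0.05
#' gives 0.349.
#'
#' @param n sample size (>= 3).
#' @param alpha two-tailed significance level in (0, 1).
#' @return the critical correlation.
#' @export
critical_r <- function(n, alpha = 0.05) {
  n <- as.integer(n)
  if (n < 3L) stop("critical_r requires n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tc <- stats::qt(1 - alpha / 2, df = n - 2L)
  tc / sqrt(tc^2 + n - 2L)
}

## "pass_04" for 0.4, "pass_07" for 0.7, "pass_045" for 0.45:
## the threshold's digits with the decimal point removed
.pass_col <- function(threshold) {
  paste0("pass_", gsub("[.]", "", formatC(threshold, format = "g")))
}

.pass_col_threshold <- function(name) {
  as.numeric(sub("^0", "0.", sub("^pass_", "", name)))
}

#' Score every feature of a dataset against lifespan
#'
#' Computes, per feature, the Pearson correlation between expression
#' and strain median lifespan over the selected (extreme-lived)
#' strains, the slope of lifespan regressed on expression, the number
#' of strains used, and pass flags at each |r| threshold (defaults
#' 0.4, the longevity-score cutoff, and 0.7, the top-hit cutoff).
#' Missing values are handled pairwise-complete per feature with a
#' minimum of `min_obs` observations; features below the minimum or
#' with constant values get the undefined marker (`NA`), never a
#' silent zero. Data declared on the 2z+8 scale are mapped to
#' z-scores first so slopes are in days per SD of expression.
#'
#' @param dataset an [omics_dataset()].
#' @param plan a `selection_plan` from [select_extremes()], derived
#'   from this dataset.
#' @param thresholds increasing vector of |r| cutoffs in (0, 1].
#' @param min_obs minimum complete pairs per feature (default 6).
#' @return data frame of class `longevity_scores` with columns
#'   `dataset_id`, `feature_id`, `r`, `slope`, `n_used`, and one
#'   logical `pass_XX` column per threshold.
#' @export
score_dataset <- function(dataset, plan, thresholds = c(0.4, 0.7),
                          min_obs = 6L) {
  if (!inherits(plan, "selection_plan")) stop("'plan' must be a selection_plan")
  if (nrow(plan$selected) == 0L) stop("empty strain selection")
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]")
  }
  dataset <- as_zscore(dataset)
  sel <- plan$selected
  missing_strains <- setdiff(sel$strain_id, strain_ids(dataset))
  if (length(missing_strains)) {
    stop("selection plan refers to strain(s) absent from dataset: ",
         paste(missing_strains, collapse = ", "))
  }
  m <- dataset$values[, sel$strain_id, drop = FALSE]
  life <- sel$median_lifespan_days
  n_feat <- nrow(m)

  r <- rep(NA_real_, n_feat)
  slope <- rep(NA_real_, n_feat)
  n_used <- integer(n_feat)

  complete <- !is.na(m)
  n_used <- rowSums(complete)
  full <- n_used == ncol(m)

  fidx <- which(full)
  if (length(fidx) && stats::sd(life) > 0) {
    mf <- m[fidx, , drop = FALSE]
    cm <- mf - rowMeans(mf)
    lc <- life - mean(life)
    ss_e <- rowSums(cm^2)
    cross <- as.vector(cm %*% lc)
    ok <- ss_e > 0
    denom <- sqrt(ss_e * sum(lc^2))
    r[fidx[ok]] <- cross[ok] / denom[ok]
    slope[fidx[ok]] <- cross[ok] / ss_e[ok]
  }
  partial <- which(!full & n_used >= min_obs)
  for (i in partial) {
    r[i] <- pearson_r(m[i, ], life, min_obs = min_obs)
    slope[i] <- univariate_slope(m[i, ], life, min_obs = min_obs)
  }
  r[n_used < min_obs] <- NA_real_
  slope[n_used < min_obs] <- NA_real_
  # guard against rounding just past +/-1
  r <- pmin(pmax(r, -1), 1)

  out <- data.frame(dataset_id = dataset$dataset_id,
                    feature_id = rownames(m),
                    r = r, slope = slope, n_used = as.integer(n_used),
                    stringsAsFactors = FALSE)
  for (th in thresholds) {
    out[[.pass_col(th)]] <- !is.na(r) & abs(r) >= th
  }
  attr(out, "thresholds") <- thresholds
  attr(out, "min_obs") <- min_obs
  class(out) <- c("longevity_scores", "data.frame")
  out
}

#' Restrict a score table to features passing a threshold
#'
#' @param scores a score table.
#' @param threshold |r| cutoff; features with undefined scores never
#'   pass.
#' @export
vetted <- function(scores, threshold = 0.4) {
  scores[!is.na(scores$r) & abs(scores$r) >= threshold, , drop = FALSE]
}

#' Top-k features by absolute correlation
#'
#' Features sorted by |r| descending (undefined scores excluded),
#' ties broken by feature id ascending; the first `k` returned. With
#' k = 6 this reproduces a "top six genes per dataset" table.
#'
#' @param scores a score table.
#' @param k number of features (> 0).
#' @export
top_k_features <- function(scores, k) {
  if (k <= 0) stop("k must be positive")
  key <- if ("gene_id" %in% names(scores)) scores$gene_id else scores$feature_id
  def <- !is.na(scores$r)
  s <- scores[def, , drop = FALSE]
  key <- key[def]
  ord <- order(-abs(s$r), key, method = "radix")
  out <- s[ord, , drop = FALSE][seq_len(min(k, nrow(s))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
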