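#' Normalize a strain name for matching
#'
#' Public repositories spell the same strain inconsistently ("BXD-1",
#' "bxd 1", "BXD1"). Matching is done on an upper-cased form with
#' hyphens, underscores and internal spaces stripped.
#'
#' @param x character vector of strain names.
#' @return normalized names.
#' @export
normalize_strain_id <- function(x) {
  toupper(gsub("[-_ ]+", "", trimws(x)))
}

#' Match dataset strains to the lifespan table
#'
#' Matches each strain in the dataset to a median-lifespan entry by
#' normalized name and returns the matches ordered shortest to
#' longest-lived (ties broken by normalized strain id, ascending).
#' Unmatched strains are dropped with one message per strain.
#'
#' @param dataset an [omics_dataset()].
#' @param lifespans a [lifespan_table()].
#' @param sex_policy `"match_sex"` restricts lifespan entries to the
#'   dataset's declared sex (plus `"combined"` entries); a combined
#'   dataset matches combined entries, falling back to any sex when
#'   the table has none. `"any"` uses every entry, preferring an exact
#'   sex match when one strain appears under several sexes.
#' @return data frame with columns `strain_id` (as spelled in the
#'   dataset), `norm_id`, `median_lifespan_days`, ordered by lifespan.
#' @export
match_strains <- function(dataset, lifespans,
                          sex_policy = c("match_sex", "any")) {
  sex_policy <- match.arg(sex_policy)
  lt <- as.data.frame(lifespans)
  if (sex_policy == "match_sex") {
    if (dataset$sex %in% c("male", "female")) {
      lt <- lt[lt$sex %in% c(dataset$sex, "combined"), , drop = FALSE]
    } else {
      comb <- lt[lt$sex == "combined", , drop = FALSE]
      if (nrow(comb) > 0L) lt <- comb
    }
  }
  lt$norm_id <- normalize_strain_id(lt$strain_id)
  # prefer exact sex match, then combined, when a norm id repeats
  pref <- ifelse(lt$sex == dataset$sex, 0L, ifelse(lt$sex == "combined", 1L, 2L))
  lt <- lt[order(lt$norm_id, pref, method = "radix"), , drop = FALSE]
  lt <- lt[!duplicated(lt$norm_id), , drop = FALSE]

  ds_ids <- strain_ids(dataset)
  norm <- normalize_strain_id(ds_ids)
  idx <- match(norm, lt$norm_id)
  dropped <- ds_ids[is.na(idx)]
  for (s in dropped) message("match_strains: dropped unmatched strain '", s, "'")
  keep <- !is.na(idx)
  if (!any(keep)) stop("no strains mappable to lifespan table")
  out <- data.frame(strain_id = ds_ids[keep],
                    norm_id = norm[keep],
                    median_lifespan_days = lt$median_lifespan_days[idx[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$median_lifespan_days, out$norm_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  out
}

#' Select the extreme-lived strains for scoring
#'
#' In `"tails"` mode the `tail_size` shortest- and `tail_size`
#' longest-lived matched strains are selected (default 4 + 4, the
#' extreme-strain design: the strains at the far ends of the lifespan
#' ranking are expected to show the largest expression differences in
#' lifespan-determining genes). When fewer than `2 * tail_size`
#' strains are matched the selection falls back to all strains with a
#' warning, mirroring the handling of small datasets such as liver.
#' `"all"` mode selects every matched strain.
#'
#' @param matched output of [match_strains()] (ordered by lifespan).
#' @param mode `"tails"` or `"all"`.
#' @param tail_size strains per tail (>= 1).
#' @return a `selection_plan`: list with `mode` (the mode actually
#'   applied), `tail_size`, `matched`, and `selected` (a data frame
#'   with a `tail` column: `"short"`, `"long"` or `"all"`).
#' @export
select_extremes <- function(matched, mode = c("tails", "all"), tail_size = 4L) {
  mode <- match.arg(mode)
  tail_size <- as.integer(tail_size)
  if (nrow(matched) == 0L) stop("no matched strains to select from")
  if (mode == "tails" && tail_size < 1L) stop("tail_size must be >= 1")
  n <- nrow(matched)
  applied <- mode
  if (mode == "tails" && n < 2L * tail_size) {
    warning("only ", n, " matched strains (< ", 2L * tail_size,
            "); falling back to mode='all'")
    applied <- "all"
  }
  if (applied == "tails") {
    sel <- rbind(
      cbind(matched[seq_len(tail_size), , drop = FALSE], tail = "short"),
      cbind(matched[seq.int(n - tail_size + 1L, n), , drop = FALSE],
            tail = "long"))
  } else {
    sel <- cbind(matched, tail = "all")
  }
  rownames(sel) <- NULL
  structure(list(mode = applied, tail_size = tail_size,
                 matched = matched, selected = sel),
            class = "selection_plan")
}

#' @export
print.selection_plan <- function(x, ...) {
  cat(sprintf("selection_plan: mode=%s, %d/%d strains selected\n",
              x$mode, nrow(x$selected), nrow(x$matched)))
  invisible(x)
}

#' Export a selection plan as a tidy table
#'
#' One row per matched strain with its lifespan rank and selection
#' status; the TSV emitted by the pipeline's `select` stage.
#'
#' @param plan a `selection_plan`.
#' @export
selection_plan_table <- function(plan) {
  m <- plan$matched
  sel_idx <- match(m$strain_id, plan$selected$strain_id)
  data.frame(strain_id = m$strain_id,
             median_lifespan_days = m$median_lifespan_days,
             rank = seq_len(nrow(m)),
             selected = !is.na(sel_idx),
             tail = ifelse(is.na(sel_idx), "",
                           plan$selected$tail[sel_idx]),
             stringsAsFactors = FALSE)
}
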