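#' Construct an omics dataset
#'
#' Container for one tissue/sex/omics-type expression matrix with
#' features in rows and strains in columns, plus a declared
#' normalization convention. This is the unit of analysis: one
#' GeneNetwork-style export of transcript or peptide abundances for a
#' strain panel.
#'
#' @param values numeric matrix, features x strains, with unique
#'   rownames (feature ids) and colnames (strain ids). Entries may be
#'   `NA` for missing measurements.
#' @param dataset_id short identifier for the dataset.
#' @param tissue tissue of origin (free text).
#' @param sex one of `"male"`, `"female"`, `"combined"`.
#' @param omics_type one of `"transcript"`, `"protein"`.
#' @param normalization declared scale of `values`: `"zscore"`
#'   (per-feature z-scores), `"two_z_plus_8"` (z-scores rescaled to
#'   mean 8, SD 2, a GeneNetwork convention), or `"other"`.
#' @return an object of class `omics_dataset`.
#' @export
omics_dataset <- function(values, dataset_id,
                          tissue = "unknown",
                          sex = c("combined", "male", "female"),
                          omics_type = c("transcript", "protein"),
                          normalization = c("zscore", "two_z_plus_8", "other")) {
  sex <- match.arg(sex)
  omics_type <- match.arg(omics_type)
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x strains)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry feature ids as rownames and strain ids as colnames")
  }
  x <- structure(
    list(dataset_id = as.character(dataset_id),
         tissue = as.character(tissue),
         sex = sex,
         omics_type = omics_type,
         normalization = normalization,
         values = values),
    class = "omics_dataset")
  validate_omics_dataset(x)
}

validate_omics_dataset <- function(x) {
  fid <- rownames(x$values)
  sid <- colnames(x$values)
  if (anyDuplicated(fid)) {
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicate strain id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (any(!nzchar(fid)) || any(!nzchar(sid))) stop("empty feature or strain id")
  x
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset '%s': %d features x %d strains\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  cat(sprintf("  tissue=%s sex=%s type=%s normalization=%s missing=%d\n",
              x$tissue, x$sex, x$omics_type, x$normalization,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
feature_ids <- function(x) rownames(x$values)

#' @export
strain_ids <- function(x) colnames(x$values)

## numeric formatting used by every writer so that write -> read round
## trips are value-exact (17 significant digits suffice for doubles)
.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  out
}

#' Read a tab-delimited expression matrix
#'
#' Expects features in rows and strains in columns: first column holds
#' the feature id, the header row the strain ids. Empty cells and "NA"
#' are read as missing. A `transpose = TRUE` flag handles exports with
#' strains in rows.
#'
#' @param path path to a TSV file.
#' @param dataset_id,tissue,sex,omics_type,normalization dataset
#'   descriptors, see [omics_dataset()].
#' @param transpose if `TRUE` the file is strains-in-rows and is
#'   transposed after parsing.
#' @return an [omics_dataset()].
#' @export
read_expression_matrix <- function(path, dataset_id,
                                   tissue = "unknown",
                                   sex = "combined",
                                   omics_type = "transcript",
                                   normalization = "zscore",
                                   transpose = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) {
    stop("malformed header in ", path, ": expected feature-id column plus strain columns")
  }
  col_ids <- trimws(header[-1L])
  dup <- col_ids[duplicated(col_ids)]
  if (length(dup)) {
    stop("duplicate strain id in header of ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  nc <- length(col_ids)
  body <- fields[-1L]
  row_ids <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = nc)
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) > nc + 1L) {
      stop("row ", i + 1L, " of ", path, " has ", length(f) - 1L,
           " values but header declares ", nc, " strains")
    }
    length(f) <- nc + 1L   # right-pad short rows (trailing empty cells)
    row_ids[i] <- trimws(f[1L])
    cells <- trimws(f[-1L])
    cells[is.na(cells)] <- ""
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & nzchar(cells) & cells != "NA")
    if (length(bad)) {
      stop("non-numeric value '", cells[bad[1L]], "' at row ", i + 1L,
           " (feature '", row_ids[i], "'), column '", col_ids[bad[1L]],
           "' of ", path)
    }
    vals[i, ] <- num
  }
  dupf <- row_ids[duplicated(row_ids)]
  if (length(dupf)) {
    stop("duplicate feature id in ", path, ": ",
         paste(unique(dupf), collapse = ", "))
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (transpose) vals <- t(vals)
  omics_dataset(vals, dataset_id = dataset_id, tissue = tissue, sex = sex,
                omics_type = omics_type, normalization = normalization)
}

#' Write an expression matrix as TSV
#'
#' Missing entries are written as empty cells. Inverse of
#' [read_expression_matrix()] up to the dataset metadata, which lives
#' outside the file.
#'
#' @param dataset an [omics_dataset()].
#' @param path output path.
#' @export
write_expression_matrix <- function(dataset, path) {
  v <- dataset$values
  header <- paste(c("feature_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], .fmt_num(v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a strain median-lifespan table
#'
#' TSV with columns `strain_id`, `median_lifespan_days`, `sex`.
#' Lifespans must be strictly positive and (strain, sex) pairs unique.
#'
#' @param path path to the TSV file.
#' @return a data frame of class `lifespan_table`.
#' @export
read_lifespan_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("strain_id", "median_lifespan_days", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("lifespan table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  lifespan_table(df$strain_id, df$median_lifespan_days, df$sex)
}

#' Construct a lifespan table
#'
#' @param strain_id character vector of strain names.
#' @param median_lifespan_days positive median lifespans in days.
#' @param sex per-entry sex: `"male"`, `"female"` or `"combined"`.
#' @return a validated data frame of class `lifespan_table`.
#' @export
lifespan_table <- function(strain_id, median_lifespan_days,
                           sex = "combined") {
  df <- data.frame(strain_id = as.character(strain_id),
                   median_lifespan_days = as.numeric(median_lifespan_days),
                   sex = rep_len(as.character(sex), length(strain_id)),
                   stringsAsFactors = FALSE)
  if (any(!df$sex %in% c("male", "female", "combined"))) {
    stop("sex must be male, female or combined")
  }
  if (any(!is.finite(df$median_lifespan_days)) ||
      any(df$median_lifespan_days <= 0)) {
    stop("median lifespans must be finite and strictly positive")
  }
  key <- paste(df$strain_id, df$sex, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (strain_id, sex) pair: ",
         df$strain_id[duplicated(key)][1L])
  }
  class(df) <- c("lifespan_table", "data.frame")
  df
}

#' @export
write_lifespan_table <- function(lifespans, path) {
  out <- data.frame(strain_id = lifespans$strain_id,
                    median_lifespan_days = .fmt_num(lifespans$median_lifespan_days),
                    sex = lifespans$sex)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-delimited as
#' id, description, member, member, ... Trailing empty fields are
#' ignored; duplicate members within a set are collapsed.
#'
#' @param path path to a GMT file.
#' @return a `gene_set_collection`: a list with character vectors
#'   `set_id`, `set_name` and a list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- character(length(fields))
  nms <- character(length(fields))
  members <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    f <- f[!(seq_along(f) > 2 & !nzchar(f))]   # drop trailing/interior empties past col 2
    if (length(f) < 3L) {
      stop("GMT line ", i, " of ", path,
           " has fewer than 3 fields (id, description, members...)")
    }
    ids[i] <- f[1L]
    nms[i] <- f[2L]
    members[[i]] <- unique(f[-(1:2)])
  }
  gene_set_collection(ids, nms, members)
}

#' Construct a gene-set collection
#'
#' @param set_id unique set identifiers.
#' @param set_name human-readable set names.
#' @param members list of non-empty character vectors of gene ids.
#' @export
gene_set_collection <- function(set_id, set_name, members) {
  if (anyDuplicated(set_id)) {
    stop("duplicate gene-set id: ", set_id[duplicated(set_id)][1L])
  }
  if (any(lengths(members) == 0L)) stop("gene set with no members")
  structure(list(set_id = as.character(set_id),
                 set_name = as.character(set_name),
                 members = lapply(members, as.character)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, member counts %d-%d\n",
              length(x$set_id), min(lengths(x$members)),
              max(lengths(x$members))))
  invisible(x)
}

#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$set_id), function(i) {
    paste(c(collection$set_id[i], collection$set_name[i],
            collection$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-to-gene mapping table
#'
#' Two-column TSV (`feature_id`, `gene_id`); many features may map to
#' one gene. Gene ids are compared case-sensitively after whitespace
#' trimming.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `feature_id`, `gene_id`.
#' @export
read_feature_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("feature map ", path, " needs two columns")
  names(df)[1:2] <- c("feature_id", "gene_id")
  df$feature_id <- trimws(as.character(df$feature_id))
  df$gene_id <- trimws(as.character(df$gene_id))
  if (any(!nzchar(df$feature_id))) stop("empty feature id in map ", path)
  if (anyDuplicated(df$feature_id)) {
    stop("feature mapped twice in ", path, ": ",
         df$feature_id[duplicated(df$feature_id)][1L])
  }
  df[1:2]
}

#' Convert from the 2z+8 convention to plain z-scores
#'
#' Some GeneNetwork exports rescale z-scores to mean 8 and SD 2
#' ("2z+8 score"); this undoes that rescaling: z = (x - 8) / 2.
#' Missing entries are preserved.
#'
#' @param values numeric vector or matrix on the 2z+8 scale.
#' @export
from_two_z_plus_8 <- function(values) (values - 8) / 2

#' @rdname from_two_z_plus_8
#' @export
to_two_z_plus_8 <- function(values) 2 * values + 8

#' Map a dataset's values onto the z-score scale
#'
#' Applies [from_two_z_plus_8()] when the dataset declares the
#' `two_z_plus_8` convention; `zscore` data pass through unchanged.
#' Data declared `other` are refused because the slope units would be
#' meaningless.
#'
#' @param dataset an [omics_dataset()].
#' @export
as_zscore <- function(dataset) {
  switch(dataset$normalization,
    zscore = dataset,
    two_z_plus_8 = {
      dataset$values <- from_two_z_plus_8(dataset$values)
      dataset$normalization <- "zscore"
      dataset
    },
    stop("dataset '", dataset$dataset_id,
         "' has normalization 'other'; rescale it to z-scores first"))
}

#' Collapse a feature-level score table to gene level
#'
#' For each gene, keeps the score row of its feature with maximal
#' absolute correlation (sign retained from that feature); ties are
#' broken by the lexicographically smallest feature id. Features with
#' an undefined score lose to any defined one. Unmapped features are
#' dropped and counted in a message.
#'
#' @param scores a score table from [score_dataset()].
#' @param map a feature-to-gene map, see [read_feature_gene_map()].
#' @return a score table keyed by `gene_id`, with `feature_id`
#'   recording the winning feature.
#' @export
collapse_features_to_genes <- function(scores, map) {
  idx <- match(scores$feature_id, map$feature_id)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0L) {
    message("collapse_features_to_genes: dropped ", unmapped,
            " unmapped feature(s)")
  }
  keep <- !is.na(idx)
  out <- scores[keep, , drop = FALSE]
  out$gene_id <- map$gene_id[idx[keep]]
  # rank within gene: defined |r| descending, undefined last, then feature id
  key_abs <- ifelse(is.na(out$r), -Inf, abs(out$r))
  ord <- order(out$gene_id, -key_abs, out$feature_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out[c("dataset_id", "gene_id", "feature_id",
        setdiff(names(out), c("dataset_id", "gene_id", "feature_id")))]
}

#' Write a score table (feature- or gene-level) as TSV
#' @param scores a score table.
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  out <- scores
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- .fmt_num(out[[nm]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read back a score table written by [write_score_table()]
#' @param path path to the TSV file.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  for (nm in grep("^pass_", names(df), value = TRUE)) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  df
}
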