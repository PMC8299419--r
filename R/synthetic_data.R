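## Synthetic BXD-like panel generator. Emulates the real data landscape:
## a panel of recombinant-inbred strains with known median lifespans and
## 5-8 per-tissue/sex expression datasets over partially overlapping
## strain subsets, in which a small set of planted genes carries a
## controlled linear lifespan signal on top of an independent Gaussian
## background. The planted construction is the standard bivariate-normal
## one, so the target rho is the exact population correlation and
## parameter recovery is analytically checkable.

## run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## fixed expansion of the global seed into per-component sub-seeds so
## that adding a dataset never reshuffles earlier ones
.sub_seed <- function(seed, index) {
  ((as.numeric(seed) %% 1000003) * 2039 + index * 7919) %% 2147483647
}

.default_roster <- function(n_datasets) {
  base <- data.frame(
    dataset_id = c("adrenal_m", "adrenal_f", "kidney_m", "kidney_f",
                   "liver_rna_f", "liver_prot_f", "bone_m", "eye_c"),
    tissue = c("adrenal", "adrenal", "kidney", "kidney",
               "liver", "liver", "bone", "eye"),
    sex = c("male", "female", "male", "female",
            "female", "female", "male", "combined"),
    omics_type = c("transcript", "transcript", "transcript", "transcript",
                   "transcript", "protein", "transcript", "transcript"),
    selection_mode = c("tails", "tails", "tails", "tails",
                       "all", "all", "tails", "tails"),
    stringsAsFactors = FALSE)
  if (n_datasets <= nrow(base)) return(base[seq_len(n_datasets), , drop = FALSE])
  extra <- n_datasets - nrow(base)
  add <- data.frame(dataset_id = sprintf("tissue%02d", seq_len(extra)),
                    tissue = sprintf("tissue%02d", seq_len(extra)),
                    sex = "combined", omics_type = "transcript",
                    selection_mode = "tails", stringsAsFactors = FALSE)
  rbind(base, add)
}

#' Default planted-gene design: universal genes with tissue-specific signs
#'
#' Each planted gene appears in all datasets at correlation magnitude
#' `rho`, with a per-dataset sign pattern (gene 1 flips sign between
#' the first and second half of the roster; gene 2 alternates), so
#' the panel contains pervasive lifespan-correlated genes whose
#' direction depends on the tissue -- the situation the shared-gene
#' ranking is designed to surface.
#'
#' @param n_datasets number of datasets in the panel.
#' @param n_universal number of universal planted genes.
#' @param rho target correlation magnitude in (0, 1].
#' @return data frame with columns `gene_id`, `dataset_index`, `rho`.
#' @export
planted_universal_genes <- function(n_datasets, n_universal = 2L,
                                    rho = 0.95) {
  if (n_universal == 0L) {
    return(data.frame(gene_id = character(), dataset_index = integer(),
                      rho = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(n_universal), function(g) {
    sign_pattern <- if (g %% 2L == 1L) {
      ifelse(seq_len(n_datasets) <= ceiling(n_datasets / 2), 1, -1)
    } else {
      ifelse(seq_len(n_datasets) %% 2L == 1L, 1, -1)
    }
    data.frame(gene_id = sprintf("UNIV%02d", g),
               dataset_index = seq_len(n_datasets),
               rho = rho * sign_pattern,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Configuration for the synthetic panel generator
#'
#' Defaults describe the reference study design the package validates
#' against: a 40-strain panel with uniform lifespans on 450-900 days
#' (over a twofold spread, as seen across real BXD strains), 8
#' datasets named after a multi-tissue male/female roster, 20 strains
#' per dataset sampled without replacement (so strain subsets overlap
#' only partially), 500 independent standard-normal background
#' features per dataset sharing one gene id space, and 2 universal
#' planted genes at |rho| = 0.95 with tissue-specific signs.
#'
#' @param n_strains strains in the panel (>= 2).
#' @param lifespan_range `(low, high)` days, low < high.
#' @param n_datasets number of datasets (>= 1).
#' @param n_features_per_dataset background features per dataset.
#' @param strains_per_dataset strains sampled into each dataset
#'   (<= n_strains).
#' @param planted data frame `gene_id` / `dataset_index` / `rho`
#'   (signed, |rho| <= 1); see [planted_universal_genes()].
#' @param noise_sd standard deviation of background features (> 0).
#'   The planted-gene noise term keeps unit variance so the planted
#'   rho is the exact population correlation.
#' @param missing_rate fraction of entries set missing at random
#'   (default 0).
#' @param normalization output scale, `"zscore"` or `"two_z_plus_8"`.
#' @param tail_size tails used by downstream selection (kept in the
#'   config so a panel and its analysis share one record).
#' @param seed integer seed; all panel randomness derives from it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 40L,
                             lifespan_range = c(450, 900),
                             n_datasets = 8L,
                             n_features_per_dataset = 500L,
                             strains_per_dataset = 20L,
                             planted = planted_universal_genes(n_datasets),
                             noise_sd = 1,
                             missing_rate = 0,
                             normalization = c("zscore", "two_z_plus_8"),
                             tail_size = 4L,
                             seed = 1L) {
  normalization <- match.arg(normalization)
  cfg <- list(n_strains = as.integer(n_strains),
              lifespan_range = as.numeric(lifespan_range),
              n_datasets = as.integer(n_datasets),
              n_features_per_dataset = as.integer(n_features_per_dataset),
              strains_per_dataset = as.integer(strains_per_dataset),
              planted = planted,
              noise_sd = as.numeric(noise_sd),
              missing_rate = as.numeric(missing_rate),
              normalization = normalization,
              tail_size = as.integer(tail_size),
              seed = as.integer(seed))
  if (cfg$n_strains < 2L) stop("n_strains must be >= 2")
  if (length(cfg$lifespan_range) != 2L ||
      cfg$lifespan_range[1] >= cfg$lifespan_range[2]) {
    stop("lifespan_range must be (low, high) with low < high")
  }
  if (cfg$n_datasets < 1L) stop("n_datasets must be >= 1")
  if (cfg$strains_per_dataset > cfg$n_strains) {
    stop("strains_per_dataset must not exceed n_strains")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (nrow(cfg$planted) > 0L) {
    if (any(abs(cfg$planted$rho) > 1)) stop("|rho| must be <= 1")
    if (any(cfg$planted$dataset_index < 1 |
            cfg$planted$dataset_index > cfg$n_datasets)) {
      stop("planted dataset_index out of range")
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a strain lifespan table
#'
#' `n_strains` strains named `SYN001`, `SYN002`, ... with median
#' lifespans drawn uniformly on `lifespan_range` (sex `"combined"`).
#' Deterministic per seed.
#'
#' @param n_strains number of strains (>= 2).
#' @param lifespan_range `(low, high)` in days.
#' @param seed integer seed.
#' @return a [lifespan_table()].
#' @export
generate_lifespans <- function(n_strains, lifespan_range = c(450, 900),
                               seed = 1L) {
  if (n_strains < 2L) stop("n_strains must be >= 2")
  if (lifespan_range[1] >= lifespan_range[2]) stop("need low < high")
  life <- .with_seed(seed,
    stats::runif(n_strains, lifespan_range[1], lifespan_range[2]))
  lifespan_table(sprintf("SYN%03d", seq_len(n_strains)), life, "combined")
}

#' Generate one synthetic dataset with planted lifespan signal
#'
#' Samples `strains_per_dataset` strains without replacement, fills a
#' background of i.i.d. `N(0, noise_sd^2)` features, and plants each
#' configured gene g as
#' `expr_g = rho * z_L + sqrt(1 - rho^2) * eps`, `eps ~ N(0, 1)`,
#' where `z_L` is the standardized lifespan over the dataset's strain
#' subset -- so the population correlation between `expr_g` and
#' lifespan is exactly `rho`. The dataset's sub-seed is a fixed
#' function of the config seed and `dataset_index`.
#'
#' @param config a [synthetic_config()].
#' @param lifespans the panel [lifespan_table()].
#' @param dataset_index which dataset of the panel to generate.
#' @return list with `dataset` (an [omics_dataset()]) and `truth`
#'   (data frame `dataset_id` / `gene_id` / `rho` / `sign`).
#' @export
generate_dataset <- function(config, lifespans, dataset_index) {
  roster <- .default_roster(config$n_datasets)[dataset_index, ]
  planted <- config$planted[config$planted$dataset_index == dataset_index, ,
                            drop = FALSE]
  res <- .with_seed(.sub_seed(config$seed, dataset_index), {
    sub <- sort(sample.int(config$n_strains, config$strains_per_dataset))
    sid <- lifespans$strain_id[sub]
    life <- lifespans$median_lifespan_days[sub]
    zl <- as.vector(scale(life))
    ns <- length(sid)

    bg_ids <- sprintf("BG%05d", seq_len(config$n_features_per_dataset))
    vals <- matrix(stats::rnorm(config$n_features_per_dataset * ns,
                                sd = config$noise_sd),
                   nrow = config$n_features_per_dataset,
                   dimnames = list(bg_ids, sid))
    if (nrow(planted) > 0L) {
      pl <- t(vapply(planted$rho, function(rho) {
        rho * zl + sqrt(1 - rho^2) * stats::rnorm(ns)
      }, numeric(ns)))
      rownames(pl) <- planted$gene_id
      vals <- rbind(pl, vals)
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(vals)) < config$missing_rate
      vals[drop] <- NA_real_
    }
    vals
  })
  if (config$normalization == "two_z_plus_8") res <- to_two_z_plus_8(res)
  ds <- omics_dataset(res, dataset_id = roster$dataset_id,
                      tissue = roster$tissue, sex = roster$sex,
                      omics_type = roster$omics_type,
                      normalization = config$normalization)
  truth <- if (nrow(planted) > 0L) {
    data.frame(dataset_id = roster$dataset_id, gene_id = planted$gene_id,
               rho = planted$rho, sign = sign(planted$rho),
               stringsAsFactors = FALSE)
  } else {
    data.frame(dataset_id = character(), gene_id = character(),
               rho = numeric(), sign = numeric(), stringsAsFactors = FALSE)
  }
  list(dataset = ds, truth = truth)
}

#' Generate a full multi-dataset synthetic panel
#'
#' Lifespans plus `n_datasets` datasets over partially overlapping
#' strain subsets, with the planted design of the config. Regenerating
#' with the same config (and seed) reproduces the panel exactly.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_panel`: `datasets` (named list of
#'   [omics_dataset()]), `lifespans`, `truth` (per dataset x planted
#'   gene: rho and sign), `roster` (dataset metadata incl. the
#'   per-dataset selection mode), and the `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lifespans <- generate_lifespans(config$n_strains, config$lifespan_range,
                                  seed = .sub_seed(config$seed, 0L))
  out <- lapply(seq_len(config$n_datasets), function(i) {
    generate_dataset(config, lifespans, i)
  })
  datasets <- lapply(out, `[[`, "dataset")
  names(datasets) <- vapply(datasets, `[[`, character(1), "dataset_id")
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  structure(list(datasets = datasets, lifespans = lifespans,
                 truth = truth,
                 roster = .default_roster(config$n_datasets),
                 config = config),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(paste0("synthetic_panel: %d datasets, %d strains, ",
                     "%d planted gene(s), seed %d\n"),
              length(x$datasets), nrow(x$lifespans),
              length(unique(x$truth$gene_id)), x$config$seed))
  invisible(x)
}

#' Write a synthetic panel to a directory in the package's TSV dialects
#'
#' Emits `lifespans.tsv`, one `<dataset_id>.tsv` expression matrix
#' per dataset, and `truth.tsv` with the planted design.
#'
#' @param panel a [generate_panel()] result.
#' @param dir output directory (created if needed).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lifespan_table(panel$lifespans, file.path(dir, "lifespans.tsv"))
  for (ds in panel$datasets) {
    write_expression_matrix(ds, file.path(dir, paste0(ds$dataset_id, ".tsv")))
  }
  tr <- panel$truth
  tr$rho <- .fmt_num(tr$rho)
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
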