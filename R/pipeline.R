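## End-to-end orchestration: simulate or ingest datasets, match and
## select strains, score features against lifespan, collapse to genes,
## merge across datasets, enrich, and emit tidy per-stage TSVs plus a
## machine-readable run report. Output layout: one subdirectory per
## dataset plus a global/ directory, mirroring the per-tissue vs
## panel-wide split of the analysis.

.log_levels <- c(debug = 1L, info = 2L, warning = 3L)

.new_log <- function(level = "info") {
  env <- new.env(parent = emptyenv())
  env$lines <- character()
  env$min <- .log_levels[[level]]
  env
}

.log <- function(log, level, ...) {
  if (.log_levels[[level]] >= log$min) {
    line <- paste0("[", level, "] ", paste0(..., collapse = ""))
    log$lines <- c(log$lines, line)
    message(line)
  }
  invisible(NULL)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' The two formats carry the same schema; the file extension picks
#' the parser (`.yaml`/`.yml` vs `.json`).
#'
#' @param path path to the config file.
#' @return a named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported config extension '", ext, "' (use yaml or json)"))
  cfg
}

.default_run_config <- function() {
  list(thresholds = c(0.4, 0.7),
       sex_policy = "match_sex",
       tail_size = 4L,
       min_obs = 6L,
       top_k = 6L,
       top_n_shared = 10L,
       log_level = "info",
       seed = 1L)
}

.ingest_datasets <- function(config, log) {
  if (!is.null(config$simulate)) {
    .log(log, "info", "stage simulate: generating synthetic panel")
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    if (!is.null(sim_args$planted) && !is.data.frame(sim_args$planted)) {
      p <- sim_args$planted
      nd <- if (is.null(sim_args$n_datasets)) 8L else sim_args$n_datasets
      sim_args$planted <- if (!is.null(p$n_universal) || !is.null(p$rho)) {
        # shortcut form: {n_universal: 2, rho: 0.95}
        planted_universal_genes(
          nd,
          n_universal = if (is.null(p$n_universal)) 2L else p$n_universal,
          rho = if (is.null(p$rho)) 0.95 else p$rho)
      } else {
        # explicit form: list of {gene_id, dataset_index, rho} records
        do.call(rbind, lapply(p, as.data.frame))
      }
    }
    scfg <- do.call(synthetic_config, sim_args)
    panel <- generate_panel(scfg)
    modes <- panel$roster$selection_mode
    names(modes) <- panel$roster$dataset_id
    list(datasets = panel$datasets, lifespans = panel$lifespans,
         modes = modes, panel = panel)
  } else {
    if (is.null(config$datasets) || is.null(config$lifespan_table)) {
      stop("config needs either 'simulate' or 'datasets' + 'lifespan_table'")
    }
    datasets <- list()
    modes <- character()
    for (d in config$datasets) {
      ds <- read_expression_matrix(
        d$path, dataset_id = d$dataset_id,
        tissue = if (is.null(d$tissue)) "unknown" else d$tissue,
        sex = if (is.null(d$sex)) "combined" else d$sex,
        omics_type = if (is.null(d$omics_type)) "transcript" else d$omics_type,
        normalization = if (is.null(d$normalization)) "zscore" else d$normalization,
        transpose = isTRUE(d$transpose))
      datasets[[ds$dataset_id]] <- ds
      modes[ds$dataset_id] <-
        if (is.null(d$selection_mode)) "tails" else d$selection_mode
      .log(log, "info", "stage ingest: read dataset ", ds$dataset_id,
           " (", nrow(ds$values), " features x ", ncol(ds$values), " strains)")
    }
    list(datasets = datasets,
         lifespans = read_lifespan_table(config$lifespan_table),
         modes = modes, panel = NULL)
  }
}

#' Run the full lifespan-correlation pipeline
#'
#' Executes simulate/ingest, strain selection, per-dataset longevity
#' scoring, optional probe-to-gene collapse, cross-dataset overlap and
#' shared-gene ranking, optional gene-set enrichment, and the figure
#' tables; writes every stage output under `out_dir` and returns the
#' run report. The run is deterministic given the config and seed:
#' rerunning with identical inputs reproduces every output file
#' byte for byte.
#'
#' @param config a named list (or path to a YAML/JSON file, see
#'   [read_run_config()]) with either a `simulate` block
#'   ([synthetic_config()] arguments) or `datasets` (list of
#'   path + metadata entries) plus `lifespan_table`; optional
#'   `gene_map`, `gene_sets` (GMT path), `thresholds` (default
#'   0.4/0.7), `sex_policy`, `tail_size`, `min_obs`, `top_k`,
#'   `top_n_shared`, `seed`, `log_level`.
#' @param out_dir output directory; defaults to `config$output_dir`.
#' @return invisibly, a `run_report` list: per-dataset counts, the
#'   global summaries, and the in-memory stage results (`$results`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  config <- utils::modifyList(.default_run_config(), config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  if (is.null(out_dir)) stop("no output directory (out_dir / config$output_dir)")
  log <- .new_log(config$log_level)
  dir.create(file.path(out_dir, "global"), recursive = TRUE,
             showWarnings = FALSE)
  thresholds <- sort(as.numeric(config$thresholds))
  th_main <- thresholds[1L]

  ing <- withCallingHandlers(
    .ingest_datasets(config, log),
    warning = function(w) .log(log, "warning", "stage ingest: ",
                               conditionMessage(w)))
  datasets <- ing$datasets
  lifespans <- ing$lifespans

  gene_map <- if (!is.null(config$gene_map)) {
    read_feature_gene_map(config$gene_map)
  } else NULL
  gene_sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
               else NULL

  per_dataset <- list()
  plans <- list()
  score_tables <- list()
  gene_tables <- list()

  for (id in names(datasets)) {
    ds <- datasets[[id]]
    ds_dir <- file.path(out_dir, id)
    dir.create(ds_dir, showWarnings = FALSE)

    matched <- tryCatch(
      withCallingHandlers(
        match_strains(ds, lifespans, sex_policy = config$sex_policy),
        message = function(m) {
          .log(log, "info", "stage select [", id, "]: ",
               sub("\n$", "", conditionMessage(m)))
          invokeRestart("muffleMessage")
        }),
      error = function(e) stop("stage select [", id, "]: ",
                               conditionMessage(e), call. = FALSE))
    mode <- if (id %in% names(ing$modes)) ing$modes[[id]] else "tails"
    plan <- withCallingHandlers(
      select_extremes(matched, mode = mode, tail_size = config$tail_size),
      warning = function(w) {
        .log(log, "warning", "stage select [", id, "]: ",
             conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    plans[[id]] <- plan
    utils::write.table(selection_plan_table(plan),
                       file.path(ds_dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    scores <- tryCatch(
      score_dataset(ds, plan, thresholds = thresholds,
                    min_obs = config$min_obs),
      error = function(e) stop("stage score [", id, "]: ",
                               conditionMessage(e), call. = FALSE))
    score_tables[[id]] <- scores
    write_score_table(scores, file.path(ds_dir, "scores.tsv"))

    gt <- if (!is.null(gene_map)) {
      withCallingHandlers(
        collapse_features_to_genes(scores, gene_map),
        message = function(m) {
          .log(log, "info", "stage collapse [", id, "]: ",
               sub("\n$", "", conditionMessage(m)))
          invokeRestart("muffleMessage")
        })
    } else {
      scores   # feature ids already are gene ids
    }
    gene_tables[[id]] <- gt
    write_score_table(gt, file.path(ds_dir, "gene_scores.tsv"))

    n_undef <- sum(is.na(scores$r))
    hits <- vapply(thresholds, function(th) nrow(vetted(gt, th)), integer(1))
    names(hits) <- .pass_col(thresholds)
    per_dataset[[id]] <- list(
      dataset_id = id, tissue = ds$tissue, sex = ds$sex,
      omics_type = ds$omics_type,
      selection_mode = plan$mode,
      strains_matched = nrow(matched),
      strains_selected = nrow(plan$selected),
      features_scored = nrow(scores),
      features_undefined = n_undef,
      hits = as.list(hits))
    .log(log, "info", "stage score [", id, "]: ", nrow(scores),
         " features, ", n_undef, " undefined, ",
         paste(sprintf("%s=%d", names(hits), hits), collapse = ", "))
  }

  overlaps <- list()
  if (length(gene_tables) >= 2L) {
    for (th in thresholds) {
      ov <- overlap_matrix(gene_tables, threshold = th)
      overlaps[[.pass_col(th)]] <- ov
      write_overlap_table(ov, file.path(out_dir, "global",
                                        sprintf("overlap_%s.tsv",
                                                .pass_col(th))))
    }
  } else {
    .log(log, "info", "stage overlap: skipped (single dataset)")
  }

  ranking <- shared_gene_ranking(gene_tables, threshold = th_main)
  write_score_like <- function(df, path) {
    out <- df
    for (nm in names(out)) {
      if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
        out[[nm]] <- .fmt_num(out[[nm]])
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  write_score_like(ranking, file.path(out_dir, "global", "shared_ranking.tsv"))

  hist <- presence_histogram(ranking)
  utils::write.table(
    data.frame(presence_count = as.integer(names(hist)),
               n_genes = as.integer(hist)),
    file.path(out_dir, "global", "presence_histogram.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  pattern <- sign_pattern_matrix(ranking, top_n = config$top_n_shared)
  write_score_like(
    data.frame(gene_id = rownames(pattern), as.data.frame(pattern),
               check.names = FALSE),
    file.path(out_dir, "global", "sign_pattern.tsv"))

  enrichments <- list()
  if (!is.null(gene_sets)) {
    for (id in names(gene_tables)) {
      gt <- gene_tables[[id]]
      universe <- .score_key(gt)
      hits <- .score_key(vetted(gt, th_main))
      er <- tryCatch(
        run_enrichment(hits, universe, gene_sets),
        error = function(e) stop("stage enrich [", id, "]: ",
                                 conditionMessage(e), call. = FALSE))
      enrichments[[id]] <- er
      write_enrichment_table(er, file.path(out_dir, id, "enrichment.tsv"))
      .log(log, "info", "stage enrich [", id, "]: ", nrow(er),
           " sets tested, ", sum(er$fdr < 0.05), " at FDR < 0.05")
    }
  }

  figures <- make_figure_tables(
    plans = plans, score_tables = score_tables, gene_tables = gene_tables,
    ranking = ranking, overlaps = overlaps, datasets = datasets,
    top_k = config$top_k, top_n_shared = config$top_n_shared)
  for (nm in names(figures)) {
    write_score_like(figures[[nm]],
                     file.path(out_dir, "global", paste0(nm, ".tsv")))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("lifecor")),
    seed = config$seed,
    thresholds = thresholds,
    n_datasets = length(datasets),
    per_dataset = per_dataset,
    presence_histogram = as.list(hist),
    top_shared_genes = utils::head(ranking$gene_id, config$top_n_shared),
    n_ranked_genes = nrow(ranking),
    config = config[setdiff(names(config), "output_dir")])
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log$lines, file.path(out_dir, "run.log"))

  report$results <- list(datasets = datasets, lifespans = lifespans,
                         plans = plans, score_tables = score_tables,
                         gene_tables = gene_tables, ranking = ranking,
                         overlaps = overlaps, enrichments = enrichments,
                         figures = figures,
                         truth = if (!is.null(ing$panel)) ing$panel$truth)
  class(report) <- "run_report"
  invisible(report)
}

#' Build tidy per-figure tables from pipeline stage results
#'
#' One tidy table per display of the analysis: ranked lifespans with
#' tail flags (per dataset), top-k features by |r| per dataset, the
#' pairwise overlap fractions, the sign-pattern matrix of the top
#' shared genes, and expression-vs-lifespan points for the top shared
#' genes over the selected strains.
#'
#' @param plans named list of selection plans.
#' @param score_tables,gene_tables named lists of score tables.
#' @param ranking a [shared_gene_ranking()].
#' @param overlaps named list of [overlap_matrix()] results.
#' @param datasets named list of [omics_dataset()].
#' @param top_k features per dataset in the top-gene table.
#' @param top_n_shared genes in the sign-pattern and points tables.
#' @return named list of data frames.
#' @export
make_figure_tables <- function(plans, score_tables, gene_tables, ranking,
                               overlaps, datasets, top_k = 6L,
                               top_n_shared = 10L) {
  fig1 <- do.call(rbind, lapply(names(plans), function(id) {
    cbind(dataset_id = id, selection_plan_table(plans[[id]]))
  }))

  fig2 <- do.call(rbind, lapply(names(score_tables), function(id) {
    top <- top_k_features(score_tables[[id]], top_k)
    if (nrow(top) > 0L) cbind(top, rank = seq_len(nrow(top))) else NULL
  }))

  fig4 <- if (length(overlaps)) {
    do.call(rbind, lapply(names(overlaps), function(nm) {
      cbind(threshold = overlaps[[nm]]$threshold, overlaps[[nm]]$pairs)
    }))
  } else {
    data.frame(threshold = numeric(), dataset_a = character(),
               dataset_b = character(), fraction = numeric())
  }

  pattern <- sign_pattern_matrix(ranking, top_n = max(1L, top_n_shared))
  fig5 <- data.frame(gene_id = rownames(pattern), as.data.frame(pattern),
                     check.names = FALSE)

  top_genes <- utils::head(ranking$gene_id, top_n_shared)
  fig6 <- do.call(rbind, lapply(names(datasets), function(id) {
    ds <- as_zscore(datasets[[id]])
    sel <- plans[[id]]$selected
    g <- intersect(top_genes, rownames(ds$values))
    if (!length(g)) return(NULL)
    expr <- ds$values[g, sel$strain_id, drop = FALSE]
    data.frame(dataset_id = id,
               gene_id = rep(g, each = nrow(sel)),
               strain_id = rep(sel$strain_id, times = length(g)),
               median_lifespan_days = rep(sel$median_lifespan_days,
                                          times = length(g)),
               expression = as.vector(t(expr)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(fig6)) {
    fig6 <- data.frame(dataset_id = character(), gene_id = character(),
                       strain_id = character(),
                       median_lifespan_days = numeric(),
                       expression = numeric())
  }

  list(fig1_lifespan_ranking = fig1,
       fig2_top_features = fig2,
       fig4_overlap = fig4,
       fig5_sign_pattern = fig5,
       fig6_top_gene_points = fig6)
}

#' Audit a run report against the files it describes
#'
#' Recomputes the per-dataset and global counts from the TSVs emitted
#' by [run_pipeline()] and checks them against the report, so any
#' drift between the summary and the artifacts is caught.
#'
#' @param out_dir the pipeline output directory.
#' @return `TRUE` invisibly; stops with a description on mismatch.
#' @export
audit_run_report <- function(out_dir) {
  report <- jsonlite::fromJSON(file.path(out_dir, "run_report.json"),
                               simplifyDataFrame = FALSE)
  for (pd in report$per_dataset) {
    id <- pd$dataset_id
    sel <- utils::read.delim(file.path(out_dir, id, "selection.tsv"))
    if (nrow(sel) != pd$strains_matched ||
        sum(sel$selected) != pd$strains_selected) {
      stop("selection counts for ", id, " disagree with selection.tsv")
    }
    sc <- read_score_table(file.path(out_dir, id, "scores.tsv"))
    if (nrow(sc) != pd$features_scored ||
        sum(is.na(sc$r)) != pd$features_undefined) {
      stop("score counts for ", id, " disagree with scores.tsv")
    }
    gt <- read_score_table(file.path(out_dir, id, "gene_scores.tsv"))
    for (nm in names(pd$hits)) {
      th <- .pass_col_threshold(nm)
      if (nrow(vetted(gt, th)) != pd$hits[[nm]]) {
        stop("hit count ", nm, " for ", id, " disagrees with gene_scores.tsv")
      }
    }
  }
  rk <- utils::read.delim(file.path(out_dir, "global", "shared_ranking.tsv"))
  if (nrow(rk) != report$n_ranked_genes) {
    stop("ranked gene count disagrees with shared_ranking.tsv")
  }
  hist <- utils::read.delim(file.path(out_dir, "global",
                                      "presence_histogram.tsv"))
  if (sum(hist$n_genes) != nrow(rk)) {
    stop("presence histogram does not sum to the number of ranked genes")
  }
  rep_hist <- unlist(report$presence_histogram)
  if (!identical(as.integer(hist$n_genes),
                 as.integer(rep_hist[as.character(hist$presence_count)]))) {
    stop("presence histogram disagrees with run_report.json")
  }
  invisible(TRUE)
}
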