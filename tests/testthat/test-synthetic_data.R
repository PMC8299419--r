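test_that("generated lifespans are in range, distinct-named, deterministic", {
  lt <- generate_lifespans(30, c(450, 900), seed = 3)
  expect_equal(nrow(lt), 30L)
  expect_true(all(lt$median_lifespan_days >= 450 &
                  lt$median_lifespan_days <= 900))
  expect_lte(max(lt$median_lifespan_days) / min(lt$median_lifespan_days), 2)
  expect_false(anyDuplicated(lt$strain_id) > 0)
  expect_identical(generate_lifespans(30, c(450, 900), seed = 3), lt)
  expect_false(identical(generate_lifespans(30, c(450, 900), seed = 4), lt))

  lt2 <- generate_lifespans(2, c(450, 900), seed = 1)
  expect_equal(nrow(lt2), 2L)
  expect_error(generate_lifespans(1), ">= 2")
  expect_error(generate_lifespans(10, c(900, 450)), "low < high")
})

test_that("planted correlation is recovered at large sample size", {
  cfg <- synthetic_config(
    n_strains = 10000, strains_per_dataset = 10000, n_datasets = 1,
    n_features_per_dataset = 5,
    planted = data.frame(gene_id = c("P9", "P0"), dataset_index = 1,
                         rho = c(0.9, 0)),
    seed = 21)
  lt <- generate_lifespans(cfg$n_strains, cfg$lifespan_range, seed = 99)
  out <- generate_dataset(cfg, lt, 1)
  life <- lt$median_lifespan_days
  r9 <- cor(out$dataset$values["P9", ], life)
  r0 <- cor(out$dataset$values["P0", ], life)
  expect_gte(r9, 0.89); expect_lte(r9, 0.91)
  expect_lt(abs(r0), 0.03)
})

test_that("rho = 1 plants an exactly linear feature", {
  cfg <- synthetic_config(
    n_strains = 12, strains_per_dataset = 12, n_datasets = 1,
    n_features_per_dataset = 2,
    planted = data.frame(gene_id = "P1", dataset_index = 1, rho = 1),
    seed = 8)
  lt <- generate_lifespans(12, seed = 8)
  out <- generate_dataset(cfg, lt, 1)
  expect_equal(cor(out$dataset$values["P1", ], lt$median_lifespan_days), 1,
               tolerance = 1e-12)
})

test_that("panel construction, truth bookkeeping and determinism", {
  cfg <- synthetic_config(seed = 5)
  panel <- generate_panel(cfg)
  expect_length(panel$datasets, 8L)
  expect_equal(table(panel$truth$gene_id),
               table(rep(c("UNIV01", "UNIV02"), each = 8)))
  # tissue-specific signs: both signs present for each universal gene
  for (g in c("UNIV01", "UNIV02")) {
    s <- panel$truth$sign[panel$truth$gene_id == g]
    expect_setequal(unique(s), c(-1, 1))
  }
  # truth consistent with emitted datasets
  for (i in seq_len(nrow(panel$truth))) {
    ds <- panel$datasets[[panel$truth$dataset_id[i]]]
    expect_true(panel$truth$gene_id[i] %in% rownames(ds$values))
  }
  # strain subsets are proper, partially overlapping subsets of the panel
  subs <- lapply(panel$datasets, strain_ids)
  expect_true(all(vapply(subs, function(s)
    all(s %in% panel$lifespans$strain_id), logical(1))))
  expect_gt(length(Reduce(union, subs)), cfg$strains_per_dataset)

  panel2 <- generate_panel(synthetic_config(seed = 5))
  expect_identical(panel2$datasets, panel$datasets)
  expect_identical(panel2$lifespans, panel$lifespans)

  empty <- generate_panel(synthetic_config(
    n_datasets = 2, n_features_per_dataset = 10,
    planted = planted_universal_genes(2, n_universal = 0), seed = 1))
  expect_equal(nrow(empty$truth), 0L)
})

test_that("adding datasets does not reshuffle earlier ones", {
  des <- planted_universal_genes(5)
  mk <- function(nd) generate_panel(synthetic_config(
    n_datasets = nd, n_features_per_dataset = 20,
    planted = des[des$dataset_index <= nd, ], seed = 11))
  p3 <- mk(3)
  p5 <- mk(5)
  expect_identical(p3$datasets[[1]]$values, p5$datasets[[1]]$values)
  expect_identical(p3$datasets[[3]]$values, p5$datasets[[3]]$values)
})

test_that("missing injection and output normalization conventions", {
  cfg <- synthetic_config(n_datasets = 1, n_features_per_dataset = 200,
                          planted = planted_universal_genes(1, 0),
                          missing_rate = 0.1, seed = 2)
  lt <- generate_lifespans(cfg$n_strains, seed = 1)
  out <- generate_dataset(cfg, lt, 1)
  frac_na <- mean(is.na(out$dataset$values))
  expect_gt(frac_na, 0.05); expect_lt(frac_na, 0.15)

  cfg8 <- synthetic_config(n_datasets = 1, n_features_per_dataset = 500,
                           planted = planted_universal_genes(1, 0),
                           normalization = "two_z_plus_8", seed = 2)
  out8 <- generate_dataset(cfg8, lt, 1)
  expect_equal(out8$dataset$normalization, "two_z_plus_8")
  expect_equal(mean(out8$dataset$values), 8, tolerance = 0.1)
  expect_equal(sd(out8$dataset$values), 2, tolerance = 0.1)
})

test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(strains_per_dataset = 100, n_strains = 50),
               "strains_per_dataset")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(
    planted = data.frame(gene_id = "g", dataset_index = 1, rho = 1.2)),
    "rho")
  expect_error(synthetic_config(
    planted = data.frame(gene_id = "g", dataset_index = 99, rho = 0.5)),
    "dataset_index")
})

test_that("background null calibration over 8 extreme strains", {
  # background genes are independent of lifespan: the fraction with
  # |r| >= 0.4 over 8 strains should match the analytic t-tail (~0.33)
  cfg <- synthetic_config(n_strains = 8, strains_per_dataset = 8,
                          n_datasets = 1, n_features_per_dataset = 5000,
                          planted = planted_universal_genes(1, 0), seed = 31)
  lt <- generate_lifespans(8, seed = 77)
  ds <- generate_dataset(cfg, lt, 1)$dataset
  r <- as.vector(cor(t(ds$values), lt$median_lifespan_days))
  t_star <- 0.4 * sqrt(6 / (1 - 0.16))
  p_null <- 2 * pt(t_star, 6, lower.tail = FALSE)
  expect_close(mean(abs(r) >= 0.4), p_null, 0.02)
})

test_that("panel round trips through the TSV dialects", {
  cfg <- synthetic_config(n_datasets = 2, n_features_per_dataset = 30,
                          planted = planted_universal_genes(2), seed = 13)
  panel <- generate_panel(cfg)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  back <- read_expression_matrix(
    file.path(dir, "adrenal_m.tsv"), dataset_id = "adrenal_m", sex = "male")
  expect_identical(back$values, panel$datasets$adrenal_m$values)
  lt <- read_lifespan_table(file.path(dir, "lifespans.tsv"))
  expect_equal(lt$median_lifespan_days, panel$lifespans$median_lifespan_days)
})
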