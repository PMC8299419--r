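test_that("overlap fraction is Jaccard over the shared measured universe", {
  ta <- make_score_table("A", c("g1", "g2", "g3", "g4", "g5"),
                         c(0.8, 0.9, -0.5, 0.1, 0.2))
  tb <- make_score_table("B", c("g1", "g2", "g3", "g4", "g5"),
                         c(0.1, 0.7, 0.6, -0.9, 0.0))
  ov <- overlap_matrix(list(ta, tb), threshold = 0.4)
  # hits A = {g1,g2,g3}, hits B = {g2,g3,g4}: 2 / 4
  expect_equal(ov$fraction["A", "B"], 0.5)
  expect_equal(ov$fraction["B", "A"], 0.5)
  expect_equal(ov$fraction["A", "A"], 1)
  pr <- ov$pairs[ov$pairs$dataset_a == "A" & ov$pairs$dataset_b == "B", ]
  expect_equal(pr$n_intersection, 2L)
  expect_equal(pr$n_union, 4L)

  # identical and disjoint hit sets
  expect_equal(overlap_matrix(list(ta, ta2 <- transform(ta, dataset_id = "C")),
                              0.4)$fraction["A", "C"], 1)
  td <- make_score_table("D", c("g1", "g2", "g3", "g4", "g5"),
                         c(0.1, 0.2, 0.1, -0.9, 0.8))
  expect_equal(overlap_matrix(list(ta, td), 0.4)$fraction["A", "D"], 0)

  expect_error(overlap_matrix(list(ta)), "at least 2")
})

test_that("overlap restricts hit sets to genes measured in both datasets", {
  ta <- make_score_table("A", c("g1", "g2", "g3"), c(0.8, 0.9, 0.5))
  tb <- make_score_table("B", c("g2", "g3"), c(0.7, 0.1))
  ov <- overlap_matrix(list(ta, tb), 0.4)
  # shared universe {g2,g3}; hits A -> {g2,g3}, hits B -> {g2}: 1/2
  expect_equal(ov$fraction["A", "B"], 0.5)
  # empty union -> undefined marker
  t0a <- make_score_table("A", c("g1", "g2"), c(0.1, NA))
  t0b <- make_score_table("B", c("g1", "g2"), c(0.2, 0.1))
  expect_true(is.na(overlap_matrix(list(t0a, t0b), 0.4)$fraction["A", "B"]))
})

test_that("shared-gene ranking sorts by presence, then mean |r|, then id", {
  t1 <- make_score_table("d1", c("X", "Y", "Z"), c(0.6, 0.9, 0.41))
  t2 <- make_score_table("d2", c("X", "Y", "Z"), c(-0.6, 0.9, 0.41))
  t3 <- make_score_table("d3", c("X", "Y", "W"), c(0.6, 0.2, 0.9))
  rk <- shared_gene_ranking(list(t1, t2, t3), 0.4)
  expect_equal(rk$gene_id[1], "X")        # 3/3 beats 2/3 despite lower |r|
  expect_equal(rk$presence_count[rk$gene_id == "X"], 3L)
  expect_equal(rk$mean_abs_r[rk$gene_id == "X"], 0.6)
  expect_equal(rk$presence_count[rk$gene_id == "Y"], 2L)
  expect_equal(rk$n_measured[rk$gene_id == "W"], 1L)
  # signed r preserved per dataset; failing datasets are NA
  expect_equal(rk$r_d2[rk$gene_id == "X"], -0.6)
  expect_true(is.na(rk$r_d3[rk$gene_id == "Y"]))
  # tie in presence and mean |r| broken by gene id
  same <- shared_gene_ranking(
    list(make_score_table("d1", c("B", "A"), c(0.5, 0.5))), 0.4)
  expect_equal(same$gene_id, c("A", "B"))

  none <- shared_gene_ranking(
    list(make_score_table("d1", c("a", "b"), c(0.1, NA))), 0.4)
  expect_equal(nrow(none), 0L)
})

test_that("presence histogram counts genes exactly and conserves totals", {
  t1 <- make_score_table("d1", c("X", "Y", "Z"), c(0.6, 0.9, 0.1))
  t2 <- make_score_table("d2", c("X", "Y"), c(0.6, 0.2))
  rk <- shared_gene_ranking(list(t1, t2), 0.4)
  h <- presence_histogram(rk)
  expect_equal(as.integer(h[c("1", "2")]), c(1L, 1L))
  expect_equal(sum(h), nrow(rk))
  empty <- shared_gene_ranking(
    list(make_score_table("d1", "a", 0.1),
         make_score_table("d2", "a", 0.1)), 0.4)
  expect_true(all(presence_histogram(empty) == 0))
})

test_that("sign-pattern matrix keeps signed r and explicit missingness", {
  tables <- lapply(1:8, function(i) {
    rho <- if (i <= 4) 0.9 else -0.9
    make_score_table(paste0("d", i), c("U", "bg"), c(rho, 0.05))
  })
  rk <- shared_gene_ranking(tables, 0.4)
  m <- sign_pattern_matrix(rk, top_n = 10)
  expect_lte(nrow(m), 10L)
  expect_equal(sum(m["U", ] > 0), 4L)
  expect_equal(sum(m["U", ] < 0), 4L)
  expect_error(sign_pattern_matrix(rk, 0), "positive")

  # unmeasured gene -> NA marker, never 0
  t1 <- make_score_table("d1", c("A", "B"), c(0.8, 0.5))
  t2 <- make_score_table("d2", "A", 0.9)
  m2 <- sign_pattern_matrix(shared_gene_ranking(list(t1, t2), 0.4), 5)
  expect_true(is.na(m2["B", "d2"]))
})

test_that("raising the threshold never increases presence or overlap", {
  panel <- generate_panel(synthetic_config(
    n_features_per_dataset = 100, seed = 17))
  tables <- lapply(panel$datasets, function(ds) {
    plan <- select_extremes(match_strains(ds, panel$lifespans,
                                          sex_policy = "any"),
                            mode = "tails")
    score_dataset(ds, plan)
  })
  for (pair in list(c(0.4, 0.5), c(0.5, 0.7), c(0.4, 0.7))) {
    lo <- shared_gene_ranking(tables, pair[1])
    hi <- shared_gene_ranking(tables, pair[2])
    common <- intersect(lo$gene_id, hi$gene_id)
    expect_true(all(hi$presence_count[match(common, hi$gene_id)] <=
                    lo$presence_count[match(common, lo$gene_id)]))
    expect_true(all(hi$gene_id %in% lo$gene_id))
    # hit sets shrink with the threshold, so intersections, unions and
    # the universe-normalized overlap are all non-increasing (the
    # Jaccard ratio itself may tick up when the union shrinks faster)
    p_lo <- overlap_matrix(tables, pair[1])$pairs
    p_hi <- overlap_matrix(tables, pair[2])$pairs
    expect_true(all(p_hi$n_intersection <= p_lo$n_intersection))
    expect_true(all(p_hi$n_union <= p_lo$n_union))
    both <- !is.na(p_lo$fraction_of_universe) &
            !is.na(p_hi$fraction_of_universe)
    expect_true(all(p_hi$fraction_of_universe[both] <=
                    p_lo$fraction_of_universe[both] + 1e-12))
  }
})

test_that("background-only presence counts follow the null binomial model", {
  # independent datasets over 8 extreme strains: presence ~ Bin(k, p0)
  # with p0 the analytic null pass rate at |r| >= 0.4, n = 8
  panel <- generate_panel(synthetic_config(
    n_strains = 40, strains_per_dataset = 20, n_datasets = 8,
    n_features_per_dataset = 600,
    planted = planted_universal_genes(8, n_universal = 0), seed = 23))
  tables <- lapply(panel$datasets, function(ds) {
    plan <- select_extremes(match_strains(ds, panel$lifespans,
                                          sex_policy = "any"),
                            mode = "tails")
    score_dataset(ds, plan)
  })
  rk <- shared_gene_ranking(tables, 0.4)
  h <- presence_histogram(rk)
  n_genes <- 600
  h["0"] <- n_genes - sum(h)
  p0 <- 2 * pt(0.4 * sqrt(6 / 0.84), 6, lower.tail = FALSE)
  expected <- dbinom(0:8, 8, p0) * n_genes
  # goodness of fit over pooled tails (expected count >= 5)
  pool <- pmin(0:8, 6)
  obs <- tapply(as.integer(h), pool, sum)
  exp <- tapply(expected, pool, sum)
  chi <- sum((obs - exp)^2 / exp)
  expect_lt(chi, qchisq(0.999, df = length(obs) - 1))
  # mean presence within Monte-Carlo tolerance of 8 * p0
  mean_pres <- sum(as.integer(h) * 0:8) / n_genes
  expect_equal(mean_pres, 8 * p0, tolerance = 0.1)
})
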