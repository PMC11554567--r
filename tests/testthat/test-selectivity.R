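test_that("activity is CPM over induced replicates and shares normalise", {
  one <- make_counts(tibble::tibble(contig = "c", pos = 1L, ref = "C",
                                    alt = "T"),
                     depth = 100, af_induced = 0.05, mapped = 1e6)
  a <- activity_per_dvr(one, induced = "induced")
  expect_equal(a$activity, 5)
  expect_equal(a$share, 1)

  two <- dplyr::bind_rows(
    make_counts(tibble::tibble(contig = "c", pos = 1L, ref = "C", alt = "T"),
                depth = 100, af_induced = 0.05),
    make_counts(tibble::tibble(contig = "c", pos = 50L, ref = "C", alt = "T"),
                depth = 100, af_induced = 0.05))
  a2 <- activity_per_dvr(two, induced = "induced")
  expect_equal(a2$share, c(0.5, 0.5))
  expect_equal(sum(a2$share), 1, tolerance = 1e-9)

  # doubling library sizes halves activities, leaves shares unchanged
  doubled <- dplyr::mutate(two, mapped_reads = mapped_reads * 2)
  a3 <- activity_per_dvr(doubled, induced = "induced")
  expect_equal(a3$activity, a2$activity / 2)
  expect_equal(a3$share, a2$share)

  zero <- make_counts(tibble::tibble(contig = "c", pos = 1L, ref = "C",
                                     alt = "T"), depth = 100)
  expect_error(activity_per_dvr(zero, induced = "induced"), "zero")
})

test_that("Gini agrees with the pairwise mean-absolute-difference oracle", {
  expect_equal(lorenz_gini(c(1, 1, 1, 1))$gini, 0, tolerance = 1e-12)
  expect_equal(lorenz_gini(c(0, 0, 0, 1))$gini, 0.75, tolerance = 1e-12)

  pairwise_gini <- function(x) {
    n <- length(x)
    sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  }
  withr::with_seed(31, {
    for (r in 1:100) {
      x <- rgamma(sample(2:40, 1), shape = runif(1, 0.2, 3))
      expect_equal(lorenz_gini(x)$gini, pairwise_gini(x), tolerance = 1e-9)
    }
  })

  # maximum-inequality limit: one nonzero among many
  g_limit <- lorenz_gini(c(rep(0, 999), 1))$gini
  expect_gt(g_limit, 0.99)
  expect_lt(g_limit, 1)
  expect_error(lorenz_gini(c(0, 0)), "zero")
})

test_that("Gini is scale- and permutation-invariant, monotone in zeros", {
  withr::with_seed(13, x <- rgamma(25, 1))
  g <- lorenz_gini(x)$gini
  expect_equal(lorenz_gini(7.3 * x)$gini, g, tolerance = 1e-12)
  expect_equal(lorenz_gini(sample(x))$gini, g, tolerance = 1e-12)
  expect_gte(lorenz_gini(c(x, 0))$gini, g)
})

test_that("the Lorenz curve is a valid convex cumulative-share curve", {
  withr::with_seed(17, x <- rgamma(30, 0.5))
  lor <- lorenz_gini(x)
  cv <- lor$curve
  expect_equal(cv$rank_frac[1], 0)
  expect_equal(cv$cum_share[1], 0)
  expect_equal(cv$rank_frac[nrow(cv)], 1)
  expect_equal(cv$cum_share[nrow(cv)], 1, tolerance = 1e-12)
  expect_true(all(diff(cv$cum_share) >= 0))
  expect_true(all(diff(diff(cv$cum_share)) >= -1e-12))  # convex
  expect_true(all(cv$cum_share <= cv$rank_frac + 1e-12))
  expect_equal(glance(lor)$gini, lor$gini)
})

test_that("gene concentration finds the smallest covering gene set", {
  shares <- tibble::tibble(gene_id = c("g1", "g2"), share = c(0.3, 0.7))
  conc <- gene_concentration(shares, target = 0.4)
  expect_equal(attr(conc, "k_genes"), 1L)
  expect_equal(conc$gene_id[1], "g2")

  equal10 <- tibble::tibble(gene_id = paste0("g", 1:10), share = rep(0.1, 10))
  expect_equal(attr(gene_concentration(equal10, target = 0.4), "k_genes"), 4L)

  # shares of multiple DVRs per gene aggregate; totals conserved
  multi <- tibble::tibble(gene_id = c("a", "a", "b", NA),
                          share = c(0.2, 0.3, 0.4, 0.1))
  conc2 <- gene_concentration(multi)
  expect_equal(sum(conc2$share), 1, tolerance = 1e-12)
  expect_equal(conc2$share[conc2$gene_id == "a"], 0.5)
  expect_true("NA" %in% conc2$gene_id)
})

test_that("editing concentration rises with the planted Zipf exponent", {
  gene_gini_for <- function(alpha) {
    cfg <- sim_config(seed = 404, n_genes = 30, n_cu_edits = 60,
                      n_ag_edits = 0, n_dna_snvs = 0, n_null_sites = 0,
                      depth_mean = 80, selectivity_alpha = alpha)
    ref <- simulate_reference(cfg)
    planted <- plant_sites(ref, cfg)
    counts <- simulate_counts(planted$truth, cfg)
    act <- activity_per_dvr(counts, induced = "induced",
                            sites = planted$truth)
    per_gene <- gene_concentration(act)
    # activity concentration over all genes, unedited ones at zero
    shares <- per_gene$share[match(ref$genes$gene_id, per_gene$gene_id)]
    shares[is.na(shares)] <- 0
    lorenz_gini(shares)$gini
  }
  expect_lt(gene_gini_for(0), gene_gini_for(1.5))
})
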