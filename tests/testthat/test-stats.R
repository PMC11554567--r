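test_that("pooled AF and delta AF follow the printed definitions", {
  expect_equal(pooled_af(c(10L, 30L), c(100L, 100L)), 0.2)
  expect_equal(pooled_af(0L, 50L), 0)
  expect_equal(pooled_af(50L, 50L), 1)
  expect_true(is.na(pooled_af(integer(0), integer(0))))

  expect_equal(delta_af(10L, 200L, 40L, 200L), 0.15)
  expect_equal(delta_af(c(5L, 5L), c(50L, 50L), c(5L, 5L), c(50L, 50L)), 0)
  expect_equal(delta_af(50L, 100L, 0L, 100L), -0.5)
  expect_error(delta_af(integer(0), integer(0), 1L, 2L), "both condition")
})

test_that("beta-binomial log-likelihood matches binomial limits and oracle", {
  expect_equal(betabin_loglik(1L, 2L, 0.5, 1e-12), log(0.5), tolerance = 1e-9)

  withr::with_seed(11, {
    for (r in 1:20) {
      n <- sample(10:100, 4, TRUE)
      k <- rbinom(4, n, 0.3)
      pi <- runif(1, 0.05, 0.95)
      expect_equal(betabin_loglik(k, n, pi, 1e-10),
                   sum(dbinom(k, n, pi, log = TRUE)), tolerance = 1e-6)
      # general-rho agreement with the independent pmf formula
      rho <- runif(1, 0.01, 0.4)
      expect_equal(betabin_loglik(k, n, pi, rho), oracle_bb_ll(k, n, pi, rho),
                   tolerance = 1e-9)
    }
  })

  # finite at the pi boundary via the binomial limit
  expect_true(is.finite(betabin_loglik(c(0L, 0L), c(50L, 50L), 0, 1e-12)))
  expect_true(is.finite(betabin_loglik(c(50L, 50L), c(50L, 50L), 1, 1e-12)))
})

test_that("likelihood is maximised near the empirical pooled AF", {
  k <- c(198L, 205L, 201L, 196L)
  n <- rep(1000L, 4)
  grid <- seq(0.01, 0.99, by = 0.001)
  ll <- vapply(grid, function(p) betabin_loglik(k, n, p, 1e-10), numeric(1))
  expect_equal(grid[which.max(ll)], sum(k) / sum(n), tolerance = 2e-3)
})

test_that("LRT is null on identical groups and strong on clean separation", {
  same <- lrt_site(c(5L, 6L, 4L, 5L), rep(100L, 4), c(5L, 6L, 4L, 5L),
                   rep(100L, 4))
  expect_lte(same$lrt_stat, 1e-6)
  expect_gte(same$pvalue, 0.999)
  expect_gte(same$loglik_alt, same$loglik_null - 1e-6)

  sep <- lrt_site(rep(0L, 4), rep(100L, 4), rep(50L, 4), rep(100L, 4))
  expect_lt(sep$pvalue, 1e-7)
  # agreement with the brute-force grid oracle on the same fits
  ora_null <- oracle_grid_null(c(rep(0L, 4), rep(50L, 4)), rep(100L, 8))
  ora_alt <- oracle_grid_alt(rep(0L, 4), rep(100L, 4), rep(50L, 4),
                             rep(100L, 4))
  stat_oracle <- 2 * (ora_alt$ll - ora_null$ll)
  expect_equal(sep$lrt_stat, stat_oracle, tolerance = 1e-3)
})

test_that("MLEs agree with the dense grid-search oracle on random sites", {
  withr::with_seed(202, {
    for (r in 1:6) {
      n1 <- rpois(4, 60) + 10L; n2 <- rpois(4, 60) + 10L
      pi1 <- runif(1, 0.15, 0.85); pi2 <- runif(1, 0.15, 0.85)
      rho <- runif(1, 0.02, 0.2)
      a <- pi1 * (1 - rho) / rho; b <- (1 - pi1) * (1 - rho) / rho
      k1 <- rbinom(4, n1, rbeta(4, a, b))
      a2 <- pi2 * (1 - rho) / rho; b2 <- (1 - pi2) * (1 - rho) / rho
      k2 <- rbinom(4, n2, rbeta(4, a2, b2))
      fit <- lrt_site(k1, n1, k2, n2)
      ora <- oracle_grid_alt(k1, n1, k2, n2)
      expect_equal(fit$pi_ctrl, ora$pi1, tolerance = 1e-3)
      expect_equal(fit$pi_induced, ora$pi2, tolerance = 1e-3)
      expect_equal(fit$rho_alt, ora$rho, tolerance = 1e-3)
      expect_gte(fit$loglik_alt, ora$ll - 1e-4)
    }
  })
})

test_that("tidy and glance expose the fitted model", {
  fit <- lrt_site(c(1L, 2L, 1L, 3L), rep(50L, 4), c(9L, 11L, 10L, 12L),
                  rep(50L, 4))
  td <- tidy(fit)
  expect_equal(td$term, c("pi_null", "pi_ctrl", "pi_induced", "rho_null",
                          "rho_alt"))
  gl <- glance(fit)
  expect_equal(gl$delta_af, gl$af_induced - gl$af_ctrl)
  expect_true(gl$converged)
})

test_that("BH q-values match the hand-computed step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  # hand-computed step-up: m*p/rank = .02,.018,.0667,.5; cummin from the top
  expect_equal(bh_fdr(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.2 / 3, 0.5), tolerance = 1e-12)
  pr <- withr::with_seed(5, runif(50))
  q <- bh_fdr(pr)
  expect_true(all(q <= 1 & q >= 0))
  # monotone: larger p never gets a smaller q
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
})

test_that("edit classification respects transcript strand", {
  expect_equal(classify_edit("C", "T", "+"), "C>U")
  expect_equal(classify_edit("C", "U", "-"), "C>U")
  expect_equal(classify_edit("A", "G", "+"), "A>G(I)")
  expect_equal(classify_edit("C", "A", "+"), "other")
  expect_equal(classify_edit("C", "T", NA), "unstranded")
  # genomic minus-strand events complement before classification upstream:
  ref <- tiny_reference()
  sites <- tibble::tibble(contig = "geneB", pos = 10L, ref = "G", alt = "A")
  ori <- orient_to_transcript(sites, ref$genes)
  expect_equal(classify_edit(ori$ref_ts, ori$alt_ts, ori$strand), "C>U")
})

test_that("call_dvrs produces calibrated joint results on a small table", {
  sites <- tibble::tibble(
    contig = c("geneA", "geneA", "geneB"), pos = c(50L, 120L, 40L),
    ref = c("C", "A", "G"), alt = c("T", "C", "A"))
  counts <- dplyr::bind_rows(
    make_counts(sites[1, ], depth = 200, af_control = 0.01, af_induced = 0.25),
    make_counts(sites[2, ], depth = 200, af_control = 0.02, af_induced = 0.02),
    make_counts(sites[3, ], depth = 200, af_control = 0.01, af_induced = 0.30))
  ref <- tiny_reference()
  res <- call_dvrs(counts, genes = ref$genes)
  expect_s3_class(res, "dvr_results")
  expect_equal(nrow(res), 3L)
  expect_equal(res$fdr, bh_fdr(res$pvalue))
  expect_true(all(res$fdr >= res$pvalue))
  called <- dplyr::filter(res, is_dvr)
  expect_setequal(called$pos, c(50L, 40L))
  expect_equal(dplyr::filter(res, pos == 40L)$class, "C>U")  # minus strand

  bd <- dvr_breakdown(res)
  expect_equal(sum(bd$n), nrow(called))
})

test_that("median LRT statistic is monotone in the planted effect size", {
  meds <- vapply(c(0.05, 0.15, 0.3), function(d) {
    withr::with_seed(77, {
      stats <- vapply(1:25, function(i) {
        n <- rpois(8, 80)
        a_ctrl <- rbinom(4, n[1:4], 0.01)
        a_ind <- rbinom(4, n[5:8], 0.01 + d)
        lrt_site(a_ctrl, n[1:4], a_ind, n[5:8])$lrt_stat
      }, numeric(1))
      median(stats)
    })
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})
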