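test_that("windows are centred, strand-aware and flagged when truncated", {
  ref <- tiny_reference()  # geneA "+": ACGT repeated; geneB "-": GGCA repeated
  win <- extract_window(
    tibble::tibble(contig = "geneA", pos = 150L, strand = "+"),
    ref$reference, width = 100)
  expect_equal(nchar(win$window), 100L)
  expect_equal(win$offset, 51L)
  expect_false(win$truncated)
  # offset marks the edited base: genomic base at 150 is C ("ACGT" phase 2)
  expect_equal(substr(win$window, 51, 51), "C")

  # site at pos 51 of a 100-nt contig: whole contig, offset 51
  small <- Biostrings::DNAStringSet(c(tiny = paste(rep("A", 100),
                                                   collapse = "")))
  w2 <- extract_window(tibble::tibble(contig = "tiny", pos = 51L),
                       small, width = 100)
  expect_equal(nchar(w2$window), 100L)
  expect_equal(w2$offset, 51L)
  expect_false(w2$truncated)

  # truncation near the contig start: 10 - 50 clips to 1, 59 nt remain
  w3 <- extract_window(tibble::tibble(contig = "tiny", pos = 10L),
                       small, width = 100)
  expect_equal(nchar(w3$window), 59L)
  expect_equal(w3$offset, 10L)
  expect_true(w3$truncated)

  # minus strand: reverse complement, offset still marks the edited base
  wm <- extract_window(
    tibble::tibble(contig = "geneB", pos = 150L, strand = "-"),
    ref$reference, width = 100)
  gen_base <- as.character(Biostrings::subseq(ref$reference[["geneB"]],
                                              150, 150))
  expect_equal(substr(wm$window, 51, 51),
               chartr("ACGT", "UGCA", gen_base))

  expect_error(extract_window(tibble::tibble(contig = "nope", pos = 5L),
                              small), "missing from reference")
})

test_that("control-site sampling is deterministic, depth- and motif-aware", {
  ref <- tiny_reference()
  s1 <- sample_control_sites(ref$reference, ref$genes, n = 50, seed = 3)
  s2 <- sample_control_sites(ref$reference, ref$genes, n = 50, seed = 3)
  expect_identical(s1, s2)
  s3 <- sample_control_sites(ref$reference, ref$genes, n = 50, seed = 4)
  expect_false(identical(s1$pos, s3$pos))

  # pool smaller than n: everything returned with a warning
  expect_warning(
    all_of_them <- sample_control_sites(ref$reference, ref$genes, n = 10000),
    "eligible")
  expect_equal(nrow(all_of_them), 600L)

  # motif constraint: every control context matches on the transcript strand
  uucv <- motif_pattern("UUCV", anchor = 3)
  ref2 <- list(
    reference = Biostrings::DNAStringSet(c(
      g1 = paste(rep("AATTCAGGAA", 30), collapse = ""))),
    genes = tibble::tibble(contig = "g1", start = 0L, end = 300L,
                           gene_id = "g1", score = 0, strand = "+",
                           start1 = 1L, end1 = 300L))
  suppressWarnings(
    hits <- sample_control_sites(ref2$reference, ref2$genes, n = 20,
                                 motif = uucv, seed = 1))
  win <- extract_window(hits, ref2$reference, width = 11)
  expect_true(all(match_motif(win$window, win$offset, uucv)))

  # depth restriction through a counts table
  counts <- make_counts(tibble::tibble(contig = "geneA", pos = 42L,
                                       ref = "C", alt = "T"), depth = 50)
  suppressWarnings(
    deep <- sample_control_sites(ref$reference, ref$genes, n = 5,
                                 counts = counts))
  expect_equal(deep$pos, 42L)
})

test_that("loop enrichment reproduces the pooled two-proportion Z formula", {
  # identical fractions: z = 0, p = 1
  same <- loop_enrichment(rep(c(TRUE, FALSE), 10), rep(c(TRUE, FALSE), 50))
  expect_equal(same$z_stat, 0)
  expect_equal(same$pvalue, 1)

  # hand formula: 90/100 vs 500/1000
  en <- loop_enrichment(rep(c(TRUE, FALSE), c(90, 10)),
                        rep(c(TRUE, FALSE), c(500, 500)))
  p <- (90 + 500) / 1100
  z <- (0.9 - 0.5) / sqrt(p * (1 - p) * (1 / 100 + 1 / 1000))
  expect_equal(en$z_stat, z, tolerance = 1e-9)
  expect_equal(en$pvalue, 2 * pnorm(-abs(z)), tolerance = 1e-9)

  expect_error(loop_enrichment(logical(0), TRUE), "empty")
})

test_that("MFE comparison behaves like a rank-sum test", {
  withr::with_seed(8, a <- rnorm(50, -10, 3))
  same <- mfe_compare(a, a)
  expect_gt(same$pvalue, 0.99)
  shifted <- mfe_compare(a, a - 10)
  expect_lt(shifted$pvalue, 1e-6)
  expect_equal(shifted$median_diff, 10, tolerance = 1e-9)
  # U + U' = n1 * n2
  b <- a[1:30] + 1
  u1 <- mfe_compare(a, b)$u_stat
  u2 <- mfe_compare(b, a)$u_stat
  expect_equal(u1 + u2, length(a) * length(b))
})

test_that("fold_sites annotates loop membership end to end", {
  # a reference with a strong planted hairpin around the site
  cassette <- "GCGCGCGCAUUCAAGCGCGCGC"
  seqs <- paste0(paste(rep("A", 40), collapse = ""), cassette,
                 paste(rep("A", 40), collapse = ""))
  ref <- Biostrings::DNAStringSet(c(h = chartr("U", "T", seqs)))
  sites <- tibble::tibble(contig = "h", pos = 52L, strand = "+")  # the C
  ann <- fold_sites(sites, ref, width = 60)
  expect_true(ann$in_loop)
  expect_equal(ann$loop_type, "hairpin")
  expect_lt(ann$mfe, -10)
})
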