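small_cfg <- function(...) {
  sim_config(seed = 9, n_genes = 8, gene_length_range = c(800, 1200),
             n_dna_snvs = 6, n_cu_edits = 12, n_ag_edits = 5,
             n_null_sites = 10, min_site_separation = 40, ...)
}

test_that("the generator is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_cfg(), d1)
  simulate_study(small_cfg(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # a different seed changes the outputs
  d3 <- withr::local_tempdir()
  simulate_study(sim_config(seed = 10, n_genes = 8, n_dna_snvs = 6,
                            n_cu_edits = 12, n_ag_edits = 5,
                            n_null_sites = 10, min_site_separation = 40,
                            gene_length_range = c(800, 1200)), d3)
  expect_false(identical(readLines(file.path(d1, "reference.fa")),
                         readLines(file.path(d3, "reference.fa"))))
})

test_that("reference generation honours gc_fraction and n_genes", {
  pure_gc <- sim_config(seed = 2, n_genes = 3, gc_fraction = 1,
                        gene_length_range = c(200, 300))
  ref <- simulate_reference(pure_gc)
  expect_equal(length(ref$reference), 3L)
  for (s in as.character(ref$reference)) {
    expect_true(grepl("^[GC]+$", s))
  }
  empty <- simulate_reference(sim_config(seed = 2, n_genes = 0))
  expect_equal(length(empty$reference), 0L)
  expect_equal(nrow(empty$genes), 0L)
})

test_that("planted sites satisfy their declared truth attributes", {
  cfg <- small_cfg(frac_cu_in_uucv = 1, frac_cu_in_loop = 0.5)
  planted <- plant_sites(simulate_reference(cfg), cfg)
  truth <- planted$truth
  expect_equal(sum(truth$truth_class == "cu_edit"), 12L)
  expect_equal(sum(truth$truth_class == "dna_snv"), 6L)

  cu <- dplyr::filter(truth, truth_class == "cu_edit")
  # every C>U context matches UUCV on the transcript strand
  win <- extract_window(cu, planted$reference, width = 11)
  expect_true(all(match_motif(win$window, win$offset,
                              motif_pattern("UUCV", anchor = 3))))
  # minus-strand C>U edits appear genomically as G>A
  minus <- dplyr::filter(cu, strand == "-")
  if (nrow(minus) > 0) {
    expect_true(all(minus$ref == "G" & minus$alt == "A"))
  }
  plus <- dplyr::filter(cu, strand == "+")
  if (nrow(plus) > 0) {
    expect_true(all(plus$ref == "C" & plus$alt == "T"))
  }
  # the genomic reference carries the planted ref allele at every site
  base_at <- vapply(seq_len(nrow(truth)), function(i) {
    as.character(Biostrings::subseq(planted$reference[[truth$contig[i]]],
                                    truth$pos[i], truth$pos[i]))
  }, character(1))
  expect_equal(base_at, truth$ref)

  # loop-planted sites really sit in a predicted hairpin loop
  looped <- dplyr::filter(cu, in_loop)
  ann <- fold_sites(looped, planted$reference, width = 60)
  expect_true(all(ann$in_loop))
  expect_true(all(ann$loop_type == "hairpin"))

  # truth classes partition the planted sites
  expect_equal(nrow(truth),
               nrow(dplyr::distinct(truth, contig, pos, ref, alt)))
  expect_true(all(truth$truth_class %in%
                    c("cu_edit", "ag_edit", "dna_snv", "null")))
  # genomic SNVs have no planted condition effect
  expect_true(all(truth$planted_delta_af[truth$truth_class == "dna_snv"] == 0))
  # planted sites are mutually separated by at least 5 bp per contig
  seps <- truth |>
    dplyr::group_by(contig) |>
    dplyr::summarise(min_sep = ifelse(dplyr::n() < 2, Inf,
                                      min(diff(sort(pos)))))
  expect_true(all(seps$min_sep >= 5))
  # the genomic VCF holds exactly the planted SNVs
  expect_equal(nrow(planted$dna_snvs), 6L)
})

test_that("an over-subscribed gene errors out", {
  tiny <- sim_config(seed = 1, n_genes = 1, gene_length_range = c(260, 260),
                     n_cu_edits = 40, n_ag_edits = 0, n_dna_snvs = 0,
                     n_null_sites = 0)
  expect_error(plant_sites(simulate_reference(tiny), tiny), "too short")
})

test_that("simulated counts are calibrated to the planted allele fractions", {
  # binomial-limit sanity: huge depth, single site, af recovered within 3 SD
  cfg <- sim_config(seed = 33, n_genes = 2, gene_length_range = c(500, 600),
                    n_cu_edits = 1, n_ag_edits = 0, n_dna_snvs = 1,
                    n_null_sites = 0, depth_mean = 1e6,
                    overdispersion_rho = 0, cu_delta_af_range = c(0.2, 0.2))
  planted <- plant_sites(simulate_reference(cfg), cfg)
  counts <- simulate_counts(planted$truth, cfg)
  cu <- dplyr::semi_join(counts,
                         dplyr::filter(planted$truth, truth_class == "cu_edit"),
                         by = c("contig", "pos"))
  ind <- dplyr::filter(cu, condition == "induced")
  af_hat <- sum(ind$alt_count) / sum(ind$total_count)
  af_true <- 0.2 + cfg$base_error_af
  se <- sqrt(af_true * (1 - af_true) / sum(ind$total_count))
  expect_lt(abs(af_hat - af_true), 3 * se)

  # genomic SNV at fraction 0.5 or 1: both condition groups agree
  snv <- dplyr::semi_join(counts,
                          dplyr::filter(planted$truth, truth_class == "dna_snv"),
                          by = c("contig", "pos"))
  af_by_cond <- snv |>
    dplyr::group_by(condition) |>
    dplyr::summarise(af = sum(alt_count) / sum(total_count))
  expect_equal(af_by_cond$af[1], af_by_cond$af[2], tolerance = 0.01)
  expect_true(all(counts$alt_count <= counts$total_count))
})

test_that("null sites are marginally calibrated to the base error rate", {
  cfg <- sim_config(seed = 44, n_genes = 40, n_cu_edits = 0, n_ag_edits = 0,
                    n_dna_snvs = 0, n_null_sites = 1000, depth_mean = 50,
                    min_site_separation = 40)
  planted <- plant_sites(simulate_reference(cfg), cfg)
  counts <- simulate_counts(planted$truth, cfg)
  per_site <- counts |>
    dplyr::group_by(contig, pos) |>
    dplyr::summarise(af = sum(alt_count) / sum(total_count), .groups = "drop")
  mc_se <- sd(per_site$af) / sqrt(nrow(per_site))
  expect_lt(abs(mean(per_site$af) - cfg$base_error_af), 3 * mc_se)
  # planted_delta_af = 0 everywhere: group difference centred on 0
  d <- counts |>
    dplyr::group_by(condition) |>
    dplyr::summarise(af = sum(alt_count) / sum(total_count))
  expect_lt(abs(diff(d$af)), 3 * mc_se * sqrt(2))
})

test_that("library sizes vary and fill mapped_reads per sample", {
  cfg <- small_cfg()
  planted <- plant_sites(simulate_reference(cfg), cfg)
  counts <- simulate_counts(planted$truth, cfg)
  libs <- counts |>
    dplyr::distinct(condition, replicate, mapped_reads)
  expect_equal(nrow(libs), 8L)
  expect_gte(max(libs$mapped_reads) / min(libs$mapped_reads), 1)
  expect_true(all(libs$mapped_reads >= cfg$library_size_range[1] &
                    libs$mapped_reads <= cfg$library_size_range[2]))
})

test_that("eCLIP tracks put IP signal only 3' of C>U sites", {
  cfg <- small_cfg(eclip_fold = 6)
  planted <- plant_sites(simulate_reference(cfg), cfg)
  eclip <- simulate_eclip(planted$truth, planted, cfg)
  cu <- dplyr::filter(planted$truth, truth_class == "cu_edit")
  base <- cfg$eclip_baseline
  for (i in seq_len(min(nrow(cu), 6))) {
    st <- cu$strand[i]; cg <- cu$contig[i]; p <- cu$pos[i]
    hot <- if (st == "+") (p + 1):(p + 10) else (p - 10):(p - 1)
    ipv <- eclip$ip[[st]]$values[[cg]]
    expect_gt(mean(ipv[hot]), 3 * base)             # enriched window
    cold <- setdiff((p - 15):(p + 15), hot)
    cold <- cold[cold >= 1 & cold <= length(ipv)]
    expect_lt(mean(ipv[cold]), 2 * base)            # flat elsewhere
  }
  # no added signal at A>G or SNV sites
  other <- dplyr::filter(planted$truth,
                         truth_class %in% c("ag_edit", "dna_snv"))
  for (i in seq_len(min(nrow(other), 6))) {
    st <- other$strand[i]
    ipv <- eclip$ip[[st]]$values[[other$contig[i]]]
    reg <- (other$pos[i] + 1):(other$pos[i] + 10)
    expect_lt(mean(ipv[reg]), 2 * base)
  }
  # eclip_fold = 1: equal expected mass between IP and input
  cfg1 <- small_cfg(eclip_fold = 1)
  p1 <- plant_sites(simulate_reference(cfg1), cfg1)
  e1 <- simulate_eclip(p1$truth, p1, cfg1)
  expect_equal(e1$ip[["+"]]$total_mass, e1$input[["+"]]$total_mass,
               tolerance = 0.02)
})
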