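#' Configuration of a synthetic editing study
#'
#' Defines every knob of the synthetic-study generator: the reference
#' (one gene per contig, random strand), planted genomic SNVs, planted
#' C>U and A>G(I) RNA edits with controllable sequence-motif and
#' hairpin-loop placement, replicated beta-binomial counts, and strand-aware
#' eCLIP tracks with signal immediately 3' of C>U sites. The defaults
#' emulate a 4-vs-4 replicated induction design.
#'
#' @param seed Master RNG seed; fans out to fixed per-stage child seeds.
#' @param n_genes Number of genes (= contigs).
#' @param gene_length_range Min/max gene length in nt.
#' @param gc_fraction GC content of the background sequence.
#' @param n_dna_snvs,n_cu_edits,n_ag_edits,n_null_sites Planted site counts.
#' @param frac_cu_in_uucv Fraction of C>U edits placed in a UUCV context
#'   (transcript strand).
#' @param frac_cu_in_loop Fraction of C>U edits embedded in a hairpin-loop
#'   cassette (stem 8 bp, loop 6 nt).
#' @param replicates_per_group Replicates per condition (default 4).
#' @param min_site_separation Minimum distance in bp between planted sites
#'   (default 250, comfortably wider than the eCLIP profile window so
#'   per-site signals do not overlap, emulating the sparsity of real variant
#'   sites; dense designs may lower it, with 5 bp the hard floor).
#' @param depth_mean Mean per-replicate site depth (Poisson).
#' @param base_error_af Background alternative-allele fraction.
#' @param cu_delta_af_range Range of planted induced-minus-control AF for
#'   edits.
#' @param overdispersion_rho Beta-binomial intra-site correlation.
#' @param selectivity_alpha Zipf exponent concentrating C>U edits in few
#'   genes (0 = uniform).
#' @param eclip_offset_window Offsets (3' of the edited base, transcript
#'   orientation) receiving eCLIP signal.
#' @param eclip_fold IP/input signal ratio inside the window.
#' @param eclip_baseline Mean per-base input signal (reads per base; deep
#'   enough that per-base IP/input ratios are stable).
#' @param library_size_range Range of per-sample mapped-read totals
#'   (spanning up to 2x to exercise per-million normalisation).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 60,
                       gene_length_range = c(3000, 5000),
                       gc_fraction = 0.45,
                       n_dna_snvs = 50,
                       n_cu_edits = 100,
                       n_ag_edits = 60,
                       n_null_sites = 300,
                       frac_cu_in_uucv = 0.9,
                       frac_cu_in_loop = 0.9,
                       replicates_per_group = 4,
                       min_site_separation = 250,
                       depth_mean = 50,
                       base_error_af = 0.005,
                       cu_delta_af_range = c(0.05, 0.4),
                       overdispersion_rho = 0.01,
                       selectivity_alpha = 1.0,
                       eclip_offset_window = c(1, 10),
                       eclip_fold = 5,
                       eclip_baseline = 40,
                       library_size_range = c(10e6, 20e6)) {
  cfg <- as.list(environment())
  fracs <- c(cfg$gc_fraction, cfg$frac_cu_in_uucv, cfg$frac_cu_in_loop,
             cfg$base_error_af)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            cfg$depth_mean > 0,
            cfg$replicates_per_group >= 2,
            cfg$overdispersion_rho >= 0 & cfg$overdispersion_rho < 1,
            length(cfg$cu_delta_af_range) == 2L,
            cfg$cu_delta_af_range[1] <= cfg$cu_delta_af_range[2],
            cfg$eclip_fold > 0, cfg$eclip_baseline > 0,
            cfg$min_site_separation >= 5)
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Simulate the reference and gene annotation
#'
#' One gene per contig with a random strand; lengths uniform over
#' `gene_length_range`. Byte-identical output under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `reference` ([Biostrings::DNAStringSet]) and `genes`
#'   (BED-style tibble: `contig, start, end, gene_id, score, strand,
#'   start1, end1`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 101L, {
    n <- config$n_genes
    if (n == 0L) {
      return(list(reference = Biostrings::DNAStringSet(),
                  genes = tibble(contig = character(), start = integer(),
                                 end = integer(), gene_id = character(),
                                 score = numeric(), strand = character(),
                                 start1 = integer(), end1 = integer())))
    }
    ids <- sprintf("gene_%03d", seq_len(n))
    lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(.rand_dna(L, config$gc_fraction), collapse = "")
    }, character(1))
    ref <- Biostrings::DNAStringSet(setNames(seqs, ids))
    genes <- tibble(
      contig = ids, start = 0L, end = as.integer(lens), gene_id = ids,
      score = 0, strand = sample(c("+", "-"), n, replace = TRUE)
    ) |>
      mutate(start1 = .data$start + 1L, end1 = .data$end)
    list(reference = ref, genes = genes)
  })
}

# Pick a transcript-space position in [margin, L - margin] at least min_sep
# from all previously chosen positions; NA when the gene is saturated.
.alloc_position <- function(chosen, L, margin = 120L, min_sep = 30L,
                            tries = 60L) {
  lo <- margin; hi <- L - margin
  if (hi < lo) return(NA_integer_)
  for (t in seq_len(tries)) {
    p <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    if (length(chosen) == 0L || all(abs(chosen - p) >= min_sep)) return(p)
  }
  NA_integer_
}

.STEM_LEN <- 8L
.LOOP_LEN <- 6L

# Hairpin cassette on the transcript strand: GC-rich 8-bp stem, 6-nt loop
# with the edited C at loop position 4 (cassette offset 12 of 22).
.make_cassette <- function(in_uucv) {
  stem <- sample(c("G", "C", "G", "C", "A", "T"), .STEM_LEN, replace = TRUE)
  v <- sample(c("A", "C", "G"), 1)
  loop <- if (in_uucv) {
    c("A", "T", "T", "C", v, "A")           # ts U U C V around the C
  } else {
    c(sample(c("A", "C", "G"), 1), sample(c("A", "T", "G", "C"), 1),
      sample(c("A", "C", "G"), 1), "C", sample(c("A", "T", "G", "C"), 1),
      sample(c("A", "C", "G"), 1))          # C without a UU prefix
  }
  rc <- rev(chartr("ACGT", "TGCA", stem))
  c(stem, loop, rc)
}
.CASSETTE_SITE <- 12L  # offset of the edited base within the 22-nt cassette

#' Plant genomic SNVs and RNA edit sites into a simulated reference
#'
#' C>U edits are placed on the transcript strand (genomic G>A on
#' minus-strand genes); the configured fractions receive a UUCV context
#' and/or a constructive hairpin cassette (8-bp stem, 6-nt loop holding the
#' edited C). A>G(I) edits, genomic SNVs (allele fraction 0.5 or 1, equal in
#' both conditions) and null background sites are placed uniformly. Planted
#' sites are at least `min_site_separation` bp apart.
#'
#' @param ref_bundle Output of [simulate_reference()].
#' @param config The [sim_config()].
#' @return List: `reference` (sequence with planted contexts written in),
#'   `genes`, `truth` (one row per planted site: coordinates, genomic
#'   alleles, `truth_class`, `planted_delta_af`, `in_uucv`, `in_loop`,
#'   per-condition true allele fractions), and `dna_snvs` (tibble for the
#'   genomic VCF).
#' @export
plant_sites <- function(ref_bundle, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- ref_bundle$genes
  withr::with_seed(config$seed + 202L, {
    ts_seq <- lapply(seq_len(nrow(genes)), function(i) {
      s <- ref_bundle$reference[[genes$contig[i]]]
      if (genes$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      strsplit(as.character(s), "", fixed = TRUE)[[1]]
    })
    names(ts_seq) <- genes$contig
    chosen <- lapply(ts_seq, function(x) integer(0))
    lens <- vapply(ts_seq, length, integer(1))

    pick_gene <- function(weights) {
      sample.int(nrow(genes), 1L, prob = weights)
    }
    zipf_w <- if (config$selectivity_alpha == 0) rep(1, nrow(genes)) else
      seq_len(nrow(genes))^(-config$selectivity_alpha)
    unif_w <- rep(1, nrow(genes))

    place <- function(weights) {
      for (attempt in seq_len(500L)) {
        g <- pick_gene(weights)
        p <- .alloc_position(chosen[[g]], lens[g],
                             min_sep = config$min_site_separation)
        if (!is.na(p)) {
          chosen[[g]] <<- c(chosen[[g]], p)
          return(list(g = g, t = p))
        }
      }
      stop("sequence too short to host requested sites")
    }

    n_cu <- config$n_cu_edits
    uucv_flags <- loop_flags <- logical(n_cu)
    if (n_cu > 0) {
      uucv_flags[sample.int(n_cu, round(config$frac_cu_in_uucv * n_cu))] <- TRUE
      loop_flags[sample.int(n_cu, round(config$frac_cu_in_loop * n_cu))] <- TRUE
    }

    rows <- list()
    add_row <- function(...) rows[[length(rows) + 1L]] <<- tibble(...)

    to_genomic <- function(g, t) {
      if (genes$strand[g] == "-") lens[g] - t + 1L else t
    }

    for (i in seq_len(n_cu)) {
      loc <- place(zipf_w)
      g <- loc$g; t <- loc$t
      if (loop_flags[i]) {
        cas <- .make_cassette(uucv_flags[i])
        a <- t - .CASSETTE_SITE + 1L
        ts_seq[[g]][a:(a + length(cas) - 1L)] <- cas
      } else {
        ts_seq[[g]][t] <- "C"
        if (uucv_flags[i]) {
          ts_seq[[g]][t - 2L] <- "T"
          ts_seq[[g]][t - 1L] <- "T"
          ts_seq[[g]][t + 1L] <- sample(c("A", "C", "G"), 1)
        } else {
          ts_seq[[g]][t - 1L] <- sample(c("A", "C", "G"), 1)
        }
      }
      minus <- genes$strand[g] == "-"
      d <- runif(1, config$cu_delta_af_range[1], config$cu_delta_af_range[2])
      add_row(contig = genes$contig[g], pos = to_genomic(g, t),
              ref = if (minus) "G" else "C", alt = if (minus) "A" else "T",
              strand = genes$strand[g], gene_id = genes$gene_id[g],
              truth_class = "cu_edit", planted_delta_af = d,
              in_uucv = uucv_flags[i], in_loop = loop_flags[i],
              af_ctrl_true = config$base_error_af,
              af_ind_true = config$base_error_af + d)
    }

    for (i in seq_len(config$n_ag_edits)) {
      loc <- place(unif_w)
      g <- loc$g; t <- loc$t
      ts_seq[[g]][t] <- "A"
      minus <- genes$strand[g] == "-"
      d <- runif(1, config$cu_delta_af_range[1], config$cu_delta_af_range[2])
      add_row(contig = genes$contig[g], pos = to_genomic(g, t),
              ref = if (minus) "T" else "A", alt = if (minus) "C" else "G",
              strand = genes$strand[g], gene_id = genes$gene_id[g],
              truth_class = "ag_edit", planted_delta_af = d,
              in_uucv = FALSE, in_loop = FALSE,
              af_ctrl_true = config$base_error_af,
              af_ind_true = config$base_error_af + d)
    }

    for (i in seq_len(config$n_dna_snvs)) {
      loc <- place(unif_w)
      g <- loc$g; t <- loc$t
      gp <- to_genomic(g, t)
      minus <- genes$strand[g] == "-"
      ref_now <- if (minus) chartr("ACGT", "TGCA", ts_seq[[g]][t]) else ts_seq[[g]][t]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref_now), 1)
      af <- sample(c(0.5, 1.0), 1)
      add_row(contig = genes$contig[g], pos = gp,
              ref = ref_now, alt = alt,
              strand = genes$strand[g], gene_id = genes$gene_id[g],
              truth_class = "dna_snv", planted_delta_af = 0,
              in_uucv = FALSE, in_loop = FALSE,
              af_ctrl_true = af, af_ind_true = af)
    }

    for (i in seq_len(config$n_null_sites)) {
      loc <- place(unif_w)
      g <- loc$g; t <- loc$t
      minus <- genes$strand[g] == "-"
      ref_now <- if (minus) chartr("ACGT", "TGCA", ts_seq[[g]][t]) else ts_seq[[g]][t]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref_now), 1)
      add_row(contig = genes$contig[g], pos = to_genomic(g, t),
              ref = ref_now, alt = alt,
              strand = genes$strand[g], gene_id = genes$gene_id[g],
              truth_class = "null", planted_delta_af = 0,
              in_uucv = FALSE, in_loop = FALSE,
              af_ctrl_true = config$base_error_af,
              af_ind_true = config$base_error_af)
    }

    truth <- bind_rows(rows) |> arrange(.data$contig, .data$pos)
    new_seqs <- vapply(seq_len(nrow(genes)), function(g) {
      s <- paste(ts_seq[[g]], collapse = "")
      if (genes$strand[g] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      s
    }, character(1))
    reference <- Biostrings::DNAStringSet(setNames(new_seqs, genes$contig))
    list(reference = reference, genes = genes, truth = truth,
         dna_snvs = filter(truth, .data$truth_class == "dna_snv") |>
           select("contig", "pos", "ref", "alt"))
  })
}

# Beta-binomial sampler, (mean pi, correlation rho) parameterisation.
.rbetabin <- function(size, pi, rho) {
  n <- length(size)
  p <- if (rho < 1e-9) rep(pi, length.out = n) else {
    a <- pi * (1 - rho) / rho
    b <- (1 - pi) * (1 - rho) / rho
    rbeta(n, a, b)
  }
  rbinom(n, size, p)
}

#' Simulate replicated allele counts for planted sites
#'
#' Per site and replicate, `total_count ~ Poisson(depth_mean)` and
#' `alt_count ~ BetaBinomial(total, pi, rho)` where `pi` is the site's true
#' per-condition allele fraction from the truth table. Per-sample library
#' sizes span `library_size_range` and fill the `mapped_reads` column.
#'
#' @param truth Truth tibble from [plant_sites()].
#' @param config The [sim_config()].
#' @return Count table in the [read_counts_table()] schema, conditions
#'   `control` and `induced`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 303L, {
    R <- config$replicates_per_group
    samples <- tidyr::expand_grid(condition = c("control", "induced"),
                                  replicate = seq_len(R))
    samples$mapped_reads <- round(runif(nrow(samples),
                                        config$library_size_range[1],
                                        config$library_size_range[2]))
    out <- tidyr::expand_grid(
      truth |> select("contig", "pos", "ref", "alt",
                      "af_ctrl_true", "af_ind_true"),
      samples
    ) |>
      mutate(total_count = rpois(dplyr::n(), config$depth_mean))
    af <- ifelse(out$condition == "control", out$af_ctrl_true,
                 out$af_ind_true)
    alt <- integer(nrow(out))
    for (a in unique(af)) {
      idx <- which(af == a)
      alt[idx] <- .rbetabin(out$total_count[idx], a, config$overdispersion_rho)
    }
    out$alt_count <- alt
    out |>
      select("contig", "pos", "ref", "alt", "condition", "replicate",
             "alt_count", "total_count", "mapped_reads") |>
      arrange(.data$contig, .data$pos, .data$alt, .data$condition,
              .data$replicate)
  })
}

#' Simulate strand-specific eCLIP IP and size-matched input tracks
#'
#' Input tracks are Poisson noise around a uniform baseline; IP tracks carry
#' `eclip_fold` times the baseline inside `eclip_offset_window` immediately
#' 3' (transcript orientation) of every planted C>U edit, and baseline
#' elsewhere. No signal is added at A>G(I) or genomic-SNV sites. With
#' `eclip_fold = 1` IP and input have equal expected mass.
#'
#' @param truth Truth tibble from [plant_sites()].
#' @param ref_bundle The planted reference bundle (for contig lengths and
#'   gene strands).
#' @param config The [sim_config()].
#' @return List `ip` and `input`, each `list("+" = coverage_track, "-" =
#'   coverage_track)`.
#' @export
simulate_eclip <- function(truth, ref_bundle, config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- setNames(Biostrings::width(ref_bundle$reference),
                   names(ref_bundle$reference))
  withr::with_seed(config$seed + 404L, {
    mk <- function() lapply(lens, function(L) rpois(L, config$eclip_baseline) + 0)
    tracks <- list(
      ip = list(`+` = mk(), `-` = mk()),
      input = list(`+` = mk(), `-` = mk())
    )
    cu <- filter(truth, .data$truth_class == "cu_edit")
    w <- seq(config$eclip_offset_window[1], config$eclip_offset_window[2])
    for (i in seq_len(nrow(cu))) {
      st <- cu$strand[i]; cg <- cu$contig[i]
      gpos <- if (st == "+") cu$pos[i] + w else cu$pos[i] - w
      gpos <- gpos[gpos >= 1 & gpos <= lens[[cg]]]
      tracks$ip[[st]][[cg]][gpos] <-
        rpois(length(gpos), config$eclip_baseline * config$eclip_fold) + 0
    }
    list(
      ip = list(`+` = coverage_track(tracks$ip[[
        "+"]], "+"), `-` = coverage_track(tracks$ip[["-"]], "-")),
      input = list(`+` = coverage_track(tracks$input[[
        "+"]], "+"), `-` = coverage_track(tracks$input[["-"]], "-"))
    )
  })
}

#' Generate and write a complete synthetic study
#'
#' Runs [simulate_reference()], [plant_sites()], [simulate_counts()] and
#' [simulate_eclip()] and writes reference FASTA, BED6 annotation, genomic
#' VCF, counts TSV, truth TSV and four bedGraphs (IP/input x strand) to a
#' directory. Every file is byte-identical across runs with the same
#' config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and all file paths.
#' @export
simulate_study <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref0 <- simulate_reference(config)
  planted <- plant_sites(ref0, config)
  counts <- simulate_counts(planted$truth, config)
  eclip <- simulate_eclip(planted$truth, planted, config)
  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    bed = file.path(dir, "genes.bed"),
    vcf = file.path(dir, "wgs_snvs.vcf"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.tsv"),
    ip_plus = file.path(dir, "eclip_ip_plus.bedgraph"),
    ip_minus = file.path(dir, "eclip_ip_minus.bedgraph"),
    input_plus = file.path(dir, "eclip_input_plus.bedgraph"),
    input_minus = file.path(dir, "eclip_input_minus.bedgraph")
  )
  write_reference(planted$reference, paths$fasta)
  write_bed_genes(planted$genes, paths$bed)
  lens <- setNames(Biostrings::width(planted$reference),
                   names(planted$reference))
  write_sites_vcf(planted$dna_snvs, paths$vcf, contig_lengths = lens)
  write_counts_table(counts, paths$counts)
  readr::write_tsv(planted$truth, paths$truth, progress = FALSE)
  write_bedgraph(eclip$ip[["+"]], paths$ip_plus)
  write_bedgraph(eclip$ip[["-"]], paths$ip_minus)
  write_bedgraph(eclip$input[["+"]], paths$input_plus)
  write_bedgraph(eclip$input[["-"]], paths$input_minus)
  invisible(list(config = config, reference = planted$reference,
                 genes = planted$genes, truth = planted$truth,
                 counts = counts, eclip = eclip, paths = paths))
}
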