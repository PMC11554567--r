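#' Assemble a pipeline run configuration
#'
#' Collects all input paths and analysis thresholds for an end-to-end run.
#' Thresholds default to the study conventions: DVR qualification at BH
#' FDR <= 0.05, per-replicate depth >= 10, 10,000 random control sites,
#' 100-nt folding windows.
#'
#' @param counts,wgs_vcf,fasta,bed Required input paths (count table,
#'   genomic SNV VCF, reference FASTA, BED6 gene annotation).
#' @param blacklist_vcf Optional population-SNP VCF.
#' @param ip_plus,ip_minus,input_plus,input_minus Optional strand-specific
#'   eCLIP bedGraphs (IP and size-matched input; all four or none).
#' @param out_dir Output directory.
#' @param fdr_alpha,min_delta_af DVR qualification thresholds.
#' @param min_total_per_replicate,min_alt_reads_pooled Depth filters.
#' @param n_controls Random control sites for structure/motif enrichment.
#' @param fold_width Folding window width (nt).
#' @param flank PFM flank (nt).
#' @param profile_half_width eCLIP profile half-window (nt).
#' @param target_share Gene-concentration target cumulative share.
#' @param control,induced Condition labels (default: alphabetical order).
#' @param keep_filtered Keep non-PASS VCF records.
#' @param seed Master seed (fans out to fixed child seeds per stage).
#' @return List of class `dvr_config`.
#' @export
dvr_config <- function(counts, wgs_vcf, fasta, bed,
                       blacklist_vcf = NULL,
                       ip_plus = NULL, ip_minus = NULL,
                       input_plus = NULL, input_minus = NULL,
                       out_dir = "dvrscan_out",
                       fdr_alpha = 0.05, min_delta_af = 0,
                       min_total_per_replicate = 10,
                       min_alt_reads_pooled = 2,
                       n_controls = 10000,
                       fold_width = 100, flank = 5,
                       profile_half_width = 100,
                       target_share = 0.40,
                       control = NULL, induced = NULL,
                       keep_filtered = FALSE,
                       seed = 1) {
  structure(as.list(environment()), class = "dvr_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [dvr_config()] arguments.
#' @return A `dvr_config`.
#' @export
read_dvr_config <- function(path) {
  do.call(dvr_config, yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges, file existence and eCLIP track pairing without
#' running anything.
#'
#' @param config A [dvr_config()].
#' @return Tibble of violations (`field`, `problem`); zero rows means the
#'   configuration is valid.
#' @export
validate_dvr_config <- function(config) {
  v <- list()
  bad <- function(field, problem) v[[length(v) + 1L]] <<-
    tibble(field = field, problem = problem)
  for (f in c("counts", "wgs_vcf", "fasta", "bed")) {
    if (is.null(config[[f]])) bad(f, "missing required path")
    else if (!file.exists(config[[f]])) bad(f, paste0("file not found: ", config[[f]]))
  }
  if (!is.null(config$blacklist_vcf) && !file.exists(config$blacklist_vcf)) {
    bad("blacklist_vcf", "file not found")
  }
  eclip <- c("ip_plus", "ip_minus", "input_plus", "input_minus")
  given <- !vapply(config[eclip], is.null, logical(1))
  if (any(given) && !all(given)) {
    bad("eclip", "IP and input tracks must be given for both strands or not at all")
  }
  for (f in eclip[given]) {
    if (!file.exists(config[[f]])) bad(f, "file not found")
  }
  if (!(config$fdr_alpha > 0 && config$fdr_alpha < 1)) {
    bad("fdr_alpha", "must lie in (0, 1)")
  }
  if (config$n_controls < 1) bad("n_controls", "must be >= 1")
  if (config$fold_width < 11) bad("fold_width", "too small to fold")
  if (length(v) == 0L) {
    tibble(field = character(), problem = character())
  } else bind_rows(v)
}

.tbl_to_list <- function(x) lapply(as.list(x), function(col) unname(col))

#' Run the full DVR pipeline
#'
#' Executes the stages in order -- depth filtering, genomic-SNV
#' subtraction, per-site beta-binomial LRT with FDR control and
#' classification, structure and motif characterisation against sampled
#' controls, editing-activity selectivity, and (when tracks are given)
#' eCLIP metaprofiles -- writing each stage's tables plus an aggregate
#' `report.json` to `config$out_dir`. Fully deterministic under
#' `config$seed`.
#'
#' @param config A validated [dvr_config()].
#' @return Invisibly, the report list.
#' @export
run_dvr_pipeline <- function(config) {
  viol <- validate_dvr_config(config)
  if (nrow(viol) > 0L) {
    stop("invalid configuration:\n",
         paste0("  ", viol$field, ": ", viol$problem, collapse = "\n"))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  counts <- read_counts_table(config$counts)
  reference <- read_reference(config$fasta)
  genes <- read_bed_genes(config$bed)
  wgs <- read_vcf_sites(config$wgs_vcf, keep_filtered = config$keep_filtered)
  blacklist <- if (!is.null(config$blacklist_vcf)) {
    read_vcf_sites(config$blacklist_vcf, keep_filtered = config$keep_filtered)
  } else NULL

  # stage i: depth filters then genomic subtraction
  counts_deep <- apply_depth_filters(
    counts, min_total_per_replicate = config$min_total_per_replicate,
    min_alt_reads_pooled = config$min_alt_reads_pooled)
  depth_report <- filter_report(counts_deep)
  cand <- dplyr::distinct(counts_deep, .data$contig, .data$pos,
                          .data$ref, .data$alt)
  retained <- subtract_genomic_variants(cand, wgs, blacklist)
  genomic_report <- filter_report(retained)
  counts_use <- semi_join(counts_deep, retained,
                          by = c("contig", "pos", "ref", "alt"))

  # stage ii: per-site LRT, FDR, classification
  results <- call_dvrs(counts_use, genes = genes,
                       control = config$control, induced = config$induced,
                       fdr_alpha = config$fdr_alpha,
                       min_delta_af = config$min_delta_af)
  write_dvr_table(results, out("dvr_table.tsv"))
  breakdown <- dvr_breakdown(results)
  dvrs <- filter(results, .data$is_dvr)
  cu_dvrs <- filter(dvrs, .data$class == "C>U")
  induced_label <- attr(results, "conditions")[["induced"]]

  # stage iii: structure + motif context of C>U DVRs vs random controls
  structure_report <- NULL
  motif_report <- NULL
  if (nrow(cu_dvrs) >= 2L) {
    controls <- sample_control_sites(reference, genes, n = config$n_controls,
                                     seed = config$seed + 11L)
    cu_fold <- fold_sites(cu_dvrs, reference, width = config$fold_width)
    ctrl_fold <- fold_sites(controls, reference, width = config$fold_width)
    readr::write_tsv(select(cu_fold, -"window"), out("dvr_structure.tsv"),
                     progress = FALSE)
    loop_res <- loop_enrichment(cu_fold$in_loop, ctrl_fold$in_loop)
    mfe_res <- mfe_compare(cu_fold$mfe[!cu_fold$truncated],
                           ctrl_fold$mfe[!ctrl_fold$truncated])
    structure_report <- list(loop = .tbl_to_list(loop_res),
                             mfe = .tbl_to_list(mfe_res))

    uucv <- motif_pattern("UUCV", anchor = 3)
    test_m <- match_motif(cu_fold$window, cu_fold$offset, uucv)
    ctrl_m <- match_motif(ctrl_fold$window, ctrl_fold$offset, uucv)
    enr <- motif_enrichment(test_m, ctrl_m)
    pfm <- build_pfm(cu_dvrs, reference, flank = config$flank)
    readr::write_tsv(tidy(pfm), out("pfm.tsv"), progress = FALSE)
    motif_report <- list(uucv = .tbl_to_list(enr),
                         ic = unname(pfm$ic),
                         ic_positions = pfm$positions)
  }

  # stage iv: selectivity of editing activity
  selectivity_report <- NULL
  if (nrow(cu_dvrs) >= 1L) {
    shares <- activity_per_dvr(counts_use, induced = induced_label,
                               sites = cu_dvrs)
    lor <- lorenz_gini(shares$activity)
    conc <- gene_concentration(shares, target = config$target_share)
    readr::write_tsv(shares, out("dvr_shares.tsv"), progress = FALSE)
    readr::write_tsv(tidy(lor), out("lorenz_curve.tsv"), progress = FALSE)
    readr::write_tsv(conc, out("gene_shares.tsv"), progress = FALSE)
    selectivity_report <- list(gini = lor$gini, n_dvrs = lor$n,
                               k_genes = attr(conc, "k_genes"),
                               target_share = config$target_share)
  }

  # stage v: eCLIP metaprofile
  eclip_report <- NULL
  if (!is.null(config$ip_plus) && nrow(cu_dvrs) >= 1L) {
    lens <- setNames(Biostrings::width(reference), names(reference))
    ip <- list(`+` = read_bedgraph(config$ip_plus, lens, "+"),
               `-` = read_bedgraph(config$ip_minus, lens, "-"))
    inp <- list(`+` = read_bedgraph(config$input_plus, lens, "+"),
                `-` = read_bedgraph(config$input_minus, lens, "-"))
    prof <- site_profile_matrix(cu_dvrs, ip, inp,
                                W = config$profile_half_width)
    meta <- tidy(prof)
    readr::write_tsv(meta, out("metaprofile.tsv"), progress = FALSE)
    peak <- metaprofile_peak(prof, seed = config$seed + 12L)
    eclip_report <- list(peak = .tbl_to_list(peak))
  }

  report <- list(
    thresholds = list(
      fdr_alpha = config$fdr_alpha, min_delta_af = config$min_delta_af,
      min_total_per_replicate = config$min_total_per_replicate,
      min_alt_reads_pooled = config$min_alt_reads_pooled,
      n_controls = config$n_controls, fold_width = config$fold_width,
      flank = config$flank, profile_half_width = config$profile_half_width,
      seed = config$seed),
    filters = list(depth = .tbl_to_list(depth_report),
                   genomic = .tbl_to_list(genomic_report)),
    n_sites_tested = nrow(results),
    n_dvrs = nrow(dvrs),
    breakdown = .tbl_to_list(breakdown),
    structure = structure_report,
    motifs = motif_report,
    selectivity = selectivity_report,
    eclip = eclip_report
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}
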