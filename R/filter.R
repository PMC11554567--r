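#' Remove candidate RNA variants explained by genomic DNA
#'
#' A candidate is removed if and only if a site with identical
#' `(contig, pos)` and the same alternative allele exists in the
#' whole-genome-sequencing call set or in the optional population-SNP
#' blacklist. Matching is position *and* allele exact: a genomic C>G SNV does
#' not veto an RNA C>U call at the same base.
#'
#' @param candidates Tibble of candidate sites (`contig, pos, ref, alt`, plus
#'   any extra columns, which are preserved).
#' @param wgs_sites Genomic SNV sites from [read_vcf_sites()].
#' @param blacklist_sites Optional population-SNP sites.
#' @return The retained candidates, with a `filter_report` attribute
#'   (see [filter_report()]).
#' @export
subtract_genomic_variants <- function(candidates, wgs_sites,
                                      blacklist_sites = NULL) {
  key <- c("contig", "pos", "alt")
  n_input <- nrow(candidates)
  after_wgs <- anti_join(candidates, wgs_sites, by = key)
  n_genomic <- n_input - nrow(after_wgs)
  if (!is.null(blacklist_sites) && nrow(blacklist_sites) > 0L) {
    retained <- anti_join(after_wgs, blacklist_sites, by = key)
  } else {
    retained <- after_wgs
  }
  n_blacklist <- nrow(after_wgs) - nrow(retained)
  report <- tibble(
    n_input = n_input, n_removed_genomic = n_genomic,
    n_removed_blacklist = n_blacklist, n_removed_depth = 0L,
    n_retained = nrow(retained)
  )
  attr(retained, "filter_report") <- report
  retained
}

#' Retrieve the filtering report attached by a filter step
#'
#' @param x Output of [subtract_genomic_variants()] or
#'   [apply_depth_filters()].
#' @return Tibble with `n_input`, `n_removed_genomic`,
#'   `n_removed_blacklist`, `n_removed_depth`, `n_retained`
#'   (`n_input = sum(removed) + n_retained`).
#' @export
filter_report <- function(x) {
  attr(x, "filter_report")
}

#' Apply per-replicate depth and pooled alt-read support filters
#'
#' A site is retained iff every replicate in both condition groups has
#' `total_count >= min_total_per_replicate` and the pooled alternative reads
#' across the higher-AF group reach `min_alt_reads_pooled`.
#'
#' @param counts Count table ([read_counts_table()] schema).
#' @param min_total_per_replicate Minimum per-replicate total depth
#'   (default 10, the control-site depth convention).
#' @param min_alt_reads_pooled Minimum pooled alt reads in the
#'   higher-AF group (default 2).
#' @return The retained count rows, with a `filter_report` attribute.
#' @export
apply_depth_filters <- function(counts, min_total_per_replicate = 10,
                                min_alt_reads_pooled = 2) {
  keep <- counts |>
    group_by(.data$contig, .data$pos, .data$ref, .data$alt) |>
    summarise(
      ok_depth = all(.data$total_count >= min_total_per_replicate),
      alt_high = {
        grp <- split(seq_along(.data$condition), .data$condition)
        afs <- vapply(grp, function(i) {
          t <- sum(.data$total_count[i]); if (t == 0) 0 else sum(.data$alt_count[i]) / t
        }, numeric(1))
        sum(.data$alt_count[grp[[which.max(afs)]]])
      },
      .groups = "drop") |>
    mutate(ok = .data$ok_depth & .data$alt_high >= min_alt_reads_pooled)
  n_sites <- nrow(keep)
  retained <- semi_join(counts, dplyr::filter(keep, .data$ok),
                        by = c("contig", "pos", "ref", "alt"))
  n_kept <- sum(keep$ok)
  report <- tibble(
    n_input = n_sites, n_removed_genomic = 0L, n_removed_blacklist = 0L,
    n_removed_depth = n_sites - n_kept, n_retained = n_kept
  )
  attr(retained, "filter_report") <- report
  retained
}

.complement <- function(base) chartr("ACGTUacgtu", "TGCAAtgcaa", base)

#' Orient variant sites to the transcript strand
#'
#' Assigns each site the strand and gene of the annotation interval it falls
#' in and complements its alleles into transcript space: a genomic G>A inside
#' a minus-strand gene becomes a transcript C>U. Sites outside any gene, or
#' inside overlapping genes of conflicting strand, get strand `NA` and are
#' flagged (`strand_conflict`) rather than guessed.
#'
#' @param sites Tibble with `contig, pos, ref, alt`.
#' @param genes Annotation from [read_bed_genes()].
#' @return `sites` with added columns `strand`, `gene_id`, `ref_ts`,
#'   `alt_ts`, `strand_conflict`.
#' @export
orient_to_transcript <- function(sites, genes) {
  hit <- sites |>
    dplyr::distinct(.data$contig, .data$pos) |>
    left_join(
      genes |> select("contig", "start1", "end1", "gene_id",
                      gene_strand = "strand"),
      by = "contig", relationship = "many-to-many") |>
    filter(!is.na(.data$start1) & .data$pos >= .data$start1 &
             .data$pos <= .data$end1) |>
    group_by(.data$contig, .data$pos) |>
    summarise(
      strand = if (dplyr::n_distinct(.data$gene_strand) == 1L)
        .data$gene_strand[1] else NA_character_,
      gene_id = if (dplyr::n_distinct(.data$gene_strand) == 1L)
        sort(.data$gene_id)[1] else NA_character_,
      strand_conflict = dplyr::n_distinct(.data$gene_strand) > 1L,
      .groups = "drop")
  out <- sites |>
    left_join(hit, by = c("contig", "pos")) |>
    mutate(
      strand_conflict = ifelse(is.na(.data$strand_conflict), FALSE,
                               .data$strand_conflict),
      ref_ts = ifelse(!is.na(.data$strand) & .data$strand == "-",
                      .complement(.data$ref), .data$ref),
      alt_ts = ifelse(!is.na(.data$strand) & .data$strand == "-",
                      .complement(.data$alt), .data$alt)
    )
  out
}
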