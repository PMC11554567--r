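# In-code fixture builders shared across test files.

# counts tibble for one or more sites; af list gives per-condition fractions
make_counts <- function(sites, reps = 4, depth = 100, af_control = 0.0,
                        af_induced = 0.0, mapped = 1e6, exact = TRUE) {
  purrr::pmap_dfr(sites, function(contig, pos, ref, alt, ...) {
    tidyr::expand_grid(condition = c("control", "induced"),
                       replicate = seq_len(reps)) |>
      dplyr::mutate(
        contig = contig, pos = pos, ref = ref, alt = alt,
        total_count = as.integer(depth),
        alt_count = as.integer(round(depth * ifelse(condition == "control",
                                                    af_control, af_induced))),
        mapped_reads = mapped) |>
      dplyr::select(contig, pos, ref, alt, condition, replicate,
                    alt_count, total_count, mapped_reads)
  })
}

write_counts_file <- function(counts, path = withr::local_tempfile(
  fileext = ".tsv", .local_envir = parent.frame())) {
  readr::write_tsv(counts, path, progress = FALSE)
  path
}

write_vcf_file <- function(records, path = withr::local_tempfile(
  fileext = ".vcf", .local_envir = parent.frame())) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records
  ), path)
  path
}

write_bedgraph_file <- function(lines, path = withr::local_tempfile(
  fileext = ".bedgraph", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# small reference with one + strand and one - strand gene
tiny_reference <- function() {
  seqs <- c(
    geneA = paste(rep("ACGT", 75), collapse = ""),   # 300 nt, + strand
    geneB = paste(rep("GGCA", 75), collapse = "")    # 300 nt, - strand
  )
  list(
    reference = Biostrings::DNAStringSet(seqs),
    genes = tibble::tibble(
      contig = c("geneA", "geneB"), start = c(0L, 0L), end = c(300L, 300L),
      gene_id = c("geneA", "geneB"), score = 0, strand = c("+", "-"),
      start1 = c(1L, 1L), end1 = c(300L, 300L))
  )
}
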