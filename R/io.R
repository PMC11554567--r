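#' Read a per-site, per-replicate allele count table
#'
#' Reads the pipeline's tabular count schema: one row per site, condition and
#' replicate, with alternative-allele and total read counts plus the sample's
#' mapped-read library size. All coordinates are 1-based genomic positions and
#' alleles are given on the genomic plus strand (VCF convention).
#'
#' @param path Path to a TSV file (gzip-transparent) with header columns
#'   exactly `contig, pos, ref, alt, condition, replicate, alt_count,
#'   total_count, mapped_reads`.
#' @return A tibble with those columns, validated: every `(contig, pos, ref,
#'   alt)` site has at least one replicate in each of exactly two condition
#'   labels, and `alt_count <= total_count` on every row.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("counts table not found: ", path)
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer(),
    alt_count = readr::col_integer(),
    total_count = readr::col_integer(),
    mapped_reads = readr::col_double()
  ), progress = FALSE)
  required <- c("contig", "pos", "ref", "alt", "condition", "replicate",
                "alt_count", "total_count", "mapped_reads")
  if (!identical(names(tbl), required)) {
    stop("counts table header must be exactly: ", paste(required, collapse = ", "))
  }
  if (nrow(tbl) == 0L) return(tbl)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0L) {
    stop("malformed counts row at line ", prob$row[1] + 1L, ": ", prob$expected[1])
  }
  bad <- which(is.na(tbl$alt_count) | is.na(tbl$total_count) | is.na(tbl$pos))
  if (length(bad) > 0L) stop("malformed counts row at line ", bad[1] + 1L)
  over <- which(tbl$alt_count > tbl$total_count)
  if (length(over) > 0L) {
    stop("alt_count > total_count at line ", over[1] + 1L)
  }
  conds <- sort(unique(tbl$condition))
  if (length(conds) != 2L) {
    stop("counts table must contain exactly 2 condition labels, found ",
         length(conds), ": ", paste(conds, collapse = ", "))
  }
  chk <- tbl |>
    dplyr::distinct(.data$contig, .data$pos, .data$ref, .data$alt, .data$condition) |>
    dplyr::count(.data$contig, .data$pos, .data$ref, .data$alt) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(chk) > 0L) {
    stop("site ", chk$contig[1], ":", chk$pos[1],
         " lacks replicates in both conditions")
  }
  tbl
}

#' Write a count table in the schema read by [read_counts_table()]
#' @param counts Tibble in the count-table schema.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read SNV sites from a VCF
#'
#' Loads single-nucleotide variant records from a VCF v4.x file, splitting
#' multi-allelic records into one site per ALT allele. Indels are skipped
#' (a message reports how many). By default only records with FILTER `PASS`
#' or `.` are kept, matching the convention of somatic-caller output.
#'
#' @param path VCF path (gzip-transparent).
#' @param keep_filtered Keep records whose FILTER is neither `PASS` nor `.`.
#' @return Tibble with columns `contig, pos, ref, alt` (unique rows),
#'   positions 1-based.
#' @export
read_vcf_sites <- function(path, keep_filtered = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  empty <- tibble(contig = character(), pos = integer(),
                  ref = character(), alt = character())
  if (nrow(fx) == 0L) return(empty)
  tbl <- tibble(
    contig = fx$CHROM,
    pos = as.integer(fx$POS),
    ref = fx$REF,
    alt = fx$ALT,
    filter = if ("FILTER" %in% names(fx)) fx$FILTER else "."
  )
  if (!keep_filtered) {
    tbl <- dplyr::filter(tbl, is.na(.data$filter) |
                           .data$filter %in% c("PASS", "."))
  }
  tbl <- tidyr::separate_rows(tbl, "alt", sep = ",")
  is_snv <- nchar(tbl$ref) == 1L & nchar(tbl$alt) == 1L &
    tbl$ref %in% c("A", "C", "G", "T") & tbl$alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snv)
  if (n_skip > 0L) message(n_skip, " non-SNV record(s) skipped")
  tbl |>
    dplyr::filter(is_snv) |>
    dplyr::select("contig", "pos", "ref", "alt") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$contig, .data$pos, .data$alt)
}

#' Write variant sites as a minimal VCFv4.2 file
#'
#' @param sites Tibble with columns `contig, pos, ref, alt`.
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=dvrscan")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(sites) > 0L) {
    o <- order(sites$contig, sites$pos, sites$alt)
    s <- sites[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    s$contig, s$pos, s$ref, s$alt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED6 gene annotation
#'
#' @param path BED6 path. Intervals are 0-based half-open on disk and are
#'   converted to 1-based inclusive `start1`/`end1` columns alongside the raw
#'   `start`/`end`.
#' @return Tibble with columns `contig, start, end, gene_id, score, strand,
#'   start1, end1`.
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene_id = if (length(gr) && !is.null(gr$name)) gr$name else character(length(gr)),
    score = if (length(gr) && !is.null(gr$score)) as.numeric(gr$score) else rep(0, length(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    mutate(start1 = .data$start + 1L, end1 = .data$end)
}

#' Write a BED6 gene annotation
#' @param genes Tibble with `contig, start, end, gene_id, strand` (0-based
#'   half-open `start`/`end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$name <- genes$gene_id
  gr$score <- if ("score" %in% names(genes)) genes$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Construct a per-base coverage track
#'
#' A coverage track holds one dense non-negative signal vector per contig,
#' plus its strand label and total signal mass; it is the in-memory form of a
#' bedGraph restricted to one strand.
#'
#' @param values Named list of numeric vectors, one per contig.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, strand = "+") {
  stopifnot(is.list(values), !is.null(names(values)))
  for (v in values) {
    if (any(v < 0)) stop("coverage values must be non-negative")
  }
  structure(
    list(values = values, strand = strand,
         total_mass = sum(vapply(values, sum, numeric(1)))),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> strand", x$strand, "|", length(x$values),
      "contig(s) | total mass", format(x$total_mass), "\n")
  invisible(x)
}

#' Read a bedGraph into a dense per-base coverage track
#'
#' @param path bedGraph path; intervals 0-based half-open. Overlapping
#'   intervals are rejected (ambiguous signal is surfaced, not summed).
#' @param contig_lengths Named integer vector of contig lengths (e.g. from
#'   the reference FASTA); uncovered bases are 0.
#' @param strand Strand label to attach.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, contig_lengths, strand = "+") {
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  vals <- lapply(contig_lengths, function(n) numeric(n))
  names(vals) <- names(contig_lengths)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 0L) {
    ctg <- as.character(GenomicRanges::seqnames(gr))
    st <- GenomicRanges::start(gr)   # 1-based inclusive after import
    en <- GenomicRanges::end(gr)
    sc <- gr$score
    for (cg in unique(ctg)) {
      if (!cg %in% names(vals)) stop("bedGraph contig not in reference: ", cg)
      i <- which(ctg == cg)
      if (any(en[i] > length(vals[[cg]]))) {
        stop("bedGraph interval beyond contig length on ", cg)
      }
      o <- i[order(st[i])]
      if (length(o) > 1L && any(st[o][-1] <= en[o][-length(o)])) {
        stop("overlapping bedGraph intervals on ", cg)
      }
      for (k in o) vals[[cg]][st[k]:en[k]] <- sc[k]
    }
  }
  coverage_track(vals, strand = strand)
}

#' Write a coverage track as bedGraph
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  runs <- purrr::map_dfr(names(track$values), function(cg) {
    r <- S4Vectors::Rle(track$values[[cg]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    if (!any(keep)) return(NULL)
    tibble(contig = cg, start = starts[keep], end = ends[keep],
           score = S4Vectors::runValue(r)[keep])
  })
  if (nrow(runs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(runs$contig,
                               IRanges::IRanges(runs$start, runs$end))
  gr$score <- runs$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a reference FASTA
#' @param path FASTA path (gzip-transparent).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Write a reference FASTA
#' @param reference A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 70L)
  invisible(path)
}

#' Write a DVR result table
#'
#' @param results Tibble of per-site test results (as produced by
#'   [call_dvrs()]), with columns `contig, pos, ref, alt, strand, class,
#'   af_ctrl, af_induced, delta_af, lrt_stat, pvalue, fdr, gene_id`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dvr_table <- function(results, path) {
  cols <- c("contig", "pos", "ref", "alt", "strand", "class", "af_ctrl",
            "af_induced", "delta_af", "lrt_stat", "pvalue", "fdr", "gene_id")
  out <- results
  if ("edit_class" %in% names(out) && !"class" %in% names(out)) {
    out <- dplyr::rename(out, class = "edit_class")
  }
  out <- out |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$contig, .data$pos)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a DVR result table written by [write_dvr_table()]
#' @param path TSV path.
#' @return Tibble with the DVR table columns.
#' @export
read_dvr_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    strand = readr::col_character(),
    class = readr::col_character(),
    af_ctrl = readr::col_double(),
    af_induced = readr::col_double(),
    delta_af = readr::col_double(),
    lrt_stat = readr::col_double(),
    pvalue = readr::col_double(),
    fdr = readr::col_double(),
    gene_id = readr::col_character()
  ), progress = FALSE)
}

# 0-based half-open (BED) <-> 1-based inclusive (internal/VCF) conversions.
bed_to_pos1 <- function(start0, end0) list(start1 = start0 + 1L, end1 = end0)
pos1_to_bed <- function(start1, end1) list(start0 = start1 - 1L, end0 = end1)
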