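#' Extract transcript-strand sequence windows around variant sites
#'
#' Cuts a `width`-nt window centred on each site (for the default 100:
#' 50 nt upstream, 49 nt downstream on the transcript strand, edited base at
#' offset 51), reverse-complementing windows of minus-strand sites.
#' Windows truncated at contig edges are kept but flagged.
#'
#' @param sites Tibble with `contig`, `pos` and optionally `strand`
#'   (missing/`NA` treated as `+`).
#' @param reference [Biostrings::DNAStringSet] of contigs.
#' @param width Window width in nt (default 100).
#' @return `sites` with added `window` (RNA string), `offset` (1-based
#'   position of the site in the window) and `truncated`.
#' @export
extract_window <- function(sites, reference, width = 100) {
  lens <- setNames(Biostrings::width(reference), names(reference))
  if (!all(sites$contig %in% names(lens))) {
    stop("contig(s) missing from reference: ",
         paste(setdiff(unique(sites$contig), names(lens)), collapse = ","))
  }
  up <- width %/% 2L
  dn <- width - up - 1L
  strand <- if ("strand" %in% names(sites)) sites$strand else rep("+", nrow(sites))
  strand[is.na(strand)] <- "+"
  res <- purrr::pmap(list(sites$contig, sites$pos, strand), function(cg, p, st) {
    L <- lens[[cg]]
    if (st == "-") { a <- p - dn; b <- p + up } else { a <- p - up; b <- p + dn }
    a0 <- max(1L, a); b0 <- min(L, b)
    s <- as.character(Biostrings::subseq(reference[[cg]], a0, b0))
    if (st == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      off <- b0 - p + 1L
    } else {
      off <- p - a0 + 1L
    }
    list(window = chartr("T", "U", s), offset = off,
         truncated = (a0 != a) || (b0 != b))
  })
  sites |>
    mutate(window = purrr::map_chr(res, "window"),
           offset = purrr::map_int(res, function(x) as.integer(x$offset)),
           truncated = purrr::map_lgl(res, "truncated"))
}

#' Fold windows around sites and annotate loop membership
#'
#' Convenience wrapper chaining [extract_window()], [fold_windows()] and
#' [is_loop()].
#'
#' @inheritParams extract_window
#' @param backend Folding backend (see [fold_mfe()]).
#' @return `sites` plus `window`, `offset`, `truncated`, `dotbracket`,
#'   `mfe`, `in_loop`, `loop_type`.
#' @export
fold_sites <- function(sites, reference, width = 100,
                       backend = fold_backend_builtin()) {
  out <- sites |>
    extract_window(reference, width = width) |>
    fold_windows(backend = backend)
  loops <- purrr::map2(out$dotbracket, out$offset, is_loop)
  out |>
    mutate(in_loop = purrr::map_lgl(loops, "in_loop"),
           loop_type = purrr::map_chr(loops, "loop_type"))
}

#' Sample depth-matched random control sites
#'
#' Draws a uniform sample (without replacement) of positions inside
#' annotated genes, optionally restricted to positions covered with more
#' than `min_depth` reads in every replicate of a count table and/or
#' matching a transcript-strand IUPAC motif. Deterministic under `seed`.
#'
#' @param reference [Biostrings::DNAStringSet].
#' @param genes Annotation from [read_bed_genes()].
#' @param n Number of control sites (default 10000). If fewer positions are
#'   eligible, all are returned with a warning.
#' @param counts Optional count table; restricts eligibility to its sites
#'   with `total_count > min_depth` in every replicate.
#' @param motif Optional [motif_pattern()]; eligible positions must match it
#'   on the transcript strand.
#' @param min_depth Depth threshold used with `counts` (default 10).
#' @param seed Integer RNG seed.
#' @return Tibble of control sites: `contig, pos, strand, gene_id, ref`.
#' @export
sample_control_sites <- function(reference, genes, n = 10000, counts = NULL,
                                 motif = NULL, min_depth = 10, seed = 1) {
  pool <- purrr::pmap_dfr(
    list(genes$contig, genes$start1, genes$end1, genes$gene_id, genes$strand),
    function(cg, a, b, gid, st) {
      if (!is.null(motif)) {
        seq_g <- reference[[cg]]
        ts <- if (st == "-") Biostrings::reverseComplement(seq_g) else seq_g
        pat <- Biostrings::DNAString(chartr("U", "T", motif$pattern))
        hits <- Biostrings::matchPattern(pat, ts, fixed = FALSE)
        site_ts <- Biostrings::start(hits) + motif$anchor - 1L
        L <- length(seq_g)
        pos <- if (st == "-") L - site_ts + 1L else site_ts
        pos <- pos[pos >= a & pos <= b]
        if (length(pos) == 0L) return(NULL)
        tibble(contig = cg, pos = as.integer(pos), strand = st, gene_id = gid)
      } else {
        tibble(contig = cg, pos = seq.int(a, b), strand = st, gene_id = gid)
      }
    })
  if (!is.null(counts)) {
    deep <- counts |>
      group_by(.data$contig, .data$pos) |>
      summarise(ok = all(.data$total_count > min_depth), .groups = "drop") |>
      filter(.data$ok)
    pool <- semi_join(pool, deep, by = c("contig", "pos"))
  }
  if (nrow(pool) == 0L) stop("no eligible control positions")
  if (nrow(pool) <= n) {
    if (nrow(pool) < n) {
      warning("only ", nrow(pool), " eligible positions for n = ", n,
              "; returning all")
    }
    samp <- pool
  } else {
    idx <- withr::with_seed(seed, sample.int(nrow(pool), n))
    samp <- pool[sort(idx), , drop = FALSE]
  }
  samp |>
    mutate(ref = purrr::map2_chr(.data$contig, .data$pos, function(cg, p) {
      as.character(Biostrings::subseq(reference[[cg]], p, p))
    })) |>
    arrange(.data$contig, .data$pos)
}

#' Two-proportion Z test for loop enrichment
#'
#' Compares the fraction of unpaired ("in loop") sites between a test set
#' and a control set with the pooled two-proportion Z statistic
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` and a two-sided normal
#' p-value.
#'
#' @param test_in_loop,control_in_loop Logical vectors (loop membership per
#'   site), e.g. the `in_loop` column of [fold_sites()] output.
#' @return One-row tibble: `frac_test`, `frac_control`, `z_stat`, `pvalue`,
#'   `n_test`, `n_control`.
#' @export
loop_enrichment <- function(test_in_loop, control_in_loop) {
  n1 <- length(test_in_loop); n2 <- length(control_in_loop)
  if (n1 == 0L || n2 == 0L) stop("empty site set")
  p1 <- mean(test_in_loop); p2 <- mean(control_in_loop)
  p <- (sum(test_in_loop) + sum(control_in_loop)) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble(frac_test = p1, frac_control = p2, z_stat = z,
         pvalue = 2 * pnorm(-abs(z)), n_test = n1, n_control = n2)
}

#' Compare two MFE distributions
#'
#' Two-sided Mann-Whitney rank-sum test on minimum-free-energy values of two
#' site sets (folded with the same backend).
#'
#' @param mfe_a,mfe_b Numeric vectors of MFEs (>= 2 values each).
#' @return One-row tibble: `u_stat`, `pvalue`, `median_diff`
#'   (`median(a) - median(b)`).
#' @export
mfe_compare <- function(mfe_a, mfe_b) {
  stopifnot(length(mfe_a) >= 2L, length(mfe_b) >= 2L)
  wt <- suppressWarnings(wilcox.test(mfe_a, mfe_b, exact = FALSE))
  tibble(u_stat = unname(wt$statistic), pvalue = wt$p.value,
         median_diff = median(mfe_a) - median(mfe_b))
}
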