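.IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Define an anchored IUPAC motif
#'
#' @param pattern IUPAC string (e.g. `"UUCV"`; `V = A/C/G`, `K = G/U`,
#'   `W = A/U`, `N` = any; `T` and `U` equivalent).
#' @param anchor 1-based offset of the edited base within the pattern
#'   (e.g. 3 for the C of `UUCV`).
#' @return Object of class `motif_pattern`.
#' @export
motif_pattern <- function(pattern, anchor) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(.IUPAC))) {
    stop("invalid IUPAC code(s): ",
         paste(unique(chars[!chars %in% names(.IUPAC)]), collapse = ","))
  }
  if (length(chars) < 1L || anchor < 1L || anchor > length(chars)) {
    stop("anchor must fall within the pattern")
  }
  structure(list(pattern = paste(chartr("T", "U", chars), collapse = ""),
                 anchor = as.integer(anchor)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", x$pattern, "anchored at", x$anchor, "\n")
  invisible(x)
}

#' Match an anchored IUPAC motif at a position in a sequence
#'
#' Case-insensitive, `T` equivalent to `U`. If the window is too short to
#' cover the pattern span around the anchor the site does not match and a
#' warning flags it.
#'
#' @param sequence Character vector of sequence windows.
#' @param offset Integer vector: 1-based position of the edited base in each
#'   window.
#' @param pattern A [motif_pattern()].
#' @return Logical vector.
#' @export
match_motif <- function(sequence, offset, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  pat <- strsplit(pattern$pattern, "", fixed = TRUE)[[1]]
  plen <- length(pat)
  out <- logical(length(sequence))
  short <- FALSE
  for (i in seq_along(sequence)) {
    s <- chartr("Tt", "Uu", toupper(sequence[i]))
    start <- offset[i] - pattern$anchor + 1L
    end <- start + plen - 1L
    if (start < 1L || end > nchar(s)) { short <- TRUE; next }
    ctx <- strsplit(substr(s, start, end), "", fixed = TRUE)[[1]]
    out[i] <- all(vapply(seq_len(plen), function(k) {
      ctx[k] %in% .IUPAC[[pat[k]]]
    }, logical(1)))
  }
  if (short) warning("window(s) too short to cover the motif span; treated as non-matching")
  out
}

#' Position frequency matrix and information content around edit sites
#'
#' Builds per-position base frequencies from transcript-strand windows of
#' `2 * flank + 1` nt centred on each site, and the per-position information
#' content `IC_j = 2 + sum_b f_bj log2 f_bj` in bits (`0 log 0 = 0`). No
#' pseudocounts and no small-sample correction are applied.
#'
#' @param sites Stranded sites tibble (`contig, pos, strand`).
#' @param reference [Biostrings::DNAStringSet].
#' @param flank Flank width in nt (default 5).
#' @return Object of class `pfm`: frequency matrix (rows A,C,G,U), `ic`
#'   vector, `n_sequences`, `positions` (offsets relative to the site).
#' @export
build_pfm <- function(sites, reference, flank = 5) {
  w <- 2L * flank + 1L
  win <- extract_window(sites, reference, width = w)
  skip <- win$truncated
  if (any(skip)) {
    warning(sum(skip), " site(s) too close to a contig edge skipped")
    win <- win[!skip, , drop = FALSE]
  }
  if (nrow(win) == 0L) stop("no usable sites for PFM")
  mat <- matrix(0, nrow = 4, ncol = w,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  for (s in win$window) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (j in seq_len(w)) {
      if (ch[j] %in% rownames(mat)) mat[ch[j], j] <- mat[ch[j], j] + 1
    }
  }
  freq <- sweep(mat, 2, pmax(colSums(mat), 1), "/")
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(freq = freq, ic = ic, n_sequences = nrow(win),
                 positions = seq(-flank, flank)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm>", x$n_sequences, "sequences,", length(x$positions), "positions\n")
  print(round(x$freq, 3))
  invisible(x)
}

#' @rdname build_pfm
#' @param x A `pfm` object.
#' @param ... Unused.
#' @return `tidy.pfm`: tibble with `position`, `base`, `freq`, `ic`.
#' @export
tidy.pfm <- function(x, ...) {
  tidyr::expand_grid(position = x$positions, base = rownames(x$freq)) |>
    mutate(freq = purrr::map2_dbl(.data$position, .data$base, function(p, b) {
      x$freq[b, which(x$positions == p)]
    }),
    ic = x$ic[match(.data$position, x$positions)])
}

#' Motif enrichment of a test site set over controls
#'
#' Fold enrichment is the ratio of match fractions; the p-value is a
#' two-sided exact binomial test of the test matches with the control
#' fraction as the null probability (controls are treated as large enough to
#' fix the null). A control fraction of 0 with test matches present is
#' floored at `1 / (n_control + 1)` and flagged.
#'
#' @param test_match,control_match Logical match vectors from
#'   [match_motif()].
#' @return One-row tibble: `frac_test`, `frac_control`, `fold`, `pvalue`,
#'   `n_test`, `n_control`, `floored`.
#' @export
motif_enrichment <- function(test_match, control_match) {
  n1 <- length(test_match); n2 <- length(control_match)
  if (n1 == 0L) stop("empty test set")
  if (n2 == 0L) stop("empty control set")
  p1 <- mean(test_match); p2 <- mean(control_match)
  floored <- FALSE
  p0 <- p2
  if (p2 == 0 && sum(test_match) > 0) {
    p0 <- 1 / (n2 + 1)
    floored <- TRUE
  }
  pv <- if (p0 <= 0 || p0 >= 1) {
    if (p1 == p0) 1 else 0
  } else {
    binom.test(sum(test_match), n1, p = p0)$p.value
  }
  tibble(frac_test = p1, frac_control = p2,
         fold = if (p0 > 0) p1 / p0 else NA_real_,
         pvalue = pv, n_test = n1, n_control = n2, floored = floored)
}

#' Motif-by-structure contingency of editing effect sizes
#'
#' For each supplied pattern, partitions sites by motif match and loop
#' membership and summarises the editing effect (`delta_af`) per cell.
#'
#' @param sites Tibble with `window`, `offset`, `in_loop` and `delta_af`
#'   columns (e.g. [fold_sites()] output joined to DVR results).
#' @param patterns Named list of [motif_pattern()] objects.
#' @return Tibble with `pattern`, `matched`, `in_loop`, `n`,
#'   `mean_delta_af`, `sd_delta_af`; per pattern the cell counts sum to
#'   `nrow(sites)`.
#' @export
motif_by_structure_table <- function(sites, patterns) {
  purrr::imap_dfr(patterns, function(pat, nm) {
    m <- match_motif(sites$window, sites$offset, pat)
    tibble(pattern = nm, matched = m, in_loop = sites$in_loop,
           delta_af = sites$delta_af) |>
      group_by(.data$pattern, .data$matched, .data$in_loop) |>
      summarise(n = dplyr::n(),
                mean_delta_af = mean(.data$delta_af),
                sd_delta_af = sd(.data$delta_af),
                .groups = "drop")
  })
}
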