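#' Fold enrichment of IP signal over size-matched input at a position
#'
#' Mass-normalised per-base ratio
#' `(ip[pos] / ip_mass) / ((input[pos] + eps) / input_mass)` with a
#' pseudo-signal `eps` guarding empty input bases. Scaling either track by a
#' positive constant leaves the ratio unchanged.
#'
#' @param ip,input [coverage_track()]s on the same strand.
#' @param contig Contig name.
#' @param pos 1-based position(s); vectorised.
#' @param eps Input pseudo-signal (default 0.5).
#' @return Numeric fold enrichment(s).
#' @export
fold_enrichment <- function(ip, input, contig, pos, eps = 0.5) {
  if (input$total_mass <= 0) stop("input track has zero total mass")
  ipv <- ip$values[[contig]]
  inv <- input$values[[contig]]
  if (is.null(ipv) || is.null(inv)) stop("contig not in track: ", contig)
  (ipv[pos] / ip$total_mass) / ((inv[pos] + eps) / input$total_mass)
}

#' Per-site matrix of eCLIP fold enrichment around variant sites
#'
#' For every stranded site, computes fold enrichment at relative offsets
#' `-W..+W` in transcript orientation: offset +1 is the base immediately 3'
#' of the site on the transcript, so minus-strand sites read the genome
#' right-to-left. Offsets falling outside the contig are `NA` and excluded
#' from column summaries.
#'
#' @param sites Tibble with `contig`, `pos`, `strand` (`+`/`-`; others
#'   skipped with a warning).
#' @param ip,input Named lists `list("+" = coverage_track, "-" =
#'   coverage_track)` (a bare `coverage_track` is used for both strands).
#' @param W Half-window in nt (default 100).
#' @param eps Input pseudo-signal (default 0.5).
#' @return Matrix of class `eclip_profile` (rows sites, columns offsets).
#' @export
site_profile_matrix <- function(sites, ip, input, W = 100, eps = 0.5) {
  as_pair <- function(x) {
    if (inherits(x, "coverage_track")) list(`+` = x, `-` = x) else x
  }
  ip <- as_pair(ip); input <- as_pair(input)
  keep <- sites$strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " unstranded site(s) skipped")
    sites <- sites[keep, , drop = FALSE]
  }
  offs <- seq(-W, W)
  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = length(offs),
                dimnames = list(NULL, as.character(offs)))
  for (i in seq_len(nrow(sites))) {
    st <- sites$strand[i]
    cg <- sites$contig[i]
    ipt <- ip[[st]]; int <- input[[st]]
    L <- length(ipt$values[[cg]])
    gpos <- if (st == "+") sites$pos[i] + offs else sites$pos[i] - offs
    ok <- gpos >= 1 & gpos <= L
    mat[i, ok] <- fold_enrichment(ipt, int, cg, gpos[ok], eps = eps)
  }
  structure(mat, class = c("eclip_profile", "matrix"),
            sites = sites[, intersect(c("contig", "pos", "strand"),
                                      names(sites))])
}

#' @rdname site_profile_matrix
#' @param x An `eclip_profile` matrix.
#' @param ... Unused.
#' @return `tidy.eclip_profile`: tibble with `offset`, `mean_fe`,
#'   `median_fe`, `n_sites`.
#' @export
tidy.eclip_profile <- function(x, ...) {
  m <- unclass(x)
  tibble(
    offset = as.integer(colnames(m)),
    mean_fe = unname(apply(m, 2, mean, na.rm = TRUE)),
    median_fe = unname(apply(m, 2, median, na.rm = TRUE)),
    n_sites = unname(apply(m, 2, function(v) sum(!is.na(v))))
  )
}

#' Peak of the eCLIP metaprofile
#'
#' The metaprofile is the per-offset mean fold enrichment over sites; the
#' peak is its argmax. A bootstrap over sites gives a 95% confidence
#' interval for the peak offset, and a flat profile (max mean below
#' `flat_ratio` times the median mean) is flagged as having no peak.
#'
#' @param profile An `eclip_profile` from [site_profile_matrix()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param flat_ratio No-peak threshold on max/median of per-offset means
#'   (default 1.2).
#' @return One-row tibble: `peak_offset`, `peak_mean`, `ci_lo`, `ci_hi`,
#'   `no_peak`.
#' @export
metaprofile_peak <- function(profile, n_boot = 1000, seed = 1,
                             flat_ratio = 1.2) {
  m <- unclass(profile)
  stopifnot(nrow(m) >= 1L)
  offs <- as.integer(colnames(m))
  mu <- apply(m, 2, mean, na.rm = TRUE)
  peak <- offs[which.max(mu)]
  no_peak <- max(mu, na.rm = TRUE) < flat_ratio * median(mu, na.rm = TRUE)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(m), replace = TRUE)
      mb <- apply(m[idx, , drop = FALSE], 2, mean, na.rm = TRUE)
      offs[which.max(mb)]
    }, numeric(1))
  })
  ci <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 1)
  tibble(peak_offset = peak, peak_mean = max(mu, na.rm = TRUE),
         ci_lo = ci[1], ci_hi = ci[2], no_peak = no_peak)
}
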