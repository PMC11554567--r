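#' Per-DVR editing activity and activity shares
#'
#' Activity of a DVR is its alternative-allele read depth per million mapped
#' reads (CPM), averaged over the induced replicates; the share is each
#' DVR's activity divided by the summed activity of all DVRs. With
#' `background_subtract = TRUE` the mean control-group CPM is subtracted
#' first (floored at 0).
#'
#' @param counts Count table ([read_counts_table()] schema), typically
#'   restricted to called DVR sites.
#' @param induced Condition label of the induced group.
#' @param sites Optional tibble of sites (`contig, pos, ref, alt`, plus
#'   `gene_id` if available) to restrict to and annotate from.
#' @param background_subtract Subtract mean control CPM (default FALSE).
#' @return Tibble with one row per site: `contig, pos, ref, alt, gene_id,
#'   activity, share`; shares sum to 1.
#' @export
activity_per_dvr <- function(counts, induced, sites = NULL,
                             background_subtract = FALSE) {
  if (!induced %in% counts$condition) stop("condition not found: ", induced)
  if (!is.null(sites)) {
    counts <- semi_join(counts, sites, by = c("contig", "pos", "ref", "alt"))
  }
  act <- counts |>
    group_by(.data$contig, .data$pos, .data$ref, .data$alt) |>
    summarise(
      activity_ind = mean((.data$alt_count /
                             (.data$mapped_reads / 1e6))[.data$condition == induced]),
      activity_ctrl = mean((.data$alt_count /
                              (.data$mapped_reads / 1e6))[.data$condition != induced]),
      .groups = "drop") |>
    mutate(activity = if (background_subtract) {
      pmax(.data$activity_ind - .data$activity_ctrl, 0)
    } else .data$activity_ind) |>
    select(-"activity_ind", -"activity_ctrl")
  total <- sum(act$activity)
  if (total == 0) stop("total editing activity is zero")
  act <- mutate(act, share = .data$activity / total)
  if (!is.null(sites) && "gene_id" %in% names(sites)) {
    act <- left_join(act,
                     dplyr::distinct(sites, .data$contig, .data$pos,
                                     .data$ref, .data$alt, .data$gene_id),
                     by = c("contig", "pos", "ref", "alt"))
  } else {
    act <- mutate(act, gene_id = NA_character_)
  }
  select(act, "contig", "pos", "ref", "alt", "gene_id", "activity", "share")
}

#' Lorenz curve and Gini coefficient of editing activity
#'
#' Sorts activities ascending and builds the cumulative-share curve
#' `(k/n, sum_{i<=k} x_i / sum x)`; the Gini coefficient is computed by the
#' trapezoid rule `G = 1 - sum_k (L_k + L_{k-1}) / n`, which equals the
#' pairwise mean-absolute-difference form
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`.
#'
#' @param activities Non-negative numeric vector, not all zero.
#' @return Object of class `lorenz_result`: `curve` tibble
#'   (`rank_frac`, `cum_share`, starting at (0,0)) and `gini`.
#' @export
lorenz_gini <- function(activities) {
  stopifnot(length(activities) >= 1L, all(activities >= 0))
  if (sum(activities) == 0) stop("all activities are zero")
  x <- sort(activities)
  n <- length(x)
  L <- cumsum(x) / sum(x)
  gini <- 1 - sum(L + c(0, L[-n])) / n
  structure(list(
    curve = tibble(rank_frac = c(0, seq_len(n) / n), cum_share = c(0, L)),
    gini = gini, n = n
  ), class = "lorenz_result")
}

#' @export
print.lorenz_result <- function(x, ...) {
  cat("<lorenz_result> n =", x$n, "| Gini =", format(round(x$gini, 4)), "\n")
  invisible(x)
}

#' @rdname lorenz_gini
#' @param x A `lorenz_result`.
#' @param ... Unused.
#' @export
tidy.lorenz_result <- function(x, ...) x$curve

#' @rdname lorenz_gini
#' @export
glance.lorenz_result <- function(x, ...) tibble(gini = x$gini, n = x$n)

#' Concentration of editing activity across genes
#'
#' Aggregates DVR activity shares per gene, ranks genes by share, and finds
#' the smallest number of genes whose cumulative share reaches a target.
#'
#' @param shares Tibble from [activity_per_dvr()] (`gene_id`, `share`);
#'   unassigned DVRs count under gene `"NA"`.
#' @param target Cumulative share target (default 0.40).
#' @return Tibble of genes sorted by descending share with `share`,
#'   `cum_share` and `rank`; the attribute `k_genes` holds the smallest k
#'   with cumulative share >= target.
#' @export
gene_concentration <- function(shares, target = 0.40) {
  per_gene <- shares |>
    mutate(gene_id = ifelse(is.na(.data$gene_id), "NA", .data$gene_id)) |>
    group_by(.data$gene_id) |>
    summarise(share = sum(.data$share), .groups = "drop") |>
    arrange(dplyr::desc(.data$share)) |>
    mutate(cum_share = cumsum(.data$share), rank = dplyr::row_number())
  k <- which(per_gene$cum_share >= target)
  attr(per_gene, "k_genes") <- if (length(k)) min(k) else NA_integer_
  attr(per_gene, "target") <- target
  per_gene
}
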