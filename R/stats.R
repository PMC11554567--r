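#' Pooled allele fraction of one replicate group
#'
#' AF = (read depth of the alternative allele) / (total read depth), pooled
#' over replicates.
#'
#' @param alt_count,total_count Integer vectors, one entry per replicate.
#' @return Pooled fraction; `NA` if the pooled total is 0.
#' @export
pooled_af <- function(alt_count, total_count) {
  tot <- sum(total_count)
  if (tot == 0) return(NA_real_)
  sum(alt_count) / tot
}

#' Difference in pooled allele fraction between two groups
#'
#' `delta_af = AF(induced) - AF(control)`.
#'
#' @param alt_ctrl,total_ctrl Control-group replicate counts.
#' @param alt_ind,total_ind Induced-group replicate counts.
#' @return Signed fraction difference.
#' @export
delta_af <- function(alt_ctrl, total_ctrl, alt_ind, total_ind) {
  if (length(alt_ctrl) == 0L || length(alt_ind) == 0L) {
    stop("both condition groups must be present")
  }
  pooled_af(alt_ind, total_ind) - pooled_af(alt_ctrl, total_ctrl)
}

#' Beta-binomial log-likelihood of replicate allele counts
#'
#' The beta-binomial is parameterised by its mean allele fraction `pi` and
#' the intra-site correlation `rho`, with shape parameters
#' `alpha = pi (1 - rho) / rho` and `beta = (1 - pi)(1 - rho) / rho`.
#' As `rho -> 0` the distribution degenerates to the binomial, which is used
#' directly below `rho = 1e-9`; `pi` on the boundary is handled through the
#' binomial limit.
#'
#' @param alt_count,total_count Integer replicate counts.
#' @param pi Mean allele fraction in `[0, 1]`.
#' @param rho Overdispersion (intra-site correlation) in `[0, 1)`.
#' @return Summed log-likelihood over replicates (finite).
#' @export
betabin_loglik <- function(alt_count, total_count, pi, rho) {
  pi <- min(max(pi, 1e-12), 1 - 1e-12)
  if (rho < 1e-9) {
    return(sum(stats::dbinom(alt_count, total_count, pi, log = TRUE)))
  }
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  sum(lchoose(total_count, alt_count) +
        lbeta(alt_count + a, total_count - alt_count + b) - lbeta(a, b))
}

.PI_LO <- 1e-6
.PI_HI <- 1 - 1e-6
.RHO_LO <- 1e-9
.RHO_HI <- 0.5

# Maximise the H0 (common-mean) likelihood. Deterministic multi-start from
# pi in {pooled AF, 0.1, 0.9}.
.fit_null <- function(alt, total) {
  pooled <- pooled_af(alt, total)
  starts <- unique(pmin(pmax(c(pooled, 0.1, 0.9), .PI_LO), .PI_HI))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(c(p0, 0.01), function(th) {
        -betabin_loglik(alt, total, th[1], th[2])
      }, method = "L-BFGS-B",
      lower = c(.PI_LO, .RHO_LO), upper = c(.PI_HI, .RHO_HI)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(pi = best$par[1], rho = best$par[2], loglik = -best$value)
}

# Maximise the H1 (per-group means, shared rho) likelihood.
.fit_alt <- function(alt1, total1, alt2, total2) {
  p1 <- pooled_af(alt1, total1); p2 <- pooled_af(alt2, total2)
  starts <- list(c(p1, p2), c(0.1, 0.1), c(0.9, 0.9))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, .PI_LO), .PI_HI)
    fit <- tryCatch(
      optim(c(s, 0.01), function(th) {
        -(betabin_loglik(alt1, total1, th[1], th[3]) +
            betabin_loglik(alt2, total2, th[2], th[3]))
      }, method = "L-BFGS-B",
      lower = c(.PI_LO, .PI_LO, .RHO_LO), upper = c(.PI_HI, .PI_HI, .RHO_HI)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(pi1 = best$par[1], pi2 = best$par[2], rho = best$par[3],
       loglik = -best$value)
}

#' Likelihood-ratio test for a condition-dependent allele fraction at one site
#'
#' Fits, by numerical maximum likelihood, a null beta-binomial model with a
#' single mean allele fraction shared by both condition groups and an
#' alternative model with one mean per group; the overdispersion `rho` is
#' re-estimated under each hypothesis (profile likelihood-ratio test). The
#' statistic `2 * (loglik_alt - loglik_null)` (clipped at 0) is referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param alt_ctrl,total_ctrl Control-group replicate counts.
#' @param alt_ind,total_ind Induced-group replicate counts.
#' @return An object of class `betabin_lrt` with the fitted means, shared
#'   overdispersion under each hypothesis, log-likelihoods, LRT statistic and
#'   p-value. Non-convergence is flagged (`converged = FALSE`) and yields the
#'   conservative `pvalue = 1`.
#' @export
lrt_site <- function(alt_ctrl, total_ctrl, alt_ind, total_ind) {
  stopifnot(length(alt_ctrl) >= 2L, length(alt_ind) >= 2L)
  alt_all <- c(alt_ctrl, alt_ind)
  total_all <- c(total_ctrl, total_ind)
  out <- list(af_ctrl = pooled_af(alt_ctrl, total_ctrl),
              af_induced = pooled_af(alt_ind, total_ind))
  out$delta_af <- out$af_induced - out$af_ctrl

  degenerate <- all(alt_all == 0L) || all(alt_all == total_all)
  if (degenerate) {
    pi0 <- if (all(alt_all == 0L)) .PI_LO else .PI_HI
    ll <- betabin_loglik(alt_all, total_all, pi0, .RHO_LO)
    out <- c(out, list(pi_null = pi0, rho_null = .RHO_LO,
                       pi_ctrl = pi0, pi_induced = pi0, rho_alt = .RHO_LO,
                       loglik_null = ll, loglik_alt = ll,
                       lrt_stat = 0, pvalue = 1, converged = TRUE))
    class(out) <- "betabin_lrt"
    return(out)
  }

  f0 <- .fit_null(alt_all, total_all)
  f1 <- .fit_alt(alt_ctrl, total_ctrl, alt_ind, total_ind)
  if (is.null(f0) || is.null(f1)) {
    out <- c(out, list(pi_null = NA_real_, rho_null = NA_real_,
                       pi_ctrl = NA_real_, pi_induced = NA_real_,
                       rho_alt = NA_real_, loglik_null = NA_real_,
                       loglik_alt = NA_real_, lrt_stat = 0, pvalue = 1,
                       converged = FALSE))
    class(out) <- "betabin_lrt"
    return(out)
  }
  # H1 nests H0: never let optimiser noise report a worse alternative fit.
  ll1 <- max(f1$loglik, f0$loglik)
  stat <- max(0, 2 * (ll1 - f0$loglik))
  out <- c(out, list(pi_null = f0$pi, rho_null = f0$rho,
                     pi_ctrl = f1$pi1, pi_induced = f1$pi2, rho_alt = f1$rho,
                     loglik_null = f0$loglik, loglik_alt = ll1,
                     lrt_stat = stat,
                     pvalue = pchisq(stat, df = 1, lower.tail = FALSE),
                     converged = TRUE))
  class(out) <- "betabin_lrt"
  out
}

#' @export
print.betabin_lrt <- function(x, ...) {
  cat("<betabin_lrt> AF", format(round(x$af_ctrl, 4)), "->",
      format(round(x$af_induced, 4)),
      "| LRT", format(round(x$lrt_stat, 3)),
      "| p", format.pval(x$pvalue), "\n")
  invisible(x)
}

#' @rdname lrt_site
#' @param x A `betabin_lrt` object.
#' @param ... Unused.
#' @export
tidy.betabin_lrt <- function(x, ...) {
  tibble(
    term = c("pi_null", "pi_ctrl", "pi_induced", "rho_null", "rho_alt"),
    estimate = c(x$pi_null, x$pi_ctrl, x$pi_induced, x$rho_null, x$rho_alt)
  )
}

#' @rdname lrt_site
#' @export
glance.betabin_lrt <- function(x, ...) {
  tibble(
    af_ctrl = x$af_ctrl, af_induced = x$af_induced, delta_af = x$delta_af,
    loglik_null = x$loglik_null, loglik_alt = x$loglik_alt,
    lrt_stat = x$lrt_stat, pvalue = x$pvalue, converged = x$converged
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control:
#' `q_i = min over {j : p_j >= p_i} of m * p_j / rank_j`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Monotone q-values in `[0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Classify a substitution by edit type on the transcript strand
#'
#' @param ref_ts,alt_ts Transcript-strand reference and alternative bases
#'   (`U` and `T` both accepted).
#' @param strand Transcript strand: `"+"`, `"-"`, or `"*"`/`NA` for unknown.
#' @return Character vector over `{"C>U", "A>G(I)", "other", "unstranded"}`.
#' @export
classify_edit <- function(ref_ts, alt_ts, strand) {
  r <- sub("U", "T", toupper(ref_ts))
  a <- sub("U", "T", toupper(alt_ts))
  dplyr::case_when(
    is.na(strand) | !strand %in% c("+", "-") ~ "unstranded",
    r == "C" & a == "T" ~ "C>U",
    r == "A" & a == "G" ~ "A>G(I)",
    TRUE ~ "other"
  )
}

#' Call differential variants in RNA (DVRs) from a replicated count table
#'
#' Runs the per-site beta-binomial likelihood-ratio test across all sites of
#' a count table, applies Benjamini-Hochberg FDR control jointly across all
#' tested sites, and classifies each site's substitution on the transcript
#' strand. A site qualifies as a DVR when `fdr <= fdr_alpha` (and, if
#' requested, `|delta_af| >= min_delta_af`).
#'
#' @param counts Count table in the [read_counts_table()] schema. If the
#'   strand columns from [orient_to_transcript()] (`strand`, `gene_id`,
#'   `ref_ts`, `alt_ts`) are absent and `genes` is supplied, orientation is
#'   performed here.
#' @param genes Optional gene annotation from [read_bed_genes()].
#' @param control,induced Condition labels; by default the alphabetically
#'   first label is the control group.
#' @param fdr_alpha DVR qualification threshold on the BH q-value
#'   (default 0.05).
#' @param min_delta_af Optional absolute effect-size threshold (default 0:
#'   FDR is the sole criterion).
#' @return A tibble of class `dvr_results`, one row per site, with pooled
#'   AFs, `delta_af`, `lrt_stat`, `pvalue`, `fdr`, `class` and `is_dvr`.
#' @export
call_dvrs <- function(counts, genes = NULL, control = NULL, induced = NULL,
                      fdr_alpha = 0.05, min_delta_af = 0) {
  conds <- sort(unique(counts$condition))
  if (length(conds) != 2L) stop("need exactly 2 condition labels")
  if (is.null(control)) control <- conds[1]
  if (is.null(induced)) induced <- setdiff(conds, control)
  stopifnot(control %in% conds, induced %in% conds, control != induced)

  sites <- dplyr::distinct(counts, .data$contig, .data$pos, .data$ref, .data$alt)
  if (!is.null(genes)) {
    sites <- orient_to_transcript(sites, genes)
  } else if (!all(c("strand", "gene_id", "ref_ts", "alt_ts") %in% names(sites))) {
    sites <- sites |>
      mutate(strand = NA_character_, gene_id = NA_character_,
             ref_ts = .data$ref, alt_ts = .data$alt)
  }

  nested <- counts |>
    dplyr::group_by(.data$contig, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      fit = list(lrt_site(
        .data$alt_count[.data$condition == control],
        .data$total_count[.data$condition == control],
        .data$alt_count[.data$condition == induced],
        .data$total_count[.data$condition == induced])),
      .groups = "drop")

  res <- nested |>
    mutate(purrr::map_dfr(.data$fit, glance)) |>
    select(-"fit") |>
    left_join(sites, by = c("contig", "pos", "ref", "alt")) |>
    mutate(
      fdr = bh_fdr(.data$pvalue),
      class = classify_edit(.data$ref_ts, .data$alt_ts, .data$strand),
      is_dvr = .data$fdr <= fdr_alpha & abs(.data$delta_af) >= min_delta_af
    ) |>
    arrange(.data$contig, .data$pos, .data$alt)
  class(res) <- c("dvr_results", class(res))
  attr(res, "fdr_alpha") <- fdr_alpha
  attr(res, "conditions") <- c(control = control, induced = induced)
  res
}

#' Break down called DVRs by edit class and direction of change
#'
#' @param results A `dvr_results` tibble from [call_dvrs()].
#' @return Tibble with one row per `(class, direction)` cell among qualifying
#'   DVRs and the count `n`; row counts sum to the number of DVRs.
#' @export
dvr_breakdown <- function(results) {
  classes <- c("C>U", "A>G(I)", "other", "unstranded")
  grid <- tidyr::expand_grid(class = classes, direction = c("up", "down"))
  got <- results |>
    filter(.data$is_dvr) |>
    mutate(direction = ifelse(.data$delta_af >= 0, "up", "down")) |>
    dplyr::count(.data$class, .data$direction)
  grid |>
    left_join(got, by = c("class", "direction")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}
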