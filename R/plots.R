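#' Volcano plot of per-site test results
#'
#' Plots the change in allele fraction against the FDR, with the
#' qualification threshold marked, per edit class.
#'
#' @param object A `dvr_results` tibble from [call_dvrs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvr_results <- function(object, ...) {
  alpha <- attr(object, "fdr_alpha") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_af,
                                       y = -log10(pmax(.data$fdr, 1e-300)),
                                       colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::labs(x = expression(Delta * "AF (induced - control)"),
                  y = expression(-log[10] ~ "FDR"), colour = "class") +
    ggplot2::theme_minimal()
}

#' Lorenz curve of editing activity
#' @param object A `lorenz_result` from [lorenz_gini()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lorenz_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$rank_frac, .data$cum_share)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::annotate("text", x = 0.25, y = 0.9,
                      label = sprintf("Gini = %.3f", object$gini)) +
    ggplot2::labs(x = "cumulative fraction of DVRs (ranked by activity)",
                  y = "cumulative share of C>U activity") +
    ggplot2::theme_minimal()
}

#' eCLIP fold-enrichment metaprofile
#' @param object An `eclip_profile` from [site_profile_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eclip_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$offset, .data$mean_fe)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from site (nt, transcript orientation)",
                  y = "mean fold enrichment (IP / input)") +
    ggplot2::theme_minimal()
}

#' Information-content profile of a position frequency matrix
#' @param object A `pfm` from [build_pfm()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfm <- function(object, ...) {
  df <- tibble(position = object$positions, ic = object$ic)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$ic)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "offset from edited base (nt)",
                  y = "information content (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
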