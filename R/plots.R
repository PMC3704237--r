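#' Manhattan-style plot of an association scan
#'
#' Plots `-log10(p)` against genomic position, one panel stripe per
#' chromosome, with the significance threshold as a horizontal line and
#' validated SNPs (if a validation table is supplied) marked by triangles.
#'
#' @param gwas A `gwas_table` from [run_gwas()].
#' @param p_threshold Threshold line (default 0.001).
#' @param validation Optional [validate_snps()] result; validated SNPs are
#'   highlighted.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(gwas, p_threshold = 0.001, validation = NULL) {
  df <- gwas %>%
    filter(!.data$failed & !is.na(.data$p)) %>%
    mutate(
      chrom = factor(.data$chrom, levels = unique(.data$chrom)),
      logp = -log10(pmax(.data$p, 1e-300))
    )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$logp,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(p))),
                  title = paste0("Association scan: ",
                                 toupper(df$component[1]))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
  if (!is.null(validation) && nrow(validation)) {
    hits <- df %>% filter(.data$snp %in% validation$snp[validation$validated])
    if (nrow(hits)) {
      gg <- gg + ggplot2::geom_point(data = hits, shape = 17, size = 2,
                                     colour = "black")
    }
  }
  gg
}

#' @rdname plot_manhattan
#' @param object,... `autoplot` arguments (`object` is the `gwas_table`).
#' @export
autoplot.gwas_table <- function(object, ...) plot_manhattan(object, ...)

#' Plot fitted sire reaction norms
#'
#' Draws each sire's fitted line `mu + (b + es) * E + gp` over the range
#' of observed environments, coloured by the sire's general-production
#' estimate.
#'
#' @param object A `reaction_norm_fit`.
#' @param env_range Environment range to draw (default -2.5 to 2.5 SD).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reaction_norm_fit <- function(object, env_range = c(-2.5, 2.5), ...) {
  est <- object$sire_estimates
  df <- tidyr::crossing(est, env = seq(env_range[1], env_range[2], length.out = 2)) %>%
    mutate(y = object$mu + object$b * .data$env +
             .data$gp + .data$es * .data$env)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$env, y = .data$y,
                                   group = .data$sire, colour = .data$gp)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "standardized environment", y = "expected yield",
                  colour = "GP") +
    ggplot2::theme_minimal()
}

#' Plot the observed-scale versus log-scale ES classification
#'
#' Scatter of validation-set ES effects on the two scales (in units of
#' the respective sire slope SD), coloured by classification.
#'
#' @param object A `scale_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scale_comparison <- function(object, ...) {
  df <- object$table %>%
    filter(!is.na(.data$beta_obs_sd) | !is.na(.data$beta_log_sd)) %>%
    tidyr::replace_na(list(beta_obs_sd = 0, beta_log_sd = 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_obs_sd, y = .data$beta_log_sd,
                                   colour = .data$classification)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ES effect, observed scale (slope-SD units)",
                  y = "ES effect, log scale (slope-SD units)") +
    ggplot2::theme_minimal()
}
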