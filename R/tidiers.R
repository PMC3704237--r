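#' Tidy a reaction-norm fit
#'
#' One row per model term: fixed effects, sire (co)variance components
#' (with asymptotic SEs when the fit computed them), daughter components,
#' and per-class residual variances.
#'
#' @param x A `reaction_norm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `boundary`.
#' @export
tidy.reaction_norm_fit <- function(x, ...) {
  sc <- x$sire_components
  terms <- c("mu", "b_env",
             "sigma_s0_sq", "sigma_s0s1", "sigma_s1_sq", "rho_s0s1",
             "sigma_d0_sq",
             if (x$mode == "heterogeneous") c("sigma_d0d1", "sigma_d1_sq"),
             paste0("sigma_e_sq.", seq_len(x$n_classes)))
  est <- c(x$mu, x$b,
           sc[["sigma_s0_sq"]], sc[["sigma_s0s1"]], sc[["sigma_s1_sq"]],
           sc[["rho_s0s1"]],
           x$Gd[1, 1],
           if (x$mode == "heterogeneous") c(x$Gd[1, 2], x$Gd[2, 2]),
           x$sigma2_e)
  se <- rep(NA_real_, length(terms))
  if (!is.null(x$component_se)) {
    i <- match(x$component_se$component, terms)
    se[i[!is.na(i)]] <- x$component_se$se[!is.na(i)]
  }
  bnd <- rep(NA, length(terms))
  bnd[match(names(x$boundary), terms)] <- x$boundary
  tibble(term = terms, estimate = est, std.error = se, boundary = bnd)
}

#' Glance at a reaction-norm fit
#'
#' @param x A `reaction_norm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `n_records`, `n_sires`, `mode`,
#'   `pedigree_correlated`, `iterations`, `converged`.
#' @export
glance.reaction_norm_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    n_records = x$n_records,
    n_sires = nrow(x$sire_estimates),
    mode = x$mode,
    pedigree_correlated = x$pedigree_correlated,
    iterations = x$convergence$iterations,
    converged = identical(x$convergence$code, 0L) ||
      identical(x$convergence$code, 0)
  )
}

#' Tidy a scale-comparison result
#'
#' @param x A `scale_comparison`.
#' @param ... Unused.
#' @return The per-SNP classification tibble.
#' @export
tidy.scale_comparison <- function(x, ...) x$table
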