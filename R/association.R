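#' Random split into discovery and validation sets
#'
#' Uniformly random, seed-reproducible partition of the sire ids.
#'
#' @param ids Character vector of sire ids.
#' @param n_validation Validation-set size (default 500).
#' @param seed Integer seed.
#' @return List of class `split_plan`: `discovery`, `validation`, `seed`.
#' @export
split_sires <- function(ids, n_validation = 500, seed = 1L) {
  n <- length(ids)
  if (n_validation >= n) {
    abort("`n_validation` must be smaller than the number of sires.",
          class = "reactnorm_config_error")
  }
  set.seed(seed)
  val <- sort(sample.int(n, n_validation))
  structure(
    list(discovery = ids[-val], validation = ids[val], seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", length(x$discovery), " discovery / ",
      length(x$validation), " validation sires (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Eigendecomposition of the kinship matrix, computed once per sire set.
eigen_kinship <- function(A, ids) {
  if (!all(ids %in% rownames(A))) {
    abort("relationship matrix does not cover all requested sires.",
          class = "reactnorm_domain_error")
  }
  A <- A[ids, ids, drop = FALSE]
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(e$values)) {
    abort("relationship matrix is not positive semidefinite.",
          class = "reactnorm_domain_error")
  }
  list(U = e$vectors, lambda = pmax(e$values, 0), ids = ids)
}

# Profile REML criterion in the rotated single-SNP model; delta is the
# ratio sigma2_sire / sigma2_e.
snp_reml_profile <- function(yt, Xt, lambda, log_delta) {
  delta <- exp(log_delta)
  w <- 1 / (delta * lambda + 1)
  n <- length(yt)
  p <- ncol(Xt)
  XtW <- Xt * w
  XtWX <- crossprod(XtW, Xt)
  XtWy <- crossprod(XtW, yt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  sig2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(sig2) + 1 + log(2 * pi)) +
                  sum(log(delta * lambda + 1)) + 2 * sum(log(diag(ch))))
  list(ll = ll, beta = drop(beta), sig2 = sig2, XtWX = XtWX)
}

#' Single-SNP mixed linear model with a kinship-structured polygenic term
#'
#' Fits `y = mu + x b + u + e` with `u ~ N(0, A sigma2_s)` and
#' `e ~ N(0, I sigma2_e)` by REML: a one-time eigendecomposition of A
#' rotates the model to independent errors, after which the variance ratio
#' is profiled by one-dimensional optimization and the SNP effect is a
#' weighted regression.  The p-value is a normal-reference Wald test on
#' `b`.
#'
#' @param y Numeric response (one sire estimate per individual).
#' @param x Allele-copy counts (0/1/2) of the counted allele.
#' @param A Relationship matrix (with dimnames) or `NULL` when `eig` is
#'   given.
#' @param eig Optional precomputed eigendecomposition from the internal
#'   kinship cache; used by [run_gwas()] to avoid repeating the
#'   decomposition.
#' @param delta Optional fixed variance ratio `sigma2_s / sigma2_e`; when
#'   supplied (approximate mode) the per-SNP profiling is skipped.
#' @return List: `beta`, `se`, `stat`, `p`, `delta`, `loglik`.
#' @export
fit_snp_mlm <- function(y, x, A = NULL, eig = NULL, delta = NULL) {
  if (var(x) == 0) {
    abort("monomorphic SNP: effect undefined.", class = "reactnorm_domain_error")
  }
  if (is.null(eig)) {
    if (is.null(A)) abort("supply `A` or `eig`.", class = "reactnorm_domain_error")
    ids <- names(y)
    if (is.null(ids)) ids <- rownames(A)
    eig <- eigen_kinship(A, ids)
  }
  yt <- crossprod(eig$U, y)
  Xt <- crossprod(eig$U, cbind(1, x))
  lambda <- eig$lambda
  if (is.null(delta)) {
    opt <- optimize(function(ld) {
      v <- -snp_reml_profile(yt, Xt, lambda, ld)$ll
      if (is.finite(v)) v else 1e10
    }, interval = c(-25, 15), tol = 1e-8)
    log_delta <- opt$minimum
  } else {
    log_delta <- log(max(delta, 1e-12))
  }
  prof <- snp_reml_profile(yt, Xt, lambda, log_delta)
  if (!is.finite(prof$ll)) {
    abort("singular design in SNP model.", class = "reactnorm_domain_error")
  }
  vb <- prof$sig2 * solve(prof$XtWX)[2, 2]
  se <- sqrt(vb)
  stat <- prof$beta[2] / se
  list(beta = prof$beta[2], se = se, stat = stat,
       p = 2 * pnorm(-abs(stat)), delta = exp(log_delta), loglik = prof$ll)
}

# Estimate the variance ratio once under the no-SNP null model.
null_delta <- function(yt0, lambda) {
  opt <- optimize(function(ld) -snp_reml_profile(yt0$yt, yt0$Xt, lambda, ld)$ll,
                  interval = c(-25, 15), tol = 1e-8)
  exp(opt$minimum)
}

#' Genome-wide single-SNP association scan on sire estimates
#'
#' Runs [fit_snp_mlm()] for every SNP against the chosen sire-estimate
#' component (GP intercept or ES slope), flags significance at
#' `p < p_threshold`, and appends Storey q-values.
#'
#' @param estimates Tibble from [fit_reaction_norm()]'s `$sire_estimates`
#'   (columns `sire`, `gp`, `es`), or any data frame with a `sire` column
#'   and the component column.
#' @param genotypes A post-QC, imputed `geno_matrix` covering the sires.
#' @param A Numerator relationship matrix covering the sires.
#' @param component `"gp"` or `"es"`.
#' @param p_threshold Pointwise significance threshold (default 0.001).
#' @param reestimate_delta Re-profile the variance ratio for every SNP
#'   (exact; default) or estimate it once under the null and reuse it
#'   (faster, approximate).
#' @return Tibble of class `gwas_table`: snp, chrom, pos, component, freq,
#'   beta, se, stat, p, q, significant, failed.
#' @export
run_gwas <- function(estimates, genotypes, A, component = c("gp", "es"),
                     p_threshold = 0.001, reestimate_delta = TRUE) {
  component <- match.arg(component)
  estimates <- as_tibble(estimates)
  stopifnot("sire" %in% names(estimates), component %in% names(estimates))
  ids <- estimates$sire
  calls <- genotypes$calls
  if (!all(ids %in% rownames(calls))) {
    abort("genotypes missing for some sires with estimates.",
          class = "reactnorm_domain_error")
  }
  if (anyNA(calls)) {
    abort("genotypes contain missing calls; run `impute_sporadic()` first.",
          class = "reactnorm_domain_error")
  }
  G <- calls[ids, , drop = FALSE]
  y <- estimates[[component]]
  if (var(y) == 0) {
    warn(paste0("sire estimates for `", component,
                "` are constant (boundary variance component); ",
                "all association tests undefined."))
    out <- tibble(
      snp = genotypes$map$snp, chrom = genotypes$map$chrom,
      pos = genotypes$map$pos, component = component,
      freq = colMeans(G) / 2, beta = NA_real_, se = NA_real_,
      stat = NA_real_, p = NA_real_, q = NA_real_,
      significant = FALSE, failed = TRUE
    )
    class(out) <- c("gwas_table", class(out))
    return(out)
  }
  eig <- eigen_kinship(A, ids)
  yt <- drop(crossprod(eig$U, y))
  ones_t <- crossprod(eig$U, matrix(1, length(y), 1))
  Gt <- crossprod(eig$U, G)

  delta_fix <- if (reestimate_delta) NULL else {
    null_delta(list(yt = yt, Xt = ones_t), eig$lambda)
  }

  m <- ncol(G)
  beta <- se <- stat <- p <- freq <- rep(NA_real_, m)
  failed <- rep(FALSE, m)
  for (k in seq_len(m)) {
    x <- G[, k]
    freq[k] <- mean(x) / 2
    if (var(x) == 0) { failed[k] <- TRUE; next }
    Xt <- cbind(ones_t, Gt[, k])
    if (is.null(delta_fix)) {
      opt <- optimize(function(ld) {
        v <- -snp_reml_profile(yt, Xt, eig$lambda, ld)$ll
        if (is.finite(v)) v else 1e10
      }, interval = c(-25, 15), tol = 1e-8)
      ld <- opt$minimum
    } else {
      ld <- log(max(delta_fix, 1e-12))
    }
    prof <- snp_reml_profile(yt, Xt, eig$lambda, ld)
    if (!is.finite(prof$ll)) { failed[k] <- TRUE; next }
    vb <- prof$sig2 * solve(prof$XtWX)[2, 2]
    beta[k] <- prof$beta[2]
    se[k] <- sqrt(vb)
    stat[k] <- beta[k] / se[k]
    p[k] <- 2 * pnorm(-abs(stat[k]))
  }

  q <- rep(NA_real_, m)
  ok <- !failed & !is.na(p)
  if (any(ok)) q[ok] <- qvalues(p[ok])$qvalues
  out <- tibble(
    snp = genotypes$map$snp,
    chrom = genotypes$map$chrom,
    pos = genotypes$map$pos,
    component = component,
    freq = freq, beta = beta, se = se, stat = stat, p = p, q = q,
    significant = !is.na(p) & p < p_threshold,
    failed = failed
  )
  class(out) <- c("gwas_table", class(out))
  out
}

#' Confirm discovery-significant SNPs in the validation set
#'
#' Refits the single-SNP mixed model for each discovery-significant SNP on
#' the validation sires only.  A SNP is validated when its validation
#' p-value is below `p_validation` *and* the effect has the same (strictly
#' nonzero) sign in both sets.  Validation-set estimates are retained as
#' the reporting estimates, as they are less affected by winner's-curse
#' (Beavis) bias.
#'
#' @param discovery A `gwas_table` from [run_gwas()] on the discovery set.
#' @param validation_estimates Sire estimates for the validation sires.
#' @param genotypes,A As in [run_gwas()]; `A` is the same full-population
#'   relationship matrix, restricted internally to the validation sires.
#' @param p_validation Validation threshold (default 0.01).
#' @return Tibble: snp, component, beta_discovery, p_discovery,
#'   beta_validation, se_validation, p_validation, sign_match, validated.
#' @export
validate_snps <- function(discovery, validation_estimates, genotypes, A,
                          p_validation = 0.01) {
  stopifnot(inherits(discovery, "gwas_table"))
  component <- discovery$component[1]
  sig <- discovery %>% filter(.data$significant & !.data$failed)
  if (nrow(sig) == 0) {
    return(tibble(
      snp = character(), component = character(),
      beta_discovery = numeric(), p_discovery = numeric(),
      beta_validation = numeric(), se_validation = numeric(),
      p_validation = numeric(), sign_match = logical(), validated = logical()
    ))
  }
  validation_estimates <- as_tibble(validation_estimates)
  ids <- validation_estimates$sire
  calls <- genotypes$calls
  if (!all(ids %in% rownames(calls))) {
    abort("genotypes missing for some validation sires.",
          class = "reactnorm_domain_error")
  }
  y <- validation_estimates[[component]]
  eig <- if (var(y) > 0) eigen_kinship(A, ids) else NULL
  G <- calls[ids, sig$snp, drop = FALSE]
  res <- purrr::map(seq_len(nrow(sig)), function(i) {
    f <- if (is.null(eig)) NULL else {
      tryCatch(fit_snp_mlm(y, G[, i], eig = eig), error = function(e) NULL)
    }
    if (is.null(f)) return(tibble(beta_validation = NA_real_,
                                  se_validation = NA_real_,
                                  p_validation = NA_real_))
    tibble(beta_validation = f$beta, se_validation = f$se, p_validation = f$p)
  }) %>% bind_rows()
  out <- tibble(
    snp = sig$snp, component = component,
    beta_discovery = sig$beta, p_discovery = sig$p
  ) %>% dplyr::bind_cols(res)
  out$sign_match <- !is.na(out$beta_validation) &
    sign(out$beta_discovery) != 0 & sign(out$beta_validation) != 0 &
    sign(out$beta_discovery) == sign(out$beta_validation)
  out$validated <- !is.na(out$p_validation) &
    out$p_validation < p_validation & out$sign_match
  out
}

#' Realized false-discovery-rate estimate at the significance threshold
#'
#' Returns the q-value of the significant SNP with the largest p-value not
#' exceeding the threshold — an estimate of the proportion of
#' false-positive results among the significant associations.
#'
#' @param gwas A `gwas_table`.
#' @param p_threshold Significance threshold (default 0.001).
#' @return Scalar q-value, or `NA` (with a warning) when no SNP is
#'   significant.
#' @export
estimate_fdr_at_threshold <- function(gwas, p_threshold = 0.001) {
  ok <- !is.na(gwas$p) & gwas$p <= p_threshold
  if (!any(ok)) {
    warn("no SNP significant at the threshold; FDR estimate undefined.")
    return(NA_real_)
  }
  sub <- gwas[ok, ]
  sub$q[which.max(sub$p)]
}
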