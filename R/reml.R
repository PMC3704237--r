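# Internal data preparation for the reaction-norm REML core.
#
# Records are sorted by sire then daughter so each daughter's records are
# contiguous; the C++ routine absorbs daughter blocks in that order.
prep_reml_data <- function(records, mode, trait = "yield", n_classes = 10) {
  records <- as_tibble(records)
  need <- c("daughter", "sire", "env", trait)
  if (!all(need %in% names(records))) {
    abort(paste0("records need columns: ", paste(need, collapse = ", ")),
          class = "reactnorm_domain_error")
  }
  if (mode == "heterogeneous" && !"res_class" %in% names(records)) {
    records$res_class <- assign_residual_classes(records, n_classes = n_classes)
  }
  ord <- order(records$sire, records$daughter)
  records <- records[ord, , drop = FALSE]

  sire_levels <- unique(records$sire)
  daughter_key <- paste(records$sire, records$daughter, sep = "\r")
  d_idx <- match(daughter_key, unique(daughter_key))
  d_start <- c(0L, cumsum(tabulate(d_idx)))
  d_sire <- match(records$sire[d_start[-length(d_start)] + 1L], sire_levels) - 1L

  y <- records[[trait]]
  if (anyNA(y) || anyNA(records$env)) {
    abort("records must be complete (no missing yield or environment).",
          class = "reactnorm_domain_error")
  }
  X <- cbind(1, records$env)
  Ws <- X
  if (mode == "heterogeneous") {
    Wd <- X
    rclass <- as.integer(records$res_class)
    K <- max(rclass)
  } else {
    Wd <- matrix(1, nrow(records), 1)
    rclass <- rep(1L, nrow(records))
    K <- 1L
  }
  if (length(sire_levels) < 2) {
    abort("at least 2 sires are required.", class = "reactnorm_domain_error")
  }
  if (length(unique(records$env)) < 2) {
    abort("environment values are constant; slope not identifiable.",
          class = "reactnorm_domain_error")
  }
  list(records = records, y = y, X = X, Ws = Ws, Wd = Wd,
       d_start = as.integer(d_start), d_sire = as.integer(d_sire),
       rclass = rclass, n_classes = K, sire_levels = sire_levels,
       daughters_per_sire = tabulate(d_sire + 1L, nbins = length(sire_levels)))
}

theta_dim <- function(mode, n_classes) {
  if (mode == "heterogeneous") 6L + n_classes else 4L + 1L
}

# theta -> natural-scale components (log-Cholesky for the 2x2 blocks,
# log variance for the rest)
components_from_theta <- function(theta, mode, n_classes) {
  Ls <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  Gs <- Ls %*% t(Ls)
  if (mode == "heterogeneous") {
    Ld <- matrix(c(exp(theta[4]), theta[5], 0, exp(theta[6])), 2, 2)
    Gd <- Ld %*% t(Ld)
    sigma2_e <- exp(theta[6 + seq_len(n_classes)])
  } else {
    Gd <- matrix(exp(2 * theta[4]), 1, 1)
    sigma2_e <- exp(theta[5])
  }
  list(Gs = Gs, Gd = Gd, sigma2_e = sigma2_e)
}

theta_from_components <- function(comp, mode) {
  Ls <- t(chol(regularize_pd(comp$Gs)))
  th <- c(log(Ls[1, 1]), Ls[2, 1], log(Ls[2, 2]))
  if (mode == "heterogeneous") {
    Ld <- t(chol(regularize_pd(comp$Gd)))
    c(th, log(Ld[1, 1]), Ld[2, 1], log(Ld[2, 2]), log(comp$sigma2_e))
  } else {
    c(th, 0.5 * log(comp$Gd[1, 1]), log(comp$sigma2_e[1]))
  }
}

regularize_pd <- function(M, floor_frac = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lo <- max(abs(e$values), 1e-300) * floor_frac
  e$vectors %*% (pmax(e$values, lo) * t(e$vectors)) |> unname()
}

reml_eval <- function(prep, comp, Ainv = NULL, logdetA = 0, want_blups = FALSE) {
  .reml_blocked_cpp(
    prep$y, prep$records$env,
    prep$d_start, prep$d_sire, prep$rclass, comp$sigma2_e,
    comp$Gs, comp$Gd,
    if (is.null(Ainv)) matrix(0, 0, 0) else Ainv,
    logdetA, want_blups
  )
}

#' Restricted log-likelihood of the reaction-norm sire model
#'
#' Evaluates the exact REML log-likelihood of
#' `y = mu + b*env + (s0 + s1*env) + (d0 [+ d1*env]) + e` at given
#' variance components, with the fixed effects handled by the REML
#' projection.  Daughter effects and residuals are absorbed per daughter,
#' so the computation is linear in the number of records.
#'
#' @param records Record tibble with columns `daughter`, `sire`, `env`,
#'   the trait column, and (heterogeneous mode) `res_class`.
#' @param components List with `Gs` (2x2 sire covariance), `Gd` (2x2
#'   daughter covariance, or 1x1/scalar in homogeneous mode) and
#'   `sigma2_e` (vector of per-class residual variances; length 1 in
#'   homogeneous mode).
#' @param mode `"heterogeneous"` (daughter slope + decile residual
#'   variances) or `"homogeneous"` (daughter intercept only, single
#'   residual variance).
#' @param sire_relationship Optional numerator relationship matrix among
#'   sires (dimnames must cover all sires); `NULL` fits i.i.d. sire
#'   effects.
#' @param trait Name of the trait column.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglikelihood <- function(records, components,
                               mode = c("heterogeneous", "homogeneous"),
                               sire_relationship = NULL, trait = "yield") {
  mode <- match.arg(mode)
  comp <- normalize_components(components, mode)
  prep <- prep_reml_data(records, mode, trait = trait)
  Ak <- prep_relationship(sire_relationship, prep$sire_levels)
  reml_eval(prep, comp, Ak$Ainv, Ak$logdetA)$loglik
}

normalize_components <- function(components, mode) {
  Gs <- components$Gs
  if (is.null(dim(Gs))) Gs <- cov2_from(Gs[1], Gs[3], Gs[2] / sqrt(Gs[1] * Gs[3]))
  Gd <- components$Gd
  if (is.null(dim(Gd))) Gd <- matrix(Gd[1], 1, 1)
  if (mode == "heterogeneous" && nrow(Gd) != 2) {
    abort("heterogeneous mode needs a 2x2 daughter covariance.",
          class = "reactnorm_domain_error")
  }
  if (mode == "homogeneous") Gd <- Gd[1, 1, drop = FALSE]
  sigma2_e <- as.numeric(components$sigma2_e)
  if (any(sigma2_e <= 0)) {
    abort("residual variances must be positive.", class = "reactnorm_domain_error")
  }
  ev <- eigen(Gs, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("sire covariance must be positive semidefinite.",
          class = "reactnorm_domain_error")
  }
  list(Gs = regularize_pd(Gs), Gd = regularize_pd(Gd), sigma2_e = sigma2_e)
}

prep_relationship <- function(A, sire_levels) {
  if (is.null(A)) return(list(Ainv = NULL, logdetA = 0))
  if (is.null(dimnames(A)[[1]]) || !all(sire_levels %in% rownames(A))) {
    abort("`sire_relationship` must have dimnames covering all sires with records.",
          class = "reactnorm_domain_error")
  }
  extra <- setdiff(rownames(A), sire_levels)
  if (length(extra)) {
    A <- A[sire_levels, sire_levels, drop = FALSE]
  } else {
    A <- A[sire_levels, sire_levels, drop = FALSE]
  }
  ld <- determinant(A, logarithm = TRUE)
  if (ld$sign <= 0) {
    abort("`sire_relationship` must be positive definite.",
          class = "reactnorm_domain_error")
  }
  list(Ainv = solve(A), logdetA = as.numeric(ld$modulus))
}

# Moment-based starting values: per-sire OLS of yield on environment.
start_components <- function(prep, mode) {
  recs <- prep$records
  y <- prep$y
  vy <- var(y)
  fits <- recs %>%
    mutate(.y = y) %>%
    group_by(.data$sire) %>%
    summarise(
      n = dplyr::n(),
      nenv = length(unique(.data$env)),
      a = mean(.y),
      b = if (length(unique(.data$env)) > 1)
        stats::cov(.y, .data$env) / var(.data$env) else NA_real_,
      v = var(.y),
      .groups = "drop"
    )
  ok <- fits$n >= 3 & fits$nenv >= 2 & is.finite(fits$b)
  if (sum(ok) >= 5) {
    va <- var(fits$a[ok]); vb <- var(fits$b[ok])
    cab <- stats::cov(fits$a[ok], fits$b[ok])
    vw <- mean(fits$v[ok], na.rm = TRUE)
    Gs <- regularize_pd(0.5 * matrix(c(va, cab, cab, vb), 2, 2), 1e-4)
  } else {
    vw <- vy
    Gs <- diag(c(0.1 * vy, 0.02 * vy))
  }
  Gs <- Gs + diag(c(1e-4 * vy, 1e-5 * vy))
  if (mode == "heterogeneous") {
    Gd <- diag(c(0.25 * vw, 0.05 * vw))
    sigma2_e <- rep(0.6 * vw, prep$n_classes)
  } else {
    Gd <- matrix(0.25 * vw, 1, 1)
    sigma2_e <- 0.7 * vw
  }
  list(Gs = Gs, Gd = Gd, sigma2_e = sigma2_e)
}

#' Fit the first-order reaction-norm sire model by REML
#'
#' Maximizes the restricted likelihood of the random-regression sire model
#' over an unconstrained parameterization (log-Cholesky factors for the
#' sire and daughter covariance blocks, log residual variances) with a
#' quasi-Newton optimizer, falling back to Nelder-Mead if needed, and
#' returns the converged variance components together with the BLUP sire
#' intercept (general production, GP) and slope (environmental
#' sensitivity, ES) estimates.
#'
#' Two modes are provided.  `"heterogeneous"` is the observed-scale model:
#' correlated daughter intercept/slope effects and one residual variance
#' per environment decile.  `"homogeneous"` drops the daughter slope and
#' fits a single residual variance; it is the variant used for
#' log-transformed yields, where the full model is poorly conditioned.
#'
#' @inheritParams reml_loglikelihood
#' @param se Compute asymptotic standard errors of the sire components
#'   from the numerically differentiated observed information (moderately
#'   expensive; a singular information matrix, e.g. on a flat ridge of the
#'   likelihood, is handled by a pseudo-inverse).
#' @param start Optional starting `components` list (as in
#'   [reml_loglikelihood()]); default: method-of-moments from per-sire
#'   regressions.
#' @param control List: `iter_max` (default 200), `rel_tol` (default 1e-8
#'   on the objective), `var_floor_frac` (variance floor as a fraction of
#'   `var(y)`, default 1e-10).
#' @return An object of class `reaction_norm_fit`; see [tidy()] and
#'   [glance()] methods, `$sire_estimates` (tibble: sire, n_daughters, gp,
#'   es) and `$components`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_sires = 15, daughters_per_sire = 8,
#'                                    n_snps = 10, n_qtl = 0, seed = 4))
#' fit <- fit_reaction_norm(sim$records, se = FALSE)
#' glance(fit)
#' @export
fit_reaction_norm <- function(records,
                              mode = c("heterogeneous", "homogeneous"),
                              sire_relationship = NULL, trait = "yield",
                              se = TRUE, start = NULL, control = list()) {
  mode <- match.arg(mode)
  ctl <- utils::modifyList(
    list(iter_max = 200L, rel_tol = 1e-8, var_floor_frac = 1e-10), control)
  prep <- prep_reml_data(records, mode, trait = trait)
  Ak <- prep_relationship(sire_relationship, prep$sire_levels)
  vy <- var(prep$y)
  vfloor <- ctl$var_floor_frac * vy

  comp0 <- if (is.null(start)) start_components(prep, mode)
           else normalize_components(start, mode)
  theta0 <- theta_from_components(comp0, mode)
  K <- prep$n_classes
  npar <- theta_dim(mode, K)
  stopifnot(length(theta0) == npar)

  tracker <- new.env(parent = emptyenv())
  tracker$best <- -Inf
  tracker$trace <- numeric(0)
  negll <- function(theta) {
    comp <- components_from_theta(theta, mode, K)
    val <- tryCatch(reml_eval(prep, comp, Ak$Ainv, Ak$logdetA)$loglik,
                    error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10)
    if (val > tracker$best) {
      tracker$best <- val
      tracker$trace <- c(tracker$trace, val)
    }
    -val
  }

  # unconstrained quasi-Newton: the log-Cholesky/log parameterization keeps
  # every covariance positive (semi)definite, and non-finite evaluations
  # are mapped to a large penalty
  opt <- tryCatch(
    nlminb(theta0, negll,
           control = list(iter.max = ctl$iter_max, eval.max = 50L * ctl$iter_max,
                          rel.tol = ctl$rel_tol)),
    error = function(e) NULL
  )
  used_fallback <- FALSE
  if (is.null(opt) || !is.finite(opt$objective) || opt$objective >= 1e10) {
    used_fallback <- TRUE
    o2 <- optim(theta0, negll, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-12))
    opt <- list(par = o2$par,
                objective = o2$value, iterations = o2$counts[[1]],
                convergence = o2$convergence, message = "Nelder-Mead fallback")
  }
  if (!is.finite(opt$objective) || opt$objective >= 1e10) {
    abort("REML optimization failed to find a finite likelihood.",
          class = "reactnorm_fit_error")
  }

  # Nelder-Mead polish: quasi-Newton can declare convergence prematurely on
  # small or near-boundary problems; if the simplex search improves the
  # objective, restart the quasi-Newton pass from the better point
  polish <- optim(opt$par, negll, method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-12))
  if (is.finite(polish$value) && polish$value < opt$objective - 1e-9) {
    opt2 <- tryCatch(
      nlminb(polish$par, negll,
             control = list(iter.max = ctl$iter_max,
                            eval.max = 50L * ctl$iter_max,
                            rel.tol = ctl$rel_tol)),
      error = function(e) NULL
    )
    if (!is.null(opt2) && is.finite(opt2$objective) &&
        opt2$objective <= polish$value) {
      opt2$iterations <- opt$iterations + opt2$iterations
      opt <- opt2
    } else {
      opt <- list(par = polish$par, objective = polish$value,
                  iterations = opt$iterations,
                  convergence = 0L, message = "Nelder-Mead polish")
    }
  }

  theta_hat <- opt$par
  comp_hat <- components_from_theta(theta_hat, mode, K)
  sol <- reml_eval(prep, comp_hat, Ak$Ainv, Ak$logdetA, want_blups = TRUE)

  # Boundary detection: in the log-Cholesky parameterization a variance
  # component cannot reach 0 exactly (the likelihood flattens as the log
  # standard deviation heads to -Inf), so a slope variance that converged
  # below 0.1% of its own intercept variance — or any variance at the
  # absolute floor — is reported as a boundary (zero) estimate.
  at_floor <- function(v, ref = NULL) {
    v <= vfloor * 2 || (!is.null(ref) && v <= 1e-3 * ref)
  }
  boundary <- c(
    sigma_s0_sq = at_floor(comp_hat$Gs[1, 1]),
    sigma_s1_sq = at_floor(comp_hat$Gs[2, 2], comp_hat$Gs[1, 1]),
    sigma_d0_sq = at_floor(comp_hat$Gd[1, 1]),
    sigma_d1_sq = if (mode == "heterogeneous")
      at_floor(comp_hat$Gd[2, 2], comp_hat$Gd[1, 1]) else NA
  )
  report_var <- function(v, bnd) if (isTRUE(bnd)) 0 else v

  sire_comp <- c(
    sigma_s0_sq = report_var(comp_hat$Gs[1, 1], boundary[["sigma_s0_sq"]]),
    sigma_s0s1 = comp_hat$Gs[1, 2],
    sigma_s1_sq = report_var(comp_hat$Gs[2, 2], boundary[["sigma_s1_sq"]]),
    rho_s0s1 = if (comp_hat$Gs[1, 1] > 0 && comp_hat$Gs[2, 2] > 0)
      comp_hat$Gs[1, 2] / sqrt(comp_hat$Gs[1, 1] * comp_hat$Gs[2, 2]) else NA_real_
  )

  se_tbl <- NULL
  if (se) {
    se_tbl <- component_se(theta_hat, negll, mode, K)
  }

  est <- tibble(
    sire = prep$sire_levels,
    n_daughters = prep$daughters_per_sire,
    gp = sol$u[, 1],
    es = sol$u[, 2]
  )
  # a variance component reported as 0 (boundary) implies identically-zero
  # BLUPs for that effect: with sigma2_s1 = 0 the PSD constraint also
  # forces sigma_s0s1 = 0, so the slope predictions vanish exactly
  if (isTRUE(boundary[["sigma_s1_sq"]])) est$es <- 0
  if (isTRUE(boundary[["sigma_s0_sq"]])) est$gp <- 0

  structure(list(
    mu = sol$beta[1], b = sol$beta[2],
    Gs = comp_hat$Gs, Gd = comp_hat$Gd, sigma2_e = comp_hat$sigma2_e,
    sire_components = sire_comp,
    component_se = se_tbl,
    boundary = boundary,
    loglik = -opt$objective,
    loglik_trace = tracker$trace,
    convergence = list(iterations = opt$iterations,
                       code = opt$convergence,
                       message = if (used_fallback) "Nelder-Mead fallback"
                                 else opt$message),
    mode = mode, trait = trait,
    pedigree_correlated = !is.null(Ak$Ainv),
    theta = theta_hat, n_records = length(prep$y),
    n_classes = K,
    sire_estimates = est
  ), class = "reaction_norm_fit")
}

# Delta-method SEs for (sigma_s0_sq, sigma_s1_sq, rho) from the observed
# information of the working parameters.  A singular information matrix
# (flat likelihood ridge) falls back to an eigenvalue pseudo-inverse.
component_se <- function(theta_hat, negll, mode, K) {
  H <- tryCatch(optimHess(theta_hat, negll), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  inv <- ifelse(e$values > tol, 1 / e$values, 0)
  Vth <- e$vectors %*% (inv * t(e$vectors))
  g <- function(th) {
    cm <- components_from_theta(th, mode, K)
    r <- if (cm$Gs[1, 1] > 0 && cm$Gs[2, 2] > 0)
      cm$Gs[1, 2] / sqrt(cm$Gs[1, 1] * cm$Gs[2, 2]) else 0
    c(cm$Gs[1, 1], cm$Gs[1, 2], cm$Gs[2, 2], r)
  }
  J <- matrix(0, 4, length(theta_hat))
  h <- pmax(1e-5, abs(theta_hat) * 1e-5)
  for (j in seq_along(theta_hat)) {
    tp <- theta_hat; tm <- theta_hat
    tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
    J[, j] <- (g(tp) - g(tm)) / (2 * h[j])
  }
  Vg <- J %*% Vth %*% t(J)
  tibble(
    component = c("sigma_s0_sq", "sigma_s0s1", "sigma_s1_sq", "rho_s0s1"),
    estimate = g(theta_hat),
    se = sqrt(pmax(diag(Vg), 0))
  )
}

#' BLUP sire estimates of general production and environmental sensitivity
#'
#' Returns the best linear unbiased predictions of the per-sire
#' reaction-norm intercept (GP) and slope (ES) at the fitted variance
#' components, either as stored in the fit or re-solved for a new set of
#' records.
#'
#' @param fit A [fit_reaction_norm()] result.
#' @param records Optional records to re-solve the mixed-model equations
#'   on; default: the estimates stored in the fit.
#' @return Tibble with columns `sire`, `n_daughters`, `gp`, `es`.
#' @export
predict_sire_effects <- function(fit, records = NULL) {
  stopifnot(inherits(fit, "reaction_norm_fit"))
  if (is.null(records)) return(fit$sire_estimates)
  prep <- prep_reml_data(records, fit$mode, trait = fit$trait)
  comp <- normalize_components(
    list(Gs = fit$Gs, Gd = fit$Gd, sigma2_e = fit$sigma2_e), fit$mode)
  sol <- reml_eval(prep, comp, NULL, 0, want_blups = TRUE)
  tibble(
    sire = prep$sire_levels,
    n_daughters = prep$daughters_per_sire,
    gp = sol$u[, 1],
    es = sol$u[, 2]
  )
}

#' @export
print.reaction_norm_fit <- function(x, ...) {
  cat("<reaction_norm_fit> mode=", x$mode,
      if (x$pedigree_correlated) " (pedigree-correlated sires)" else "",
      ", ", x$n_records, " records, ", nrow(x$sire_estimates), " sires\n",
      sep = "")
  cat(sprintf("  mu=%.4g  b=%.4g  logLik=%.4f\n", x$mu, x$b, x$loglik))
  sc <- x$sire_components
  cat(sprintf("  sigma2_s0=%.4g  sigma2_s1=%.4g  rho=%.3f\n",
              sc[["sigma_s0_sq"]], sc[["sigma_s1_sq"]], sc[["rho_s0s1"]]))
  invisible(x)
}
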