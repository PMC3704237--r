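#' Configuration for the synthetic progeny-test simulator
#'
#' Bundles and validates every parameter of the synthetic half-sib
#' progeny-test generator: the family structure (sires, daughters per sire,
#' herd-test-day environments), the SNP panel, the quantitative-genetic
#' architecture (correlated sire and daughter intercept/slope effects, QTL
#' mixture), and the residual model (ten environment-decile variances).
#'
#' Defaults emulate a protein-yield progeny-test study: sire intercept/slope
#' (co)variances of 2379.37 / 17.02 with correlation 0.79 (grams-per-day
#' scale), daughter variances roughly three times the sire values (a sire
#' model assigns a quarter of the additive variance to sires and the
#' remaining three quarters, plus permanent environment, to daughters), and
#' residual variances increasing across environment deciles, as poorer
#' environments are typically less variable in absolute terms.
#'
#' @param n_sires Number of genotyped sires with daughter records.
#' @param daughters_per_sire Daughters per sire; a single count or a
#'   length-2 range sampled uniformly per sire.
#' @param records_per_daughter Records per daughter, each at a distinct
#'   herd-test-day (default 10, emulating roughly ten first-lactation
#'   test-day records per cow in routine milk recording).  With a single
#'   record per daughter the daughter covariance block is confounded with
#'   the residual-class variances (a daughter then contributes no
#'   within-daughter covariance), so at least two records are needed for
#'   the full model to be identifiable.
#' @param n_htd Number of herd-test-day environments.
#' @param n_snps Number of simulated SNPs.
#' @param n_qtl Number of SNPs with a true effect on the sire intercept and
#'   slope; must not exceed `n_snps`.
#' @param maf_range Range (length 2, in (0, 0.5]) from which per-SNP minor
#'   allele frequencies are drawn uniformly.
#' @param sigma_s0_sq,sigma_s1_sq,rho_s Sire intercept variance, slope
#'   variance (trait units squared) and intercept-slope correlation.
#' @param sigma_d0_sq,sigma_d1_sq,rho_d Daughter analogues.
#' @param residual_class_variances Ten positive residual variances, one per
#'   environment decile (lowest decile first). In multiplicative mode and
#'   for `fit_reaction_norm(mode = "homogeneous")` only a single residual
#'   variance is used; pass a length-1 value in that case or the mean of the
#'   ten is taken.
#' @param mu Overall trait mean (trait units; log-scale mean in
#'   multiplicative mode).
#' @param b_fixed Fixed regression of yield on the standardized environment.
#' @param qtl_var_fraction Fraction of the sire (co)variance attributable to
#'   the QTL set (0 when `n_qtl = 0`).
#' @param qtl_large_fraction,qtl_large_ratio Mixture architecture of QTL
#'   effects: a fraction `qtl_large_fraction` of QTL are "large", drawn with
#'   `qtl_large_ratio`-fold the standard deviation of the "small" component
#'   (many genes of small effect, few of large effect).
#' @param gxe_mode `"additive"` (yields generated on the observed scale with
#'   sire/daughter slopes and decile-heterogeneous residuals) or
#'   `"multiplicative"` (yields are exponentiated from a log-scale model
#'   with *no* slope variance, so all genotype-by-environment interaction on
#'   the observed scale is pure scaling).
#' @param missing_rate Fraction of genotype calls set missing.
#' @param seed Master integer seed; every `simulate_*()` stage derives its
#'   own sub-stream deterministically from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_sires = 20, daughters_per_sire = 10, n_snps = 50)
#' cfg$sigma_s0_sq
#' @export
sim_config <- function(n_sires = 200,
                       daughters_per_sire = 100,
                       records_per_daughter = 10,
                       n_htd = 500,
                       n_snps = 1000,
                       n_qtl = min(20L, n_snps),
                       maf_range = c(0.05, 0.5),
                       sigma_s0_sq = 2379.37,
                       sigma_s1_sq = 17.02,
                       rho_s = 0.79,
                       sigma_d0_sq = 7200,
                       sigma_d1_sq = 51,
                       rho_d = 0.6,
                       residual_class_variances = seq(20000, 33000, length.out = 10),
                       mu = 900,
                       b_fixed = 110,
                       qtl_var_fraction = if (n_qtl > 0) 0.3 else 0,
                       qtl_large_fraction = 0.1,
                       qtl_large_ratio = 5,
                       gxe_mode = c("additive", "multiplicative"),
                       missing_rate = 0,
                       seed = 1L) {
  gxe_mode <- match.arg(gxe_mode)
  stopifnot(
    length(n_sires) == 1, n_sires >= 2,
    length(daughters_per_sire) %in% c(1, 2), all(daughters_per_sire >= 1),
    length(records_per_daughter) == 1, records_per_daughter >= 1,
    n_htd >= 1, n_snps >= 1, n_qtl >= 0, n_qtl <= n_snps,
    length(maf_range) == 2
  )
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5] and be non-decreasing.",
          class = "reactnorm_config_error")
  }
  vars <- c(sigma_s0_sq, sigma_s1_sq, sigma_d0_sq, sigma_d1_sq)
  if (any(vars < 0)) {
    abort("variance components must be non-negative.", class = "reactnorm_config_error")
  }
  if (abs(rho_s) > 1 || abs(rho_d) > 1) {
    abort("|rho_s| and |rho_d| must not exceed 1.", class = "reactnorm_config_error")
  }
  if (qtl_var_fraction < 0 || qtl_var_fraction > 1) {
    abort("`qtl_var_fraction` must lie in [0, 1].", class = "reactnorm_config_error")
  }
  if (n_qtl == 0 && qtl_var_fraction > 0) {
    abort("`qtl_var_fraction` > 0 requires `n_qtl` > 0.", class = "reactnorm_config_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).", class = "reactnorm_config_error")
  }
  if (gxe_mode == "additive") {
    if (length(residual_class_variances) != 10 || any(residual_class_variances <= 0)) {
      abort("`residual_class_variances` must be 10 positive values in additive mode.",
            class = "reactnorm_config_error")
    }
  } else {
    if (any(residual_class_variances <= 0)) {
      abort("residual variance must be positive.", class = "reactnorm_config_error")
    }
  }
  structure(
    list(
      n_sires = as.integer(n_sires),
      daughters_per_sire = as.integer(daughters_per_sire),
      records_per_daughter = as.integer(records_per_daughter),
      n_htd = as.integer(n_htd),
      n_snps = as.integer(n_snps),
      n_qtl = as.integer(n_qtl),
      maf_range = as.numeric(maf_range),
      sigma_s0_sq = sigma_s0_sq, sigma_s1_sq = sigma_s1_sq, rho_s = rho_s,
      sigma_d0_sq = sigma_d0_sq, sigma_d1_sq = sigma_d1_sq, rho_d = rho_d,
      residual_class_variances = as.numeric(residual_class_variances),
      mu = mu, b_fixed = b_fixed,
      qtl_var_fraction = qtl_var_fraction,
      qtl_large_fraction = qtl_large_fraction,
      qtl_large_ratio = qtl_large_ratio,
      gxe_mode = gxe_mode,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' A multiplicative (pure-scaling GxE) simulator configuration
#'
#' Convenience wrapper around [sim_config()] with log-scale defaults: the
#' trait is generated as `exp(mu + b*E + s0 + d0 + e)` with *no* slope
#' variance on the log scale, so all observed-scale genotype-by-environment
#' interaction is scaling.  Default log-scale variances are chosen so that a
#' desk-scale study (hundreds of sires, ~100 records each) estimates sire
#' reaction-norm slopes with useful accuracy.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `"sim_config"` with `gxe_mode = "multiplicative"`.
#' @export
sim_config_multiplicative <- function(...) {
  defaults <- list(
    gxe_mode = "multiplicative",
    mu = 6.8, b_fixed = 0.15,
    sigma_s0_sq = 0.01, sigma_s1_sq = 0, rho_s = 0,
    sigma_d0_sq = 0.008, sigma_d1_sq = 0, rho_d = 0,
    residual_class_variances = 0.012
  )
  overrides <- list(...)
  do.call(sim_config, utils::modifyList(defaults, overrides))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$gxe_mode, " GxE, ", x$n_sires, " sires x ",
      paste(x$daughters_per_sire, collapse = "-"), " daughters, ",
      x$n_snps, " SNPs (", x$n_qtl, " QTL), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
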