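#' Natural-log transform of trait records
#'
#' Replaces the trait by its natural logarithm; all yields must be
#' strictly positive.  Used to remove scaling genotype-by-environment
#' interaction before refitting the reaction-norm model.
#'
#' @param records Record tibble.
#' @param trait Trait column name.
#' @return The records with `trait` log-transformed; the transformation is
#'   recorded in attribute `transform`.
#' @export
log_transform_records <- function(records, trait = "yield") {
  records <- as_tibble(records)
  y <- records[[trait]]
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad)) {
    abort(paste0("nonpositive yields cannot be log-transformed (rows ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else "", ")."),
          class = "reactnorm_domain_error")
  }
  records[[trait]] <- log(y)
  attr(records, "transform") <- "log"
  records
}

#' Observed-scale versus log-scale SNP classification
#'
#' Runs the full reaction-norm + association + validation pipeline twice —
#' on the observed scale (heterogeneous-residual model with daughter
#' slopes) and on natural-log-transformed yields (homogeneous-residual
#' model without daughter slopes) — using the *same* discovery/validation
#' split, and classifies every SNP by where it is validated for
#' environmental sensitivity (ES):
#' `observed_only` (scaling-removable GxE), `both` (persistent GxE),
#' `log_only`, or `neither`.
#'
#' @param records Record tibble (strictly positive yields).
#' @param genotypes Post-QC, imputed `geno_matrix`.
#' @param A Numerator relationship matrix over all sires.
#' @param split A [split_sires()] plan.
#' @param p_discovery,p_validation Significance thresholds (defaults 0.001
#'   and 0.01).
#' @return List of class `scale_comparison`: `table` (tibble: snp,
#'   validated_obs_es, validated_log_es, classification, beta_obs,
#'   beta_log, beta_obs_sd, beta_log_sd — the `_sd` columns are in units
#'   of the fitted sire slope SD on each scale), the two fits, and the two
#'   ES `gwas_table`s.
#' @export
run_scale_comparison <- function(records, genotypes, A, split,
                                 p_discovery = 0.001, p_validation = 0.01) {
  stopifnot(inherits(split, "split_plan"))

  run_one <- function(recs, mode) {
    fit <- fit_reaction_norm(recs, mode = mode, se = FALSE)
    est <- fit$sire_estimates
    disc <- est %>% filter(.data$sire %in% split$discovery)
    val <- est %>% filter(.data$sire %in% split$validation)
    gwas <- run_gwas(disc, genotypes, A, component = "es",
                     p_threshold = p_discovery)
    vl <- validate_snps(gwas, val, genotypes, A, p_validation = p_validation)
    list(fit = fit, gwas = gwas, validation = vl)
  }

  obs <- run_one(records, "heterogeneous")
  logs <- run_one(log_transform_records(records), "homogeneous")

  all_snps <- genotypes$map$snp
  flag_of <- function(vl) {
    v <- setNames(rep(FALSE, length(all_snps)), all_snps)
    if (nrow(vl)) v[vl$snp[vl$validated]] <- TRUE
    v
  }
  beta_of <- function(vl) {
    b <- setNames(rep(NA_real_, length(all_snps)), all_snps)
    if (nrow(vl)) b[vl$snp] <- vl$beta_validation
    b
  }
  v_obs <- flag_of(obs$validation)
  v_log <- flag_of(logs$validation)
  sd_slope_obs <- sqrt(obs$fit$Gs[2, 2])
  sd_slope_log <- sqrt(logs$fit$Gs[2, 2])
  b_obs <- beta_of(obs$validation)
  b_log <- beta_of(logs$validation)

  tab <- tibble(
    snp = all_snps,
    validated_obs_es = unname(v_obs),
    validated_log_es = unname(v_log),
    classification = dplyr::case_when(
      v_obs & v_log ~ "both",
      v_obs & !v_log ~ "observed_only",
      !v_obs & v_log ~ "log_only",
      TRUE ~ "neither"
    ),
    beta_obs = unname(b_obs),
    beta_log = unname(b_log),
    beta_obs_sd = unname(b_obs) / ifelse(sd_slope_obs > 0, sd_slope_obs, NA_real_),
    beta_log_sd = unname(b_log) / ifelse(sd_slope_log > 0, sd_slope_log, NA_real_)
  )
  structure(
    list(table = tab, fit_observed = obs$fit, fit_log = logs$fit,
         gwas_observed = obs$gwas, gwas_log = logs$gwas,
         validation_observed = obs$validation, validation_log = logs$validation,
         split = split),
    class = "scale_comparison"
  )
}

#' @export
print.scale_comparison <- function(x, ...) {
  counts <- table(factor(x$table$classification,
                         levels = c("observed_only", "both", "log_only", "neither")))
  cat("<scale_comparison> ES-validated SNP classification:\n")
  print(counts)
  invisible(x)
}
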