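#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML (or already-parsed list) with blocks:
#' `seed`; either `simulation:` (fields of [sim_config()]) or `inputs:`
#' (`records`, `pedigree` CSV paths and a PLINK `genotypes` prefix);
#' optional `qc:` thresholds (`max_missing`, `maf_min`, `call_rate_min`,
#' `hwe_alpha`); `split:` (`n_validation`); `thresholds:` (`discovery`,
#' `validation`); and `scale_comparison: true/false`.  Validation is
#' fail-fast: thresholds must lie in (0, 1), referenced files must exist,
#' and the validation set must be smaller than the sire set.
#'
#' @param config Path to a YAML file or a list.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(
    seed = 1L,
    qc = list(max_missing = 0.10, maf_min = 0.03, call_rate_min = 0.90,
              hwe_alpha = 0.001),
    split = list(n_validation = 500L),
    thresholds = list(discovery = 0.001, validation = 0.01),
    scale_comparison = FALSE
  )
  cfg <- utils::modifyList(defaults, cfg)
  thr <- unlist(cfg$thresholds)
  if (any(thr <= 0 | thr >= 1)) {
    abort("significance thresholds must lie in (0, 1).",
          class = "reactnorm_config_error")
  }
  has_sim <- !is.null(cfg$simulation)
  has_inputs <- !is.null(cfg$inputs)
  if (has_sim == has_inputs) {
    abort("exactly one of `simulation:` or `inputs:` must be given.",
          class = "reactnorm_config_error")
  }
  if (has_sim) {
    sim_args <- cfg$simulation
    sim_args$seed <- cfg$seed
    cfg$sim_config <- do.call(sim_config, sim_args)
    if (cfg$split$n_validation >= cfg$sim_config$n_sires) {
      abort("validation set must be smaller than the number of sires.",
            class = "reactnorm_config_error")
    }
  } else {
    paths <- c(cfg$inputs$records, cfg$inputs$pedigree,
               paste0(cfg$inputs$genotypes, c(".ped", ".map")))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(paste0("input files not found: ", paste(missing, collapse = ", ")),
            class = "reactnorm_config_error")
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full reaction-norm GWAS pipeline
#'
#' Orchestrates simulate (or load) -> genotype QC -> environment
#' descriptor -> reaction-norm REML fit -> kinship matrix ->
#' discovery/validation association scans for GP and ES -> optional
#' observed-vs-log scale comparison.  Every stage writes its output table
#' under `out_dir`, and a manifest records each artifact's MD5 hash, the
#' seed, and per-stage wall time, so a run can be reproduced and checked
#' byte for byte.
#'
#' @param config A [read_run_config()] result, a config list, or a YAML
#'   path.
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest` (tibble), `fit`, `gwas` (per component),
#'   `validation` (per component), and `scale_comparison` (if requested),
#'   invisibly also written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list()
  t_stage <- function(stage, files, t0) {
    tibble(stage = stage, file = basename(files),
           md5 = unname(tools::md5sum(files)),
           seconds = round(as.numeric(Sys.time()) - t0, 2),
           seed = cfg$seed)
  }
  outfile <- function(...) file.path(out_dir, paste0(...))
  log_stage <- function(...) message("[reactnorm] ", ...)

  # -- stage: data ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(cfg$sim_config)) {
    log_stage("simulate: ", cfg$sim_config$n_sires, " sires")
    sim <- simulate_dataset(cfg$sim_config)
    genotypes <- sim$genotypes
    records <- sim$records
    pedigree <- sim$pedigree
    write_plink(genotypes, outfile("genotypes"))
    readr::write_csv(records, outfile("records.csv"))
    readr::write_csv(pedigree, outfile("pedigree.csv"))
    readr::write_csv(sim$truth$sires, outfile("truth_sires.SYNTHETIC-TEST-ONLY.csv"))
    readr::write_csv(sim$truth$qtl, outfile("truth_qtl.SYNTHETIC-TEST-ONLY.csv"))
    files <- outfile(c("genotypes.ped", "genotypes.map", "records.csv",
                       "pedigree.csv", "truth_sires.SYNTHETIC-TEST-ONLY.csv",
                       "truth_qtl.SYNTHETIC-TEST-ONLY.csv"))
    manifest$data <- t_stage("simulate", files, t0)
  } else {
    log_stage("load inputs")
    genotypes <- read_plink(cfg$inputs$genotypes)
    records <- readr::read_csv(cfg$inputs$records, show_col_types = FALSE)
    pedigree <- readr::read_csv(cfg$inputs$pedigree, show_col_types = FALSE)
    manifest$data <- t_stage("load", c(cfg$inputs$records, cfg$inputs$pedigree), t0)
  }

  # -- stage: qc --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  log_stage("genotype qc")
  qc <- run_genotype_qc(genotypes,
                        max_missing = cfg$qc$max_missing,
                        maf_min = cfg$qc$maf_min,
                        call_rate_min = cfg$qc$call_rate_min,
                        hwe_alpha = cfg$qc$hwe_alpha)
  readr::write_csv(qc$snp_report, outfile("qc_snp_report.csv"))
  readr::write_csv(qc$individual_report, outfile("qc_individual_report.csv"))
  genotypes <- qc$genotypes
  manifest$qc <- t_stage("qc", outfile(c("qc_snp_report.csv",
                                         "qc_individual_report.csv")), t0)

  # -- stage: descriptor ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  log_stage("environment descriptor")
  descriptor <- compute_environment_descriptor(records)
  readr::write_csv(descriptor, outfile("environment_descriptor.csv"))
  if (!"env" %in% names(records)) {
    records <- left_join(records, select(descriptor, "htd", "env"), by = "htd")
  }
  manifest$descriptor <- t_stage("descriptor",
                                 outfile("environment_descriptor.csv"), t0)

  # -- stage: reaction norm ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  log_stage("reaction-norm REML fit")
  fit <- fit_reaction_norm(records, mode = "heterogeneous", se = FALSE)
  readr::write_csv(tidy(fit), outfile("reaction_norm_components.csv"))
  readr::write_csv(fit$sire_estimates, outfile("sire_estimates.csv"))
  manifest$fit <- t_stage("fit-rn", outfile(c("reaction_norm_components.csv",
                                              "sire_estimates.csv")), t0)

  # -- stage: kinship + split + gwas ------------------------------------
  t0 <- as.numeric(Sys.time())
  log_stage("kinship and association scans")
  sires <- fit$sire_estimates$sire
  A <- build_numerator_relationship(pedigree, sires)
  keep <- intersect(sires, rownames(genotypes$calls))
  if (length(keep) < length(sires)) {
    warn(paste0(length(sires) - length(keep),
                " sires lack post-QC genotypes and are dropped from the scan."))
  }
  est <- fit$sire_estimates %>% filter(.data$sire %in% keep)
  split <- split_sires(est$sire, n_validation = cfg$split$n_validation,
                       seed = stage_seed(cfg$seed, "split"))
  gwas <- list(); validation <- list()
  for (comp in c("gp", "es")) {
    disc <- est %>% filter(.data$sire %in% split$discovery)
    val <- est %>% filter(.data$sire %in% split$validation)
    gw <- run_gwas(disc, genotypes, A, component = comp,
                   p_threshold = cfg$thresholds$discovery)
    vl <- validate_snps(gw, val, genotypes, A,
                        p_validation = cfg$thresholds$validation)
    readr::write_csv(gw, outfile("gwas_", comp, ".csv"))
    readr::write_csv(vl, outfile("validated_", comp, ".csv"))
    gwas[[comp]] <- gw
    validation[[comp]] <- vl
  }
  manifest$gwas <- t_stage("gwas", outfile(c("gwas_gp.csv", "gwas_es.csv",
                                             "validated_gp.csv",
                                             "validated_es.csv")), t0)

  # -- stage: scale comparison ------------------------------------------
  sc <- NULL
  if (isTRUE(cfg$scale_comparison)) {
    t0 <- as.numeric(Sys.time())
    log_stage("observed vs log scale comparison")
    sc <- run_scale_comparison(records, genotypes, A, split,
                               p_discovery = cfg$thresholds$discovery,
                               p_validation = cfg$thresholds$validation)
    readr::write_csv(sc$table, outfile("scale_comparison.csv"))
    manifest$scale <- t_stage("compare-scales", outfile("scale_comparison.csv"), t0)
  }

  manifest <- bind_rows(manifest)
  readr::write_csv(manifest, outfile("manifest.csv"))
  invisible(list(manifest = manifest, fit = fit, gwas = gwas,
                 validation = validation, scale_comparison = sc,
                 split = split, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
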