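#' Simulate sire genotypes under Hardy-Weinberg sampling
#'
#' Draws a biallelic SNP panel for the sires: per-SNP allele frequencies
#' uniform on `config$maf_range`, genotypes binomial(2, f) per individual,
#' and sporadic missingness at `config$missing_rate`.  SNP metadata
#' (autosome label, base-pair position, allele pair) is assigned
#' deterministically from the seed.  No linkage disequilibrium is simulated.
#'
#' @param config A [sim_config()].
#' @return A `geno_matrix`: list with `calls` (integer matrix, sires x SNPs,
#'   values 0/1/2/`NA` counting copies of the counted allele) and `map`
#'   (tibble: snp, chrom, pos, allele1, allele2, counted_allele).  When the
#'   matrix was simulated, the pre-masking complete calls are kept in the
#'   `complete` element for ground-truth use only.
#' @examples
#' g <- simulate_genotypes(sim_config(n_sires = 10, n_snps = 5, seed = 2))
#' dim(g$calls)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_sires
  m <- config$n_snps
  f <- runif(m, config$maf_range[1], config$maf_range[2])
  calls <- matrix(
    rbinom(n * m, size = 2L, prob = rep(f, each = n)),
    nrow = n, ncol = m
  )
  ids <- sprintf("S%04d", seq_len(n))
  snps <- sprintf("snp%05d", seq_len(m))
  rownames(calls) <- ids
  colnames(calls) <- snps
  complete <- calls
  if (config$missing_rate > 0) {
    miss <- runif(n * m) < config$missing_rate
    calls[miss] <- NA_integer_
  }
  map <- tibble(
    snp = snps,
    chrom = as.character(rep_len(1:29, m)),
    pos = as.integer(seq_len(m) * 1000L),
    allele1 = "A",
    allele2 = "B",
    counted_allele = "B",
    true_freq = f
  )
  new_geno_matrix(calls, map, complete = complete)
}

new_geno_matrix <- function(calls, map, complete = NULL) {
  structure(
    list(calls = calls, map = map, complete = complete),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " SNPs; ", sum(is.na(x$calls)), " missing calls\n", sep = "")
  invisible(x)
}

#' Simulate a two-generation half-sib pedigree
#'
#' Builds a founder generation of grandsires (roughly one per ten sires, at
#' least two) and assigns each genotyped sire a random grandsire as its
#' sire; dams are unknown.  This is the paternal half-sib structure typical
#' of progeny-tested bull populations.
#'
#' @param config A [sim_config()].
#' @param n_grandsires Number of founder grandsires; default
#'   `max(2, round(n_sires / 10))`.
#' @return Tibble with columns `id`, `sire`, `dam` (`"0"` = unknown);
#'   founders first, so parents precede offspring.
#' @export
simulate_pedigree <- function(config, n_grandsires = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "pedigree"))
  n <- config$n_sires
  if (is.null(n_grandsires)) n_grandsires <- max(2L, as.integer(round(n / 10)))
  gs <- sprintf("GS%03d", seq_len(n_grandsires))
  sires <- sprintf("S%04d", seq_len(n))
  bind_rows(
    tibble(id = gs, sire = "0", dam = "0"),
    tibble(id = sires, sire = sample(gs, n, replace = TRUE), dam = "0")
  )
}

# Symmetric matrix square root tolerant of singular input.
sqrtm_psd <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

# Pseudo-inverse square root.
inv_sqrtm_psd <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- e$values
  inv <- ifelse(v > tol * max(v, tol), 1 / sqrt(v), 0)
  e$vectors %*% (inv * t(e$vectors))
}

#' Simulate true sire intercept and slope effects
#'
#' Draws per-sire reaction-norm effects `(s0, s1)` as the sum of a QTL part
#' — `n_qtl` SNPs with effects from a two-component scale mixture (many
#' small, few large), rescaled so the realized QTL covariance equals
#' `qtl_var_fraction` times the configured sire covariance — and an
#' independent polygenic remainder carrying the rest, so the total sire
#' (co)variance matches `(sigma_s0_sq, sigma_s1_sq, rho_s)`.
#'
#' @param config A [sim_config()].
#' @param genotypes A `geno_matrix` from [simulate_genotypes()].
#' @return A list of class `sim_truth` with elements `sires` (tibble: sire,
#'   s0, s1), `qtl` (tibble: snp, alpha0, alpha1), and `config`.
#' @export
simulate_sire_effects <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  set.seed(stage_seed(config$seed, "sire_effects"))
  n <- config$n_sires
  Gs <- cov2_from(config$sigma_s0_sq, config$sigma_s1_sq, config$rho_s)
  frac <- config$qtl_var_fraction
  if (frac > 1) {
    abort("requested QTL variance exceeds the total sire variance.",
          class = "reactnorm_config_error")
  }

  X <- genotypes$complete
  if (is.null(X)) {
    X <- genotypes$calls
    for (k in seq_len(ncol(X))) {
      xk <- X[, k]
      if (anyNA(xk)) X[is.na(xk), k] <- mean(xk, na.rm = TRUE)
    }
  }

  qtl <- tibble(snp = character(), alpha0 = numeric(), alpha1 = numeric())
  g_qtl <- matrix(0, n, 2)
  if (config$n_qtl > 0 && frac > 0) {
    idx <- sort(sample(ncol(X), config$n_qtl))
    large <- runif(config$n_qtl) < config$qtl_large_fraction
    scale_k <- ifelse(large, config$qtl_large_ratio, 1)
    # raw effect directions follow the shape of the sire covariance so the
    # exact recoloring below stays within its column space (a QTL never
    # receives an effect along a zero-variance direction)
    Ls <- sqrtm_psd(Gs)
    alpha <- t(Ls %*% matrix(rnorm(2 * config$n_qtl), 2)) * scale_k
    Xq <- scale(X[, idx, drop = FALSE], center = TRUE, scale = FALSE)
    g <- Xq %*% alpha
    Sg <- stats::cov(g)
    B <- sqrtm_psd(frac * Gs) %*% inv_sqrtm_psd(Sg)
    alpha <- alpha %*% t(B)
    g_qtl <- g %*% t(B)
    qtl <- tibble(
      snp = colnames(X)[idx],
      alpha0 = alpha[, 1], alpha1 = alpha[, 2]
    )
  }

  Lp <- sqrtm_psd((1 - frac) * Gs)
  poly <- t(Lp %*% matrix(rnorm(2 * n), 2))
  s <- g_qtl + poly
  structure(
    list(
      sires = tibble(
        sire = rownames(X), s0 = s[, 1], s1 = s[, 2],
        qtl0 = g_qtl[, 1], qtl1 = g_qtl[, 2]
      ),
      qtl = qtl,
      config = config
    ),
    class = "sim_truth"
  )
}

cov2_from <- function(v0, v1, rho) {
  cv <- rho * sqrt(v0 * v1)
  matrix(c(v0, cv, cv, v1), 2, 2)
}

#' Simulate daughter records
#'
#' Generates per-daughter trait records under the first-order reaction-norm
#' sire model.  Environments are one standard-normal value per
#' herd-test-day; daughters are nested within sires and assigned to
#' herd-test-days uniformly at random.  In additive mode,
#' `y = mu + b*E + s0 + s1*E + d0 + d1*E + e` with the residual variance
#' taken from the environment-decile class of each record; in
#' multiplicative mode, `y = exp(mu + b*E + s0 + d0 + e)` with a single
#' homogeneous log-scale residual variance, so all observed-scale GxE is
#' scaling.
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth` from [simulate_sire_effects()].
#' @return Tibble with columns `daughter`, `sire`, `htd`, `env`
#'   (standardized environment of the herd-test-day), `res_class`
#'   (environment decile, additive mode) and `yield`.  The realized
#'   herd-test-day environments and the true daughter effects are attached
#'   as attributes `environment` and `daughter_effects` (ground truth).
#' @export
simulate_daughter_records <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(stage_seed(config$seed, "daughter_records"))
  sires <- truth$sires
  n_s <- nrow(sires)

  nd <- if (length(config$daughters_per_sire) == 2) {
    sample(config$daughters_per_sire[1]:config$daughters_per_sire[2], n_s, replace = TRUE)
  } else {
    rep(config$daughters_per_sire, n_s)
  }
  n_d <- sum(nd)
  daughter_sire <- rep(seq_len(n_s), nd)
  daughter_id <- sprintf("D%06d", seq_len(n_d))

  env_htd <- rnorm(config$n_htd)
  htd_id <- sprintf("HTD%05d", seq_len(config$n_htd))

  Gd <- cov2_from(config$sigma_d0_sq, config$sigma_d1_sq, config$rho_d)
  d_eff <- t(sqrtm_psd(Gd) %*% matrix(rnorm(2 * n_d), 2))

  r <- config$records_per_daughter
  if (r > config$n_htd) {
    abort("`records_per_daughter` cannot exceed `n_htd`.",
          class = "reactnorm_config_error")
  }
  rec_htd <- if (r == 1) {
    sample.int(config$n_htd, n_d, replace = TRUE)
  } else {
    unlist(lapply(seq_len(n_d), function(i) sample.int(config$n_htd, r)))
  }
  rec_daughter <- rep(seq_len(n_d), each = r)

  records <- tibble(
    daughter = daughter_id[rec_daughter],
    sire = sires$sire[daughter_sire[rec_daughter]],
    htd = htd_id[rec_htd],
    env = env_htd[rec_htd]
  )

  E <- records$env
  s0 <- sires$s0[daughter_sire[rec_daughter]]
  s1 <- sires$s1[daughter_sire[rec_daughter]]
  d0 <- d_eff[rec_daughter, 1]
  d1 <- d_eff[rec_daughter, 2]

  if (config$gxe_mode == "additive") {
    records$res_class <- assign_residual_classes(records, n_classes = 10)
    sig2 <- config$residual_class_variances[records$res_class]
    e <- rnorm(nrow(records), sd = sqrt(sig2))
    records$yield <- config$mu + config$b_fixed * E + s0 + s1 * E + d0 + d1 * E + e
  } else {
    sig2 <- mean(config$residual_class_variances)
    e <- rnorm(nrow(records), sd = sqrt(sig2))
    records$yield <- exp(config$mu + config$b_fixed * E + s0 + d0 + e)
    if (any(!is.finite(records$yield)) || any(records$yield <= 0)) {
      abort(paste0(
        "multiplicative mode produced nonpositive or non-finite yields; ",
        "check `mu` (", config$mu, ") and the log-scale variances."
      ), class = "reactnorm_sim_error")
    }
    records$res_class <- 1L
  }

  attr(records, "environment") <- tibble(htd = htd_id, env = env_htd)
  attr(records, "daughter_effects") <- tibble(
    daughter = daughter_id,
    sire = sires$sire[daughter_sire],
    d0 = d_eff[, 1], d1 = d_eff[, 2]
  )
  records
}

#' Simulate a complete progeny-test dataset
#'
#' Runs [simulate_genotypes()], [simulate_pedigree()],
#' [simulate_sire_effects()] and [simulate_daughter_records()] in order and
#' collects the results with full ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `gxe_sim`: `genotypes` (`geno_matrix`), `pedigree`
#'   (tibble), `records` (tibble), and `truth` (`sim_truth`, extended with
#'   `daughters` and `environment`).
#' @examples
#' sim <- simulate_dataset(sim_config(n_sires = 10, daughters_per_sire = 5,
#'                                    n_snps = 20, n_qtl = 2, seed = 3))
#' head(sim$records)
#' @export
simulate_dataset <- function(config) {
  genotypes <- simulate_genotypes(config)
  pedigree <- simulate_pedigree(config)
  truth <- simulate_sire_effects(config, genotypes)
  records <- simulate_daughter_records(config, truth)
  truth$daughters <- attr(records, "daughter_effects")
  truth$environment <- attr(records, "environment")
  attr(records, "daughter_effects") <- NULL
  attr(records, "environment") <- NULL
  structure(
    list(genotypes = genotypes, pedigree = pedigree,
         records = records, truth = truth),
    class = "gxe_sim"
  )
}

#' @export
print.gxe_sim <- function(x, ...) {
  cat("<gxe_sim> ", nrow(x$records), " records, ",
      nrow(x$truth$sires), " sires, ", ncol(x$genotypes$calls), " SNPs (",
      nrow(x$truth$qtl), " QTL), mode ", x$truth$config$gxe_mode, "\n", sep = "")
  invisible(x)
}
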