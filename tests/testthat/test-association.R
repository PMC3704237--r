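test_that("discovery/validation split is uniform, disjoint, reproducible", {
  ids <- sprintf("S%04d", 1:2297)
  sp <- split_sires(ids, n_validation = 500, seed = 3)
  expect_length(sp$discovery, 1797)
  expect_length(sp$validation, 500)
  expect_length(intersect(sp$discovery, sp$validation), 0)
  expect_setequal(c(sp$discovery, sp$validation), ids)
  expect_identical(sp, split_sires(ids, n_validation = 500, seed = 3))
  expect_false(identical(sp$validation,
                         split_sires(ids, 500, seed = 4)$validation))
  expect_error(split_sires(ids[1:10], n_validation = 10),
               class = "reactnorm_config_error")
})

test_that("single-SNP mixed model reduces to OLS under identity kinship", {
  set.seed(11)
  n <- 120
  x <- rbinom(n, 2, 0.3)
  y <- 0.4 * x + rnorm(n)
  names(y) <- sprintf("S%04d", 1:n)
  A <- diag(n); dimnames(A) <- list(names(y), names(y))
  f <- fit_snp_mlm(y, x, A, delta = 1e-12)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(f$beta, ols[2, 1], tolerance = 1e-6)
  expect_equal(f$se, ols[2, 2], tolerance = 1e-4)
  # with no polygenic structure the profiled ratio collapses toward zero
  f2 <- fit_snp_mlm(y, x, A)
  expect_equal(f2$beta, ols[2, 1], tolerance = 1e-3)
})

test_that("single-SNP mixed model matches a dense GLS grid-search oracle", {
  set.seed(12)
  for (rep in 1:3) {
    ped <- random_pedigree(3, 5)
    ids <- tail(ped$id, 8)
    A <- build_numerator_relationship(ped, ids)
    x <- rbinom(8, 2, 0.4)
    while (var(x) == 0) x <- rbinom(8, 2, 0.4)
    L <- t(chol(A + diag(8) * 1e-8))
    y <- drop(L %*% rnorm(8)) + 0.3 * x + rnorm(8, sd = 0.5)
    names(y) <- ids
    f <- fit_snp_mlm(y, x, A)
    oracle <- gls_snp_oracle(y, x, A)
    expect_equal(f$beta, oracle$beta, tolerance = 1e-6, ignore_attr = TRUE)
    expect_gte(f$loglik, oracle$ll - 1e-6)
  }
})

test_that("allele recoding flips the effect sign but not the p-value", {
  set.seed(13)
  n <- 60
  ids <- sprintf("S%04d", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  x <- rbinom(n, 2, 0.4)
  y <- setNames(0.5 * x + rnorm(n), ids)
  f1 <- fit_snp_mlm(y, x, A)
  f2 <- fit_snp_mlm(y, 2 - x, A)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-8)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
  expect_error(fit_snp_mlm(y, rep(1, n), A), class = "reactnorm_domain_error")
})

test_that("a planted effect of half a phenotypic SD is detected", {
  set.seed(14)
  n <- 500
  ids <- sprintf("S%04d", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  x <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  y <- setNames(y + 0.5 * sd(y) * x, ids)
  f <- fit_snp_mlm(y, x, A)
  expect_lt(f$p, 1e-10)
})

test_that("a genome scan flags planted QTL and handles degenerate columns", {
  cfg <- sim_config(n_sires = 150, daughters_per_sire = 40, n_htd = 600,
                    n_snps = 30, n_qtl = 1, qtl_var_fraction = 0.6,
                    maf_range = c(0.3, 0.5), seed = 15)
  sim <- simulate_dataset(cfg)
  fit <- fit_reaction_norm(sim$records, se = FALSE)
  A <- build_numerator_relationship(sim$pedigree, fit$sire_estimates$sire)
  g <- sim$genotypes
  # duplicate the QTL column and add a monomorphic SNP
  qtl_idx <- match(sim$truth$qtl$snp, g$map$snp)
  g$calls <- cbind(g$calls, dup = g$calls[, qtl_idx],
                   mono = rep(1L, nrow(g$calls)))
  colnames(g$calls)[31:32] <- c("dup", "mono")
  g$map <- dplyr::bind_rows(
    g$map,
    tibble::tibble(snp = c("dup", "mono"), chrom = "1",
                   pos = c(31000L, 32000L), allele1 = "A", allele2 = "B",
                   counted_allele = "B", true_freq = NA))
  gw <- run_gwas(fit$sire_estimates, g, A, component = "gp")
  expect_true(gw$significant[qtl_idx])
  expect_true(gw$failed[gw$snp == "mono"])
  expect_false(gw$significant[gw$snp == "mono"])
  # duplicated SNP column gives identical statistics
  expect_equal(gw$beta[gw$snp == "dup"], gw$beta[qtl_idx], tolerance = 1e-10)
  expect_equal(gw$p[gw$snp == "dup"], gw$p[qtl_idx], tolerance = 1e-10)
  # q-values attached and within [0, 1]
  expect_true(all(gw$q[!gw$failed] >= 0 & gw$q[!gw$failed] <= 1))
})

test_that("validation applies the p-and-sign rule and reports its estimates", {
  make_gwas <- function(snps, beta, p, sig) {
    out <- tibble::tibble(snp = snps, chrom = "1",
                          pos = seq_along(snps) * 1000L, component = "gp",
                          freq = 0.5, beta = beta, se = 1, stat = beta,
                          p = p, q = p, significant = sig, failed = FALSE)
    class(out) <- c("gwas_table", class(out))
    out
  }
  set.seed(16)
  n <- 200
  ids <- sprintf("V%03d", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  x1 <- rbinom(n, 2, 0.4)  # strong, positive in validation
  x2 <- rbinom(n, 2, 0.4)  # null
  calls <- cbind(s1 = x1, s2 = x2)
  rownames(calls) <- ids
  geno <- make_geno(calls)
  yv <- setNames(2 * x1 + rnorm(n), ids)
  est <- tibble::tibble(sire = ids, gp = yv)

  disc <- make_gwas(c("s1", "s2"), beta = c(1.5, 2.0), p = c(1e-5, 1e-4),
                    sig = c(TRUE, TRUE))
  v <- validate_snps(disc, est, geno, A)
  expect_true(v$validated[v$snp == "s1"])
  expect_false(v$validated[v$snp == "s2"])

  # same strength but opposite discovery sign: sign rule rejects
  disc_flip <- make_gwas("s1", beta = -1.5, p = 1e-5, sig = TRUE)
  v2 <- validate_snps(disc_flip, est, geno, A)
  expect_lt(v2$p_validation, 0.01)
  expect_false(v2$validated)

  # empty significant set returns an empty table, not an error
  none <- make_gwas("s1", beta = 1, p = 0.5, sig = FALSE)
  expect_equal(nrow(validate_snps(none, est, geno, A)), 0)
})

test_that("FDR at the significance threshold is the boundary SNP's q-value", {
  p <- c(1e-9, rep(1, 999))
  gw <- tibble::tibble(snp = sprintf("s%03d", seq_along(p)), p = p,
                       q = qvalues(p, pi0 = 1)$qvalues)
  class(gw) <- c("gwas_table", class(gw))
  expect_equal(estimate_fdr_at_threshold(gw), gw$q[1])
  # pi0 = 1 case equals the BH adjusted p at the boundary SNP
  p2 <- c(1e-6, 5e-4, 9e-4, runif(500, 0.01, 1))
  gw2 <- tibble::tibble(snp = sprintf("s%03d", seq_along(p2)), p = p2,
                        q = qvalues(p2, pi0 = 1)$qvalues)
  class(gw2) <- c("gwas_table", class(gw2))
  expect_equal(estimate_fdr_at_threshold(gw2),
               p.adjust(p2, "BH")[which.max(p2 * (p2 <= 0.001))])
  expect_warning(res <- estimate_fdr_at_threshold(gw2, p_threshold = 1e-12),
                 "undefined")
  expect_true(is.na(res))
})

test_that("type-I error is calibrated under phenotype permutation (desk scale)", {
  set.seed(17)
  n <- 300; m <- 2000
  ped <- simulate_pedigree(sim_config(n_sires = n, n_snps = 2, seed = 18))
  ids <- sprintf("S%04d", 1:n)
  A <- build_numerator_relationship(ped, ids)
  calls <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(1:m, each = n)]), n, m)
  rownames(calls) <- ids; colnames(calls) <- sprintf("x%04d", 1:m)
  geno <- make_geno(calls)
  L <- t(chol(A))
  y <- drop(L %*% rnorm(n)) + rnorm(n)
  y_perm <- setNames(sample(y), ids)
  est <- tibble::tibble(sire = ids, gp = unname(y_perm))
  gw <- run_gwas(est, geno, A, component = "gp")
  hits <- sum(gw$p < 0.001, na.rm = TRUE)
  bounds <- qbinom(c(0.005, 0.995), m, 0.001)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2] + 1)
})
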